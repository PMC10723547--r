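#' Risk parameters of the linear-quadratic excess-relative-risk model
#'
#' The relative-risk factor at dose D is `1 + alpha * D + beta * D^2`;
#' `alpha` is the excess relative risk per Gy, `beta` per Gy^2, and `kappa`
#' a log baseline scaling. The study's true values are `alpha = 0.25`/Gy and
#' `beta = 2`/Gy^2.
#'
#' @param alpha,beta,kappa numeric scalars.
#' @return An object of class `risk_parameters`.
#' @export
risk_parameters <- function(alpha = 0.25, beta = 2, kappa = 0) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(kappa))
  structure(list(alpha = alpha, beta = beta, kappa = kappa),
            class = "risk_parameters")
}

rr_factor <- function(dose, alpha, beta) 1 + alpha * dose + beta * dose^2

#' Per-individual case probabilities under the linear-quadratic model
#'
#' The probability that individual i is a case is
#' `exp(kappa) * (1 + alpha * D_i + beta * D_i^2)`, with `kappa` chosen so
#' the probabilities sum to one: `kappa = -log(sum_i(1 + alpha D_i + beta
#' D_i^2))`.
#'
#' @param true_doses numeric vector of per-individual true doses (Gy).
#' @param alpha,beta risk coefficients.
#' @return List with `probabilities` (summing to 1) and `kappa`.
#' @examples
#' cp <- case_probabilities(rep(0.5, 4), alpha = 0.25, beta = 2)
#' sum(cp$probabilities)
#' @export
case_probabilities <- function(true_doses, alpha = 0.25, beta = 2) {
  f <- rr_factor(true_doses, alpha, beta)
  if (any(f <= 0))
    stop("1 + alpha*D + beta*D^2 must be positive for every individual")
  kappa <- -log(sum(f))
  list(probabilities = exp(kappa) * f, kappa = kappa)
}

#' Allocate a fixed number of cases across individuals
#'
#' Draws the case counts as a single multinomial sample of size `n_cases`
#' over the individual case probabilities, so the total number of cases is
#' exactly `n_cases` in every replication. Individuals may carry
#' multiplicity; only group sums reach the grouped Poisson fitters.
#'
#' @param probabilities numeric probability vector summing to 1.
#' @param n_cases total number of cases (default 250).
#' @param seed optional integer seed for the outcome stream.
#' @return Integer vector of per-individual case counts summing to `n_cases`.
#' @export
allocate_cases <- function(probabilities, n_cases = 250, seed = NULL) {
  if (any(probabilities < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(probabilities) - 1) > 1e-8)
    stop("probabilities must sum to 1")
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 0L) stop("n_cases must be >= 0")
  if (n_cases == 0L) return(integer(length(probabilities)))
  with_stream_seed(if (is.null(seed)) NULL else stream_seed(seed, "outcome"),
                   as.integer(stats::rmultinom(1L, n_cases, probabilities)))
}

#' Collapse individual data to grouped data
#'
#' Sums cases and averages the supplied per-individual doses within each
#' design group. The dose vector is method-dependent: the surrogate doses
#' for the unadjusted method, or any other per-individual dose assignment.
#'
#' @param case_counts integer vector of per-individual case counts.
#' @param doses numeric vector of per-individual doses to average.
#' @param group_index integer vector of group memberships.
#' @param design a [cohort_design()].
#' @return A `grouped_data` object: data frame with columns `group`,
#'   `persons`, `cases`, `dose`.
#' @export
collapse_to_groups <- function(case_counts, doses, group_index, design) {
  gi <- as.integer(group_index)
  stopifnot(length(case_counts) == length(gi), length(doses) == length(gi))
  cases <- as.integer(rowsum(as.numeric(case_counts), gi, reorder = TRUE))
  grouped_data(design, cases, group_mean_doses(doses, gi))
}

#' Construct grouped data directly
#'
#' @param design a [cohort_design()].
#' @param cases integer vector of per-group case counts.
#' @param dose numeric vector of per-group doses (Gy).
#' @return A `grouped_data` object.
#' @export
grouped_data <- function(design, cases, dose) {
  stopifnot(inherits(design, "cohort_design"),
            length(cases) == nrow(design), length(dose) == nrow(design))
  if (any(cases < 0)) stop("cases must be nonnegative")
  out <- data.frame(group = design$group, persons = design$persons,
                    cases = as.integer(cases), dose = as.numeric(dose))
  class(out) <- c("grouped_data", "data.frame")
  out
}

#' @export
print.grouped_data <- function(x, ...) {
  cat("Grouped cohort data:", sum(x$cases), "cases among", sum(x$persons),
      "persons in", nrow(x), "dose groups\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read/write grouped data as a delimited table
#'
#' Columns `group`, `persons`, `cases`, `dose_Gy`, so the fitters can be
#' exercised standalone on a 5-row text file.
#'
#' @param path file path.
#' @param design optional [cohort_design()]; reconstructed from the file's
#'   persons column and dose groups when omitted (doses then taken as the
#'   file's `dose_Gy`, which need not be the design central doses, so the
#'   design central doses default to the group order rank).
#' @return A `grouped_data` object.
#' @export
read_grouped_data <- function(path, design = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  need <- c("group", "persons", "cases", "dose_Gy")
  if (!all(need %in% names(tab)))
    stop("grouped data file must have columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$group), ]
  if (is.null(design))
    design <- cohort_design(seq_along(tab$persons), tab$persons)
  grouped_data(design, tab$cases, tab$dose_Gy)
}

#' @rdname read_grouped_data
#' @param data a `grouped_data` object to write.
#' @export
write_grouped_data <- function(data, path) {
  out <- data.frame(group = data$group, persons = data$persons,
                    cases = data$cases, dose_Gy = data$dose)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
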