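#' Grouped cohort design
#'
#' A cohort design is a small table of dose groups, each with a central dose
#' estimate (Gy) and a number of persons. Individuals are permanently assigned
#' to their design group; realized doses never trigger regrouping.
#'
#' @param central_dose numeric vector of central dose estimates in Gy,
#'   strictly increasing.
#' @param persons integer vector of person counts per group, all positive.
#' @return An object of class `cohort_design`: a data frame with columns
#'   `group`, `central_dose`, `persons`.
#' @examples
#' cohort_design(c(0.1, 1), c(100, 10))
#' @export
cohort_design <- function(central_dose, persons) {
  if (length(central_dose) != length(persons) || length(persons) < 1L)
    stop("central_dose and persons must be non-empty vectors of equal length")
  if (any(!is.finite(central_dose)) || any(central_dose <= 0))
    stop("central doses must be positive and finite")
  if (any(diff(central_dose) <= 0))
    stop("central doses must be strictly increasing across groups")
  persons <- as.integer(persons)
  if (any(is.na(persons)) || any(persons <= 0L))
    stop("persons must be positive counts")
  design <- data.frame(
    group = seq_along(persons),
    central_dose = as.numeric(central_dose),
    persons = persons
  )
  class(design) <- c("cohort_design", "data.frame")
  design
}

#' Default five-group leukaemia-cohort design
#'
#' The fixed design used throughout the simulation study: five dose groups
#' with central doses 0.01, 0.1, 0.5, 1.5 and 2 Gy and person counts 2591,
#' 334, 438, 102 and 6 (3471 persons in total), patterned on the person-year
#' distribution of a Japanese atomic-bomb-survivor leukaemia cohort.
#'
#' @return A [cohort_design()] with 5 groups and 3471 persons.
#' @export
default_cohort <- function() {
  cohort_design(
    central_dose = c(0.01, 0.1, 0.5, 1.5, 2),
    persons = c(2591L, 334L, 438L, 102L, 6L)
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Cohort design:", nrow(x), "dose groups,", sum(x$persons),
      "persons\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Per-individual group index for a design
#'
#' @param design a [cohort_design()].
#' @return Integer vector of length `sum(persons)` mapping each individual to
#'   its group, in group order.
#' @export
group_index <- function(design) {
  rep.int(design$group, design$persons)
}

#' Read a cohort design from a delimited text file
#'
#' Expects columns `group`, `central_dose_Gy`, `persons` (header required;
#' any of tab, comma or whitespace as separator).
#'
#' @param path file path.
#' @return A [cohort_design()].
#' @export
read_cohort_design <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (!all(c("group", "central_dose_Gy", "persons") %in% names(tab))) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("group", "central_dose_Gy", "persons")
  if (!all(need %in% names(tab)))
    stop("cohort design file must have columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$group), ]
  cohort_design(tab$central_dose_Gy, tab$persons)
}

#' Write a cohort design to a delimited text file
#'
#' @param design a [cohort_design()].
#' @param path output file path.
#' @export
write_cohort_design <- function(design, path) {
  out <- data.frame(group = design$group,
                    central_dose_Gy = design$central_dose,
                    persons = design$persons)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Composite Berkson-classical error model
#'
#' Four log-scale standard deviations (geometric standard deviations, GSD)
#' of the multiplicative lognormal error components: shared and unshared
#' Berkson error on the true dose, shared and unshared classical error on the
#' surrogate dose. A GSD of 0.2 corresponds to the "20\%" setting; shared
#' components use one standard-normal draw per realization common to all
#' individuals, unshared components one draw per individual per realization.
#'
#' @param sigma_share_berkson,sigma_unshare_berkson log-scale SDs of the
#'   shared and unshared Berkson components (>= 0).
#' @param sigma_share_class,sigma_unshare_class log-scale SDs of the shared
#'   and unshared classical components (>= 0).
#' @return An object of class `error_model`.
#' @examples
#' error_model(0.2, 0.2, 0.5, 0.5)
#' @export
error_model <- function(sigma_share_berkson = 0, sigma_unshare_berkson = 0,
                        sigma_share_class = 0, sigma_unshare_class = 0) {
  sig <- c(sigma_share_berkson = sigma_share_berkson,
           sigma_unshare_berkson = sigma_unshare_berkson,
           sigma_share_class = sigma_share_class,
           sigma_unshare_class = sigma_unshare_class)
  if (any(!is.finite(sig)) || any(sig < 0))
    stop("all error-model GSDs must be finite and >= 0")
  structure(as.list(sig), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "Error model (log-scale GSDs): Berkson shared %.3g / unshared %.3g, classical shared %.3g / unshared %.3g\n",
    x$sigma_share_berkson, x$sigma_unshare_berkson,
    x$sigma_share_class, x$sigma_unshare_class))
  invisible(x)
}
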