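#' Deterministic child seed for a named random stream
#'
#' Derives a reproducible child seed from a master seed and an arbitrary
#' sequence of integer or character keys (replication index, stream name,
#' ...). Distinct streams get distinct, stably ordered seeds, so varying one
#' stream's settings (e.g. the classical-error GSDs) leaves every other
#' stream's draws bit-identical. The mixing is a Lehmer multiplicative
#' congruential step modulo the Mersenne prime 2^31 - 1, exact in double
#' precision.
#'
#' @param master integer master seed.
#' @param ... keys identifying the stream (integers or strings).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @examples
#' stream_seed(1, 3, "berkson_shared")
#' @export
stream_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1
  a <- 48271       # MINSTD multiplier; products stay below 2^53
  h <- (abs(as.numeric(master)) %% (m - 1)) + 1
  for (key in list(...)) {
    if (is.character(key)) key <- utf8ToInt(key) else key <- as.numeric(key)
    for (k in key) {
      h <- (h + (abs(k) %% m)) %% m
      if (h == 0) h <- 1
      h <- (h * a) %% m
      h <- (h * a) %% m
    }
  }
  as.integer(h)
}

with_stream_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate true-dose realizations under multiplicative Berkson error
#'
#' Each individual's true dose in realization j is the group central dose
#' times `exp(-(s^2 + u^2)/2) * exp(s * eps_j + u * delta_ij)`, where `s` and
#' `u` are the shared and unshared Berkson GSDs, `eps_j` is one standard
#' normal draw per realization common to every individual, and `delta_ij` is
#' an individual-specific standard normal draw. The leading factor makes the
#' theoretical mean of each dose equal its central estimate.
#'
#' @param design a [cohort_design()].
#' @param err an [error_model()]; only the Berkson components are used.
#' @param n_realizations number of realizations (columns) to draw.
#' @param seed optional integer seed; when given, the shared and unshared
#'   draws come from two independent child streams of it (see
#'   [stream_seed()]), so classical-error settings elsewhere never perturb
#'   the true doses. When `NULL` the current RNG state is used.
#' @return An object of class `dose_ensemble` with elements `true_doses`
#'   (matrix, individual x realization), `group_index`, `design`,
#'   `n_realizations`, and `surrogate_doses` (`NULL` until filled by
#'   [simulate_surrogate_doses()]).
#' @examples
#' ens <- simulate_true_doses(default_cohort(), error_model(0.2, 0.2),
#'                            n_realizations = 10, seed = 1)
#' dim(ens$true_doses)
#' @export
simulate_true_doses <- function(design, err, n_realizations,
                                seed = NULL) {
  stopifnot(inherits(design, "cohort_design"), inherits(err, "error_model"))
  n_realizations <- as.integer(n_realizations)
  if (is.na(n_realizations) || n_realizations < 1L)
    stop("n_realizations must be >= 1")
  s <- err$sigma_share_berkson
  u <- err$sigma_unshare_berkson
  gi <- group_index(design)
  n <- length(gi)
  bias <- exp(-0.5 * (s^2 + u^2))
  cent <- design$central_dose[gi]

  eps <- if (s > 0) {
    with_stream_seed(if (is.null(seed)) NULL else
      stream_seed(seed, "berkson_shared"),
      stats::rnorm(n_realizations))
  } else numeric(n_realizations)
  logdev <- if (u > 0) {
    delta <- with_stream_seed(if (is.null(seed)) NULL else
      stream_seed(seed, "berkson_unshared"),
      stats::rnorm(n * n_realizations))
    matrix(u * delta, n, n_realizations)
  } else matrix(0, n, n_realizations)
  if (s > 0) logdev <- sweep(logdev, 2L, s * eps, `+`)
  true <- (bias * cent) * exp(logdev)

  structure(list(true_doses = true, surrogate_doses = NULL,
                 group_index = gi, design = design,
                 n_realizations = n_realizations),
            class = "dose_ensemble")
}

#' Simulate one surrogate-dose vector under multiplicative classical error
#'
#' The surrogate dose scatters around the group central dose (not the true
#' dose): `central * exp(-(s^2 + u^2)/2) * exp(s * mu + u * kap_i)` with one
#' shared draw `mu` for the whole vector and an unshared draw `kap_i` per
#' individual. Given group, the surrogate is therefore conditionally
#' independent of the true dose. One surrogate vector is drawn per
#' replication (the unadjusted method uses a single sampled dose per
#' individual).
#'
#' @param design a [cohort_design()].
#' @param err an [error_model()]; only the classical components are used.
#' @param seed optional integer seed; child streams as in
#'   [simulate_true_doses()].
#' @return Numeric vector of positive doses, one per individual.
#' @export
simulate_surrogate_doses <- function(design, err, seed = NULL) {
  stopifnot(inherits(design, "cohort_design"), inherits(err, "error_model"))
  s <- err$sigma_share_class
  u <- err$sigma_unshare_class
  gi <- group_index(design)
  n <- length(gi)
  bias <- exp(-0.5 * (s^2 + u^2))
  cent <- design$central_dose[gi]
  mu <- if (s > 0) {
    with_stream_seed(if (is.null(seed)) NULL else
      stream_seed(seed, "classical_shared"), stats::rnorm(1L))
  } else 0
  kap <- if (u > 0) {
    with_stream_seed(if (is.null(seed)) NULL else
      stream_seed(seed, "classical_unshared"), stats::rnorm(n))
  } else numeric(n)
  as.numeric(bias * cent * exp(s * mu + u * kap))
}

#' Per-group arithmetic mean doses
#'
#' Collapses individual doses to group means, one mean per realization.
#'
#' @param doses numeric vector (one realization) or matrix
#'   (individual x realization).
#' @param group_index integer vector mapping rows/elements to groups 1..K.
#' @return For a vector input, a K-vector of group means; for a matrix, a
#'   K x n_realizations matrix.
#' @export
group_mean_doses <- function(doses, group_index) {
  gi <- as.integer(group_index)
  k <- max(gi)
  counts <- tabulate(gi, nbins = k)
  if (any(counts == 0L)) stop("every group must contain at least one individual")
  if (is.matrix(doses)) {
    if (nrow(doses) != length(gi))
      stop("nrow(doses) must equal length(group_index)")
    out <- rowsum(doses, gi, reorder = TRUE) / counts
    dimnames(out) <- NULL
    out
  } else {
    if (length(doses) != length(gi))
      stop("length(doses) must equal length(group_index)")
    as.numeric(rowsum(doses, gi, reorder = TRUE) / counts)
  }
}

#' Regression-calibration group doses
#'
#' The calibrated dose for each group is the per-realization group mean of
#' the true doses, averaged over all realizations in the ensemble — the
#' Monte-Carlo estimate of the conditional expectation of the group-mean true
#' dose used by the regression-calibration method.
#'
#' @param ensemble a `dose_ensemble` from [simulate_true_doses()].
#' @return Numeric K-vector of calibrated group doses (Gy).
#' @export
calibrated_group_doses <- function(ensemble) {
  stopifnot(inherits(ensemble, "dose_ensemble"))
  gm <- group_mean_doses(ensemble$true_doses, ensemble$group_index)
  as.numeric(rowMeans(gm))
}

#' Sample correlation between same-group individuals' true doses
#'
#' Estimates the between-individual true-dose correlation induced by the
#' shared Berkson component: distinct same-group individuals are paired
#' (1,2), (3,4), ... within each group, their doses standardized by the
#' pooled within-group moments, and the Pearson correlation computed over
#' all pairs and realizations. The population value is
#' `(exp(s^2) - 1) / (exp(s^2 + u^2) - 1)` for shared GSD `s`, unshared `u`.
#'
#' @param ensemble a `dose_ensemble` with at least 2 realizations and at
#'   least one group of 2+ individuals.
#' @return Correlation estimate, or `NA` (with a warning) when the doses are
#'   degenerate (zero variance).
#' @export
shared_dose_correlation <- function(ensemble) {
  stopifnot(inherits(ensemble, "dose_ensemble"))
  if (ensemble$n_realizations < 2L)
    stop("need at least 2 realizations to estimate a correlation")
  gi <- ensemble$group_index
  d <- ensemble$true_doses
  xs <- list(); ys <- list()
  for (g in unique(gi)) {
    idx <- which(gi == g)
    if (length(idx) < 2L) next
    npair <- length(idx) %/% 2L
    first <- idx[seq.int(1L, by = 2L, length.out = npair)]
    second <- idx[seq.int(2L, by = 2L, length.out = npair)]
    vals <- d[idx, , drop = FALSE]
    m <- mean(vals); sdev <- stats::sd(as.numeric(vals))
    if (!is.finite(sdev) || sdev == 0) next
    xs[[length(xs) + 1L]] <- as.numeric((d[first, , drop = FALSE] - m) / sdev)
    ys[[length(ys) + 1L]] <- as.numeric((d[second, , drop = FALSE] - m) / sdev)
  }
  if (length(xs) == 0L) {
    warning("dose ensemble is degenerate (zero variance); correlation undefined")
    return(NA_real_)
  }
  stats::cor(unlist(xs), unlist(ys))
}

#' @export
print.dose_ensemble <- function(x, ...) {
  cat("Dose ensemble:", length(x$group_index), "individuals x",
      x$n_realizations, "realizations",
      if (is.null(x$surrogate_doses)) "(no surrogate vector)" else
        "(with surrogate vector)", "\n")
  invisible(x)
}

#' Export a dose ensemble's true-dose matrix to a delimited file
#'
#' One row per individual, one column per realization; first column is the
#' group index. Intended for debugging, not bulk storage.
#'
#' @param ensemble a `dose_ensemble`.
#' @param path output file path.
#' @export
write_dose_matrix <- function(ensemble, path) {
  out <- cbind(group = ensemble$group_index, ensemble$true_doses)
  colnames(out) <- c("group", paste0("realization_", seq_len(ensemble$n_realizations)))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
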