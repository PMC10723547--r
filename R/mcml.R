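#' Monte Carlo averaged grouped Poisson log-likelihood
#'
#' Averages the grouped Poisson linear relative-risk likelihood — on the
#' natural scale, not the log scale — over an ensemble of per-realization
#' group-mean dose vectors, then returns the log of the average:
#' `log[(1/R) * sum_r exp(l_r(params))]`, stabilized by the log-sum-exp
#' shift. Realizations where the relative-risk factor is infeasible
#' contribute likelihood zero; if all are infeasible the value is `-Inf`.
#'
#' @param cases integer vector of grouped case counts (length K).
#' @param group_dose_ensemble K x R matrix of per-realization group-mean
#'   doses (Gy).
#' @param persons person counts per group (offsets).
#' @param params a [risk_parameters()] object.
#' @return Averaged log-likelihood value.
#' @export
averaged_log_likelihood <- function(cases, group_dose_ensemble, persons,
                                    params) {
  stopifnot(inherits(params, "risk_parameters"))
  ll <- scenario_logliks(cases, group_dose_ensemble, persons,
                         params$alpha, params$beta, params$kappa)
  log_mean_exp(ll)
}

# vector of per-realization grouped Poisson log-likelihoods (length R);
# infeasible realizations get -Inf
scenario_logliks <- function(cases, dose_ens, persons, alpha, beta, kappa) {
  f <- 1 + alpha * dose_ens + beta * dose_ens^2
  bad <- colSums(f <= 0) > 0
  f[f <= 0] <- NA_real_  # avoid log-of-negative warnings; flagged via `bad`
  mu <- persons * exp(kappa) * f
  ll <- colSums(cases * log(mu)) - colSums(mu) - sum(lfactorial(cases))
  ll[bad] <- -Inf
  ll
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(mean(exp(x - m)))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Monte Carlo maximum-likelihood fit over a dose-realization ensemble
#'
#' Maximizes [averaged_log_likelihood()] over `(kappa, alpha, beta)`; the
#' averaged surface has no closed-form kappa profile, so the search is
#' three-dimensional. Because a likelihood averaged over dose scenarios is
#' in general multimodal (each scenario scale supports a rescaled solution),
#' the fit ascends locally (BFGS) from the regression-calibration solution —
#' the maximum-likelihood fit at the ensemble-mean group doses, which is the
#' consistent estimator in the absence of shared error — and reports the
#' mode uphill from it. Profile-likelihood intervals are computed on the
#' averaged surface by outward-walking, warm-started local profiling. With a
#' single realization (or identical realizations) the fit coincides with the
#' plain maximum-likelihood fit.
#'
#' @param cases grouped case counts (length K).
#' @param group_dose_ensemble K x R matrix of per-realization group-mean
#'   doses, e.g. `group_mean_doses(ensemble$true_doses, ensemble$group_index)`.
#' @param persons person counts per group.
#' @param compute_ci compute profile intervals (default `TRUE`).
#' @param level confidence level.
#' @param init optional `c(kappa, alpha, beta)` start overriding the
#'   regression-calibration start.
#' @return A `fit_result` with `method_tag = "mcml"`.
#' @export
fit_mcml <- function(cases, group_dose_ensemble, persons, compute_ci = TRUE,
                     level = 0.95, init = NULL) {
  dose_ens <- as.matrix(group_dose_ensemble)
  stopifnot(length(cases) == nrow(dose_ens),
            length(persons) == nrow(dose_ens))
  nll <- function(p) {  # p = (kappa, alpha, beta)
    v <- log_mean_exp(scenario_logliks(cases, dose_ens, persons,
                                       p[2L], p[3L], p[1L]))
    if (is.finite(v)) -v else 1e10
  }
  st <- if (!is.null(init)) init else {
    rc <- fit_ml(grouped_data(cohort_design(seq_len(nrow(dose_ens)),
                                            persons),
                              cases, rowMeans(dose_ens)),
                 compute_ci = FALSE)
    c(rc$kappa_hat, rc$alpha_hat, rc$beta_hat)
  }
  if (nll(st) >= 1e10) st <- c(log(sum(cases) / sum(persons)), 0.1, 1)
  if (nll(st) >= 1e10) stop("no feasible start for the MCML fit")
  opt <- stats::optim(st, nll, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  # simplex polish: the averaged surface has kinks where scenarios enter or
  # leave the feasible set, so convergence is declared when a fresh simplex
  # finds no further local improvement, not by a smooth-gradient test
  opt2 <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                       control = list(reltol = 1e-12, maxit = 2000))
  if (opt2$value <= opt$value) opt <- opt2
  polish <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                         control = list(reltol = 1e-12, maxit = 2000))
  converged <- (opt$value - polish$value) < 1e-6 * max(1, abs(opt$value))
  if (polish$value < opt$value) opt <- polish
  par <- opt$par
  llmax <- -opt$value
  profile_fixed <- function(which, value, hint = NULL) {
    # local maximum over (kappa, free coefficient) with `which` fixed
    obj <- if (which == "alpha") {
      function(p) {
        v <- log_mean_exp(scenario_logliks(cases, dose_ens, persons,
                                           value, p[2L], p[1L]))
        if (is.finite(v)) -v else 1e10
      }
    } else {
      function(p) {
        v <- log_mean_exp(scenario_logliks(cases, dose_ens, persons,
                                           p[2L], value, p[1L]))
        if (is.finite(v)) -v else 1e10
      }
    }
    st2 <- c(par[1L],
             if (!is.null(hint) && all(is.finite(hint))) hint[length(hint)]
             else if (which == "alpha") par[3L] else par[2L])
    if (length(hint) == 2L && all(is.finite(hint))) st2 <- hint
    if (obj(st2) >= 1e10) return(-Inf)
    o <- stats::optim(st2, obj, method = "BFGS",
                      control = list(reltol = 1e-11, maxit = 300))
    list(ll = -o$value, par = o$par)
  }
  res <- structure(list(
    alpha_hat = par[2L], beta_hat = par[3L], kappa_hat = par[1L],
    ci_alpha = c(NA_real_, NA_real_), ci_beta = c(NA_real_, NA_real_),
    loglik_max = llmax, converged = converged, method_tag = "mcml",
    level = level,
    profile = function(alpha, beta) profile_fixed("alpha", alpha)$ll,
    profile_fixed = profile_fixed
  ), class = "fit_result")
  if (compute_ci && converged) {
    res$ci_alpha <- mcml_profile_ci(res, "alpha", level)
    res$ci_beta <- mcml_profile_ci(res, "beta", level)
  }
  res
}

# warm-started outward walk + bisection on the averaged-likelihood profile;
# each step reuses the previous step's inner optimum so the profile tracks
# the branch connected to the reported mode
mcml_profile_ci <- function(fit, which, level = 0.95) {
  thresh <- stats::qchisq(level, df = 1)
  mle <- if (which == "alpha") fit$alpha_hat else fit$beta_hat
  bound <- function(dir) {
    step <- 0.25 * max(1, abs(mle))
    x_in <- mle
    warm <- NULL
    for (i in 1:60) {
      x <- x_in + dir * step
      pr <- fit$profile_fixed(which, x, hint = warm)
      d <- if (is.list(pr)) 2 * (fit$loglik_max - pr$ll) else Inf
      if (!is.finite(d) || d >= thresh) {
        lo <- x_in; hi <- x
        warm_b <- warm
        for (j in 1:50) {
          mid <- (lo + hi) / 2
          pm <- fit$profile_fixed(which, mid, hint = warm_b)
          dm <- if (is.list(pm)) 2 * (fit$loglik_max - pm$ll) else Inf
          if (is.finite(dm) && dm < thresh) {
            lo <- mid
            if (is.list(pm)) warm_b <- pm$par
          } else hi <- mid
          if (is.finite(dm) && abs(dm - thresh) < 1e-4) return(mid)
        }
        return((lo + hi) / 2)
      }
      x_in <- x
      warm <- pr$par
      step <- step * 1.6
    }
    dir * Inf
  }
  c(bound(-1), bound(+1))
}

#' Read a group-dose ensemble from a delimited matrix file
#'
#' Expects a header row and one row per group; columns after the first
#' (`group`) are realizations.
#'
#' @param path file path.
#' @return Numeric K x R matrix.
#' @export
read_group_dose_ensemble <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "")
  as.matrix(tab[order(tab[[1L]]), -1L, drop = FALSE])
}

#' @rdname read_group_dose_ensemble
#' @param dose_ens K x R matrix to write.
#' @export
write_group_dose_ensemble <- function(dose_ens, path) {
  out <- cbind(group = seq_len(nrow(dose_ens)), dose_ens)
  colnames(out) <- c("group", paste0("realization_", seq_len(ncol(dose_ens))))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
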