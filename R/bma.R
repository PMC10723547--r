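#' MCMC settings for the 2DMC-with-BMA sampler
#'
#' Defaults follow the study protocol: independent normal priors with mean 0
#' and SD 1000 on alpha, beta, kappa and every lambda; symmetric normal
#' proposals with SD 0.2 for kappa, 1 for alpha and beta, and 2 for the
#' lambdas; lambdas proposed in blocks of 10 with a joint accept/reject;
#' two chains; 1000 burn-in sweeps discarded and 1000 further sweeps kept.
#'
#' @param prior_sd prior SD for all parameters.
#' @param proposal_sd_kappa,proposal_sd_alpha_beta,proposal_sd_lambda
#'   proposal SDs.
#' @param lambda_block block size for joint lambda updates (the final block
#'   may be shorter).
#' @param n_chains number of independently initialized chains.
#' @param burn_in,keep discarded and retained sweeps per chain.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(prior_sd = 1000, proposal_sd_kappa = 0.2,
                          proposal_sd_alpha_beta = 1,
                          proposal_sd_lambda = 2, lambda_block = 10,
                          n_chains = 2, burn_in = 1000, keep = 1000) {
  s <- list(prior_sd = prior_sd, proposal_sd_kappa = proposal_sd_kappa,
            proposal_sd_alpha_beta = proposal_sd_alpha_beta,
            proposal_sd_lambda = proposal_sd_lambda,
            lambda_block = as.integer(lambda_block),
            n_chains = as.integer(n_chains),
            burn_in = as.integer(burn_in), keep = as.integer(keep))
  if (any(unlist(s[1:5]) <= 0) || s$n_chains < 1L || s$burn_in < 0L ||
      s$keep < 1L)
    stop("invalid MCMC settings")
  structure(s, class = "mcmc_settings")
}

#' Scenario probabilities from softmax weights
#'
#' Maps the `R - 1` free weights `lambda` to a probability vector of length
#' `R` by the reference-category softmax: `p_j = exp(lambda_j) / (1 +
#' sum(exp(lambda)))` for `j < R` and `p_R = 1 / (1 + sum(exp(lambda)))`,
#' stabilized by max-subtraction.
#'
#' @param lambdas numeric vector of finite weights (length `R - 1`).
#' @return Probability vector of length `R` summing to 1.
#' @examples
#' scenario_probabilities(c(log(2), 0, 0))
#' @export
scenario_probabilities <- function(lambdas) {
  if (any(!is.finite(lambdas))) stop("lambdas must be finite")
  lp <- c(lambdas, 0)
  m <- max(lp)
  e <- exp(lp - m)
  e / sum(e)
}

# normalized log scenario probabilities
scenario_log_probabilities <- function(lambdas) {
  lp <- c(lambdas, 0)
  lp - log_sum_exp(lp)
}

# Per-scenario Poisson log-likelihood engine for a dose-scenario ensemble.
# Units are individuals (offsets 1) or groups (offsets = person counts):
#   ll_j(kappa) = kappa*C + A_j(alpha, beta) - exp(kappa)*S_j(alpha, beta)
# with A_j = sum_i c_i log(n_i f(D_ij)), S_j = sum_i n_i f(D_ij),
# f(D) = 1 + alpha D + beta D^2, plus the -sum(log c_i!) constant.
# Feasibility (f > 0 for every unit) is checked from each scenario's dose
# range and the parabola vertex, so it never touches the full dose matrix.
make_scenario_engine <- function(cases, dose_ensemble, offsets = NULL) {
  d <- as.matrix(dose_ensemble)
  n_unit <- nrow(d)
  stopifnot(length(cases) == n_unit)
  if (is.null(offsets)) offsets <- rep(1, n_unit)
  stopifnot(length(offsets) == n_unit, all(offsets > 0))
  idx <- which(cases > 0)
  cw <- cases[idx]
  dc <- d[idx, , drop = FALSE]
  dc2 <- dc^2
  t0 <- sum(offsets)
  t1 <- colSums(offsets * d)
  t2 <- colSums(offsets * d^2)
  dmin <- apply(d, 2L, min)
  dmax <- apply(d, 2L, max)
  const <- sum(cw * log(offsets[idx])) - sum(lfactorial(cases))
  ctot <- sum(cases)
  feasible <- function(alpha, beta) {
    ok <- (1 + alpha * dmin + beta * dmin^2 > 0) &
      (1 + alpha * dmax + beta * dmax^2 > 0)
    if (beta > 0) {
      v <- -alpha / (2 * beta)
      ok <- ok & !(v > dmin & v < dmax & (1 - alpha^2 / (4 * beta)) <= 0)
    }
    ok
  }
  list(
    n_scen = ncol(d),
    ctot = ctot,
    # A_j and S_j at (alpha, beta); A_j = -Inf flags infeasible scenarios
    pieces = function(alpha, beta) {
      ok <- feasible(alpha, beta)
      f <- 1 + alpha * dc + beta * dc2
      f[f <= 0] <- NA_real_
      a <- colSums(cw * log(f)) + const
      s <- t0 + alpha * t1 + beta * t2
      a[!ok | is.na(a)] <- -Inf
      s[!ok] <- 1
      list(a = a, s = s)
    },
    ll = function(pc, kappa) {
      out <- kappa * ctot + pc$a - exp(kappa) * pc$s
      out[!is.finite(pc$a)] <- -Inf
      out
    },
    kappa0 = log(max(ctot, 1) / t0)
  )
}

#' Log posterior density of the 2DMC-with-BMA model
#'
#' The likelihood mixes at the whole-dataset level — exactly one scenario
#' (dose realization) is assumed correct — so it is `sum_j p_j(lambda) *
#' L_j(alpha, beta, kappa)` with `L_j` the Poisson likelihood of the
#' observed case counts under scenario j's doses. The data are not
#' collapsed for this method: with per-individual cases and an
#' individual-by-scenario dose matrix the component likelihoods are
#' individual-level (offsets 1); supplying grouped counts, a group-level
#' dose matrix and person-count `offsets` gives the grouped equivalent.
#' The log posterior adds the normal prior log-densities of alpha, beta,
#' kappa and every lambda. Unlike the frequentist fits, kappa is a free
#' parameter here.
#'
#' @param params a [risk_parameters()] object.
#' @param lambdas softmax weights, length `ncol(dose_ensemble) - 1`.
#' @param cases case counts per unit (individual or group).
#' @param dose_ensemble units x scenarios dose matrix (Gy).
#' @param offsets optional per-unit offsets (person counts for grouped
#'   units; default 1).
#' @param prior_sd normal prior SD (default 1000).
#' @return Log posterior density (`-Inf` if every scenario is infeasible).
#' @export
posterior_log_density <- function(params, lambdas, cases, dose_ensemble,
                                  offsets = NULL, prior_sd = 1000) {
  stopifnot(inherits(params, "risk_parameters"))
  eng <- make_scenario_engine(cases, dose_ensemble, offsets)
  stopifnot(length(lambdas) == eng$n_scen - 1L)
  ll <- eng$ll(eng$pieces(params$alpha, params$beta), params$kappa)
  lp <- scenario_log_probabilities(lambdas)
  mix <- log_sum_exp(lp + ll)
  pri <- sum(stats::dnorm(c(params$alpha, params$beta, params$kappa,
                            lambdas), 0, prior_sd, log = TRUE))
  mix + pri
}

#' Blocked Metropolis-Hastings sampler for the 2DMC-with-BMA posterior
#'
#' Each sweep updates kappa, alpha and beta singly and the lambdas in blocks
#' (joint accept/reject per block), all via symmetric normal proposals.
#' Chain 1 starts at `(alpha, beta, kappa, lambda) = (0.1, 1, data-implied
#' kappa, 0)`; further chains are overdispersed by +1 on alpha, beta and
#' kappa. Per-scenario log-likelihood pieces are cached between lambda
#' updates, which only move the softmax weights.
#'
#' @param settings an [mcmc_settings()].
#' @param cases case counts per unit (see [posterior_log_density()]).
#' @param dose_ensemble units x scenarios dose matrix.
#' @param offsets optional per-unit offsets.
#' @param seed optional integer seed (one child stream per chain).
#' @return An object of class `bma_chains`: list with `draws` (array
#'   `keep x n_chains x 3` for alpha, beta, kappa), `acceptance` (named
#'   rates), `scenario_weight_mean` (posterior-mean scenario probabilities
#'   over retained sweeps), and the settings.
#' @export
mh_sample <- function(settings, cases, dose_ensemble, offsets = NULL,
                      seed = NULL) {
  stopifnot(inherits(settings, "mcmc_settings"))
  eng <- make_scenario_engine(cases, dose_ensemble, offsets)
  n_lam <- eng$n_scen - 1L
  blocks <- if (n_lam > 0L)
    split(seq_len(n_lam), ceiling(seq_len(n_lam) / settings$lambda_block))
  else list()
  n_iter <- settings$burn_in + settings$keep
  draws <- array(NA_real_, c(settings$keep, settings$n_chains, 3L),
                 dimnames = list(NULL, NULL, c("alpha", "beta", "kappa")))
  acc <- c(alpha = 0, beta = 0, kappa = 0, lambda = 0)
  att <- c(alpha = 0, beta = 0, kappa = 0, lambda = 0)
  pmean <- numeric(eng$n_scen)
  pmean_n <- 0L
  psd <- settings$prior_sd

  run_chain <- function(chain_id, chain_seed) {
    with_stream_seed(chain_seed, {
      a <- 0.1 + (chain_id - 1)
      b <- 1 + (chain_id - 1)
      k <- eng$kappa0 + (chain_id - 1)
      lam <- numeric(n_lam)
      pc <- eng$pieces(a, b)
      ll <- eng$ll(pc, k)
      lp <- scenario_log_probabilities(lam)
      mix <- log_sum_exp(lp + ll)
      lpri_main <- stats::dnorm(c(a, b, k), 0, psd, log = TRUE)
      lpri_lam <- stats::dnorm(lam, 0, psd, log = TRUE)
      for (it in seq_len(n_iter)) {
        # kappa
        k_new <- k + stats::rnorm(1L, 0, settings$proposal_sd_kappa)
        ll_new <- eng$ll(pc, k_new)
        mix_new <- log_sum_exp(lp + ll_new)
        lpri_new <- stats::dnorm(k_new, 0, psd, log = TRUE)
        att["kappa"] <<- att["kappa"] + 1
        if (is.finite(mix_new) &&
            log(stats::runif(1L)) < (mix_new + lpri_new) -
            (mix + lpri_main[3L])) {
          k <- k_new; ll <- ll_new; mix <- mix_new; lpri_main[3L] <- lpri_new
          acc["kappa"] <<- acc["kappa"] + 1
        }
        # alpha
        a_new <- a + stats::rnorm(1L, 0, settings$proposal_sd_alpha_beta)
        pc_new <- eng$pieces(a_new, b)
        ll_new <- eng$ll(pc_new, k)
        mix_new <- log_sum_exp(lp + ll_new)
        lpri_new <- stats::dnorm(a_new, 0, psd, log = TRUE)
        att["alpha"] <<- att["alpha"] + 1
        if (is.finite(mix_new) &&
            log(stats::runif(1L)) < (mix_new + lpri_new) -
            (mix + lpri_main[1L])) {
          a <- a_new; pc <- pc_new; ll <- ll_new; mix <- mix_new
          lpri_main[1L] <- lpri_new
          acc["alpha"] <<- acc["alpha"] + 1
        }
        # beta
        b_new <- b + stats::rnorm(1L, 0, settings$proposal_sd_alpha_beta)
        pc_new <- eng$pieces(a, b_new)
        ll_new <- eng$ll(pc_new, k)
        mix_new <- log_sum_exp(lp + ll_new)
        lpri_new <- stats::dnorm(b_new, 0, psd, log = TRUE)
        att["beta"] <<- att["beta"] + 1
        if (is.finite(mix_new) &&
            log(stats::runif(1L)) < (mix_new + lpri_new) -
            (mix + lpri_main[2L])) {
          b <- b_new; pc <- pc_new; ll <- ll_new; mix <- mix_new
          lpri_main[2L] <- lpri_new
          acc["beta"] <<- acc["beta"] + 1
        }
        # lambda blocks (joint accept/reject per block)
        for (blk in blocks) {
          lam_new <- lam
          lam_new[blk] <- lam[blk] +
            stats::rnorm(length(blk), 0, settings$proposal_sd_lambda)
          lp_new <- scenario_log_probabilities(lam_new)
          mix_new <- log_sum_exp(lp_new + ll)
          dpri <- sum(stats::dnorm(lam_new[blk], 0, psd, log = TRUE)) -
            sum(lpri_lam[blk])
          att["lambda"] <<- att["lambda"] + 1
          if (is.finite(mix_new) &&
              log(stats::runif(1L)) < (mix_new - mix) + dpri) {
            lam <- lam_new; lp <- lp_new; mix <- mix_new
            lpri_lam[blk] <- stats::dnorm(lam[blk], 0, psd, log = TRUE)
            acc["lambda"] <<- acc["lambda"] + 1
          }
        }
        if (it > settings$burn_in) {
          j <- it - settings$burn_in
          draws[j, chain_id, ] <<- c(a, b, k)
          pmean <<- pmean + exp(lp)
          pmean_n <<- pmean_n + 1L
        }
      }
    })
    invisible(NULL)
  }

  for (ch in seq_len(settings$n_chains)) {
    run_chain(ch, if (is.null(seed)) NULL else stream_seed(seed, "chain", ch))
  }
  structure(list(draws = draws,
                 acceptance = acc / pmax(att, 1),
                 scenario_weight_mean = pmean / max(pmean_n, 1L),
                 settings = settings),
            class = "bma_chains")
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' The classic PSRF from between- and within-chain variances of retained
#' draws: with m chains of length n, `W` the mean within-chain variance and
#' `B/n` the variance of the chain means, the estimate is
#' `sqrt(((n-1)/n * W + (1 + 1/m) * B/n) / W)`. Values near 1 are consistent
#' with convergence; two identical chains give `sqrt((n-1)/n) < 1`.
#'
#' @param chains numeric matrix, iterations x chains, for one scalar
#'   parameter; or a `bma_chains` object (then one value per main
#'   parameter).
#' @return PSRF value(s); `NA` with a warning if the within-chain variance
#'   is zero.
#' @export
bgr_statistic <- function(chains) {
  if (inherits(chains, "bma_chains")) {
    return(vapply(dimnames(chains$draws)[[3L]], function(p)
      bgr_statistic(chains$draws[, , p, drop = TRUE]), numeric(1)))
  }
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2L || n < 2L) stop("need >= 2 chains of length >= 2")
  w <- mean(apply(chains, 2L, stats::var))
  if (!is.finite(w) || w == 0) {
    warning("zero within-chain variance; BGR undefined")
    return(NA_real_)
  }
  b_over_n <- stats::var(colMeans(chains))
  vhat <- (n - 1) / n * w + (1 + 1 / m) * b_over_n
  sqrt(vhat / w)
}

#' Posterior summary of the 2DMC-with-BMA chains
#'
#' Pools the retained draws of all chains and reports the posterior mean and
#' equal-tailed 95\% credible interval (2.5 and 97.5 percentiles) for alpha
#' and beta, together with acceptance rates and the per-parameter BGR
#' statistic. Coverage bookkeeping in the experiment runner uses these
#' intervals.
#'
#' @param chains a `bma_chains` object from [mh_sample()].
#' @param level credible level (default 0.95).
#' @return An object of class `posterior_summary`.
#' @export
summarize_posterior <- function(chains, level = 0.95) {
  stopifnot(inherits(chains, "bma_chains"))
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  pool <- function(p) as.numeric(chains$draws[, , p])
  summ <- function(x) c(mean = mean(x), stats::quantile(x, qs))
  a <- summ(pool("alpha")); b <- summ(pool("beta"))
  bgr <- if (dim(chains$draws)[2L] >= 2L) bgr_statistic(chains) else
    c(alpha = NA_real_, beta = NA_real_, kappa = NA_real_)
  structure(list(
    alpha_mean = a[[1L]], ci_alpha = c(a[[2L]], a[[3L]]),
    beta_mean = b[[1L]], ci_beta = c(b[[2L]], b[[3L]]),
    kappa_mean = mean(pool("kappa")),
    acceptance = chains$acceptance,
    bgr = bgr,
    level = level
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("2DMC-with-BMA posterior summary\n")
  cat(sprintf("  alpha: mean %.4g, %g%% CrI [%.4g, %.4g]\n", x$alpha_mean,
              100 * x$level, x$ci_alpha[1], x$ci_alpha[2]))
  cat(sprintf("  beta : mean %.4g, %g%% CrI [%.4g, %.4g]\n", x$beta_mean,
              100 * x$level, x$ci_beta[1], x$ci_beta[2]))
  cat("  acceptance:", paste(sprintf("%s %.0f%%", names(x$acceptance),
                                     100 * x$acceptance), collapse = ", "),
      "\n")
  cat("  BGR:", paste(sprintf("%s %.3f", names(x$bgr), x$bgr),
                      collapse = ", "), "\n")
  invisible(x)
}

#' Fit one replication by 2DMC with BMA
#'
#' Runs [mh_sample()] on the case counts and the dose-scenario ensemble,
#' then summarizes the posterior. The result mirrors a `fit_result`:
#' posterior means as point estimates and equal-tailed credible intervals in
#' the `ci_*` slots.
#'
#' @param cases case counts per unit (individual-level by default; see
#'   [posterior_log_density()]).
#' @param dose_ensemble units x scenarios dose matrix.
#' @param offsets optional per-unit offsets.
#' @param settings an [mcmc_settings()] (defaults as in the protocol).
#' @param seed optional integer seed.
#' @param level credible level.
#' @return A `fit_result` with `method_tag = "bma"` and extra elements
#'   `summary` (the [summarize_posterior()] output) and `chains`.
#' @export
fit_bma <- function(cases, dose_ensemble, offsets = NULL,
                    settings = mcmc_settings(), seed = NULL, level = 0.95) {
  chains <- mh_sample(settings, cases, dose_ensemble, offsets, seed = seed)
  s <- summarize_posterior(chains, level = level)
  structure(list(
    alpha_hat = s$alpha_mean, beta_hat = s$beta_mean,
    kappa_hat = s$kappa_mean,
    ci_alpha = s$ci_alpha, ci_beta = s$ci_beta,
    loglik_max = NA_real_, converged = TRUE,
    method_tag = "bma", level = level,
    summary = s, chains = chains
  ), class = "fit_result")
}

#' Export retained MCMC draws as a delimited table
#'
#' Columns: iteration, chain, alpha, beta, kappa.
#'
#' @param chains a `bma_chains` object.
#' @param path output file path.
#' @export
write_chain_draws <- function(chains, path) {
  stopifnot(inherits(chains, "bma_chains"))
  d <- chains$draws
  out <- do.call(rbind, lapply(seq_len(dim(d)[2L]), function(ch) {
    data.frame(iteration = seq_len(dim(d)[1L]), chain = ch,
               alpha = d[, ch, "alpha"], beta = d[, ch, "beta"],
               kappa = d[, ch, "kappa"])
  }))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
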