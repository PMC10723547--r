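test_that("softmax scenario probabilities behave as the reference-category map", {
  expect_equal(scenario_probabilities(numeric(999)), rep(1 / 1000, 1000))
  p <- scenario_probabilities(c(log(2), numeric(998)))
  expect_equal(p[1], 2 / 1001)
  expect_equal(p[2], 1 / 1001)
  expect_equal(p[1000], 1 / 1001)
  set.seed(2)
  for (lam in list(rnorm(9, 0, 3), rnorm(49, 0, 10), 500 + rnorm(5))) {
    pr <- scenario_probabilities(lam)
    expect_equal(sum(pr), 1)
    expect_true(all(pr > 0))
  }
  expect_error(scenario_probabilities(c(1, Inf)), "finite")
})

test_that("posterior log density reduces to likelihood plus priors for one scenario", {
  gd <- noiseless_grouped()
  pr <- risk_parameters(0.2, 1.8, log(250 / 4315))
  lp <- posterior_log_density(pr, numeric(0), gd$cases,
                              matrix(gd$dose, ncol = 1),
                              offsets = gd$persons)
  expect_equal(lp, log_likelihood(gd, pr) +
                 sum(stats::dnorm(c(0.2, 1.8, log(250 / 4315)), 0, 1000,
                                  log = TRUE)))

  # identical scenarios with any weights: likelihood term unchanged
  lam <- c(0.7, -0.3)
  lp3 <- posterior_log_density(pr, lam, gd$cases,
                               matrix(gd$dose, 5, 3), offsets = gd$persons)
  expect_equal(lp3, log_likelihood(gd, pr) +
                 sum(stats::dnorm(c(0.2, 1.8, log(250 / 4315), lam), 0, 1000,
                                  log = TRUE)))
})

test_that("posterior log density matches naive mixture summation on a toy", {
  gd <- noiseless_grouped()
  set.seed(6)
  ens <- gd$dose * matrix(exp(rnorm(15, 0, 0.15)), 5, 3)
  lam <- c(0.5, -0.2)
  pr <- risk_parameters(0.22, 1.9, log(250 / 4315))
  w <- scenario_probabilities(lam)
  naive <- log(sum(w * vapply(1:3, function(j)
    exp(log_likelihood(grouped_data(default_cohort(), gd$cases, ens[, j]),
                       pr)), numeric(1)))) +
    sum(stats::dnorm(c(0.22, 1.9, log(250 / 4315), lam), 0, 1000, log = TRUE))
  expect_equal(posterior_log_density(pr, lam, gd$cases, ens,
                                     offsets = gd$persons),
               naive, tolerance = 1e-10)
})

test_that("the sampler recovers a quadrature oracle on a single-scenario posterior", {
  # grouped dataset, one scenario: the posterior over (alpha, beta, kappa)
  # is integrated on a dense grid (the SD-1000 prior is flat over the
  # integration box) and compared with the MCMC moments
  gd <- grouped_data(default_cohort(), c(151L, 20L, 41L, 35L, 3L),
                     default_cohort()$central_dose)
  ch <- mh_sample(mcmc_settings(burn_in = 2000, keep = 8000), gd$cases,
                  matrix(gd$dose, ncol = 1), offsets = gd$persons, seed = 5)
  a_draws <- as.numeric(ch$draws[, , "alpha"])
  b_draws <- as.numeric(ch$draws[, , "beta"])

  grid_a <- seq(-3, 6, length.out = 120)
  grid_b <- seq(-2, 8, length.out = 120)
  grid_k <- seq(-3.6, -2.2, length.out = 120)
  n <- gd$persons; cs <- gd$cases; D <- gd$dose
  lw <- array(-Inf, c(120, 120, 120))
  for (i in 1:120) for (j in 1:120) {
    f <- 1 + grid_a[i] * D + grid_b[j] * D^2
    if (any(f <= 0)) next
    lw[i, j, ] <- grid_k * sum(cs) + sum(cs * log(n * f)) -
      exp(grid_k) * sum(n * f)
  }
  dens <- exp(lw - max(lw))
  w <- sum(dens)
  mean_a <- sum(apply(dens, 1, sum) * grid_a) / w
  mean_b <- sum(apply(dens, 2, sum) * grid_b) / w
  expect_lt(abs(mean(a_draws) - mean_a), 0.15)
  expect_lt(abs(mean(b_draws) - mean_b), 0.15)
})

test_that("scenario weights concentrate on the case-generating dose vector", {
  design <- default_cohort()
  gi <- group_index(design)
  err <- error_model(sigma_share_berkson = 0.4,
                     sigma_unshare_berkson = 0.3)
  ens <- simulate_true_doses(design, err, 3, seed = 44)
  cp <- case_probabilities(ens$true_doses[, 1L], 0.25, 2)
  cases <- allocate_cases(cp$probabilities, 250, seed = 44)
  ch <- mh_sample(mcmc_settings(burn_in = 500, keep = 500), cases,
                  ens$true_doses, seed = 45)
  expect_gt(ch$scenario_weight_mean[1L], 1 / 3)
  expect_equal(sum(ch$scenario_weight_mean), 1, tolerance = 1e-8)
})

test_that("BGR statistic matches its defining formula and edge cases", {
  x <- c(1.2, 0.8, 1.1, 0.9, 1.0)
  expect_equal(bgr_statistic(cbind(x, x)), sqrt(4 / 5))

  # hand evaluation on two length-5 chains
  c1 <- c(0.1, 0.3, 0.2, 0.4, 0.25)
  c2 <- c(0.5, 0.6, 0.4, 0.55, 0.45)
  n <- 5; m <- 2
  w <- (stats::var(c1) + stats::var(c2)) / 2
  b_over_n <- stats::var(c(mean(c1), mean(c2)))
  by_hand <- sqrt(((n - 1) / n * w + (1 + 1 / m) * b_over_n) / w)
  expect_equal(bgr_statistic(cbind(c1, c2)), by_hand)

  expect_warning(r <- bgr_statistic(cbind(rep(1, 5), rep(1, 5))), "variance")
  expect_true(is.na(r))
  expect_error(bgr_statistic(matrix(1:5, ncol = 1)), "chains")
})

test_that("posterior summaries use pooled equal-tailed quantiles", {
  set.seed(10)
  ch <- structure(list(
    draws = array(rnorm(100 * 2 * 3), c(100, 2, 3),
                  dimnames = list(NULL, NULL, c("alpha", "beta", "kappa"))),
    acceptance = c(alpha = 0.3, beta = 0.3, kappa = 0.3, lambda = 0.5),
    scenario_weight_mean = 1,
    settings = mcmc_settings()), class = "bma_chains")
  s <- summarize_posterior(ch)
  pooled <- as.numeric(ch$draws[, , "alpha"])
  # sorting oracle for the type-7 quantile on 200 draws
  srt <- sort(pooled)
  q_oracle <- function(p) {
    h <- (length(srt) - 1) * p + 1
    srt[floor(h)] + (h - floor(h)) * (srt[floor(h) + 1] - srt[floor(h)])
  }
  expect_equal(s$ci_alpha, c(q_oracle(0.025), q_oracle(0.975)))
  expect_equal(s$alpha_mean, mean(pooled))
  expect_true(all(s$acceptance >= 0 & s$acceptance <= 1))

  # constant draws: zero-width interval at the constant
  chc <- ch
  chc$draws[] <- 0.7
  sc <- suppressWarnings(summarize_posterior(chc))
  expect_equal(sc$ci_beta, c(0.7, 0.7))
})

test_that("single-scenario posterior mode sits near the MLE under flat priors", {
  gd <- noiseless_grouped()
  fit <- fit_ml(gd, compute_ci = FALSE)
  ch <- mh_sample(mcmc_settings(burn_in = 2000, keep = 6000), gd$cases,
                  matrix(gd$dose, ncol = 1), offsets = gd$persons, seed = 3)
  a <- as.numeric(ch$draws[, , "alpha"])
  b <- as.numeric(ch$draws[, , "beta"])
  # kernel mode of the alpha draws vs the MLE (posterior is skewed, so the
  # mode, not the mean, is the right comparison)
  da <- stats::density(a)
  db <- stats::density(b)
  expect_lt(abs(da$x[which.max(da$y)] - fit$alpha_hat), 0.35)
  expect_lt(abs(db$x[which.max(db$y)] - fit$beta_hat), 0.5)
  expect_true(all(bgr_statistic(ch) < 1.2))
})

test_that("chain draws export to a delimited table", {
  gd <- noiseless_grouped()
  ch <- mh_sample(mcmc_settings(burn_in = 10, keep = 20), gd$cases,
                  matrix(gd$dose, ncol = 1), offsets = gd$persons, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chain_draws(ch, path)
  back <- utils::read.table(path, header = TRUE)
  expect_equal(nrow(back), 40L)
  expect_equal(sort(unique(back$chain)), c(1L, 2L))
})
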