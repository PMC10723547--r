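#' Scenario specification for the simulation study
#'
#' Bundles one error-model setting with the study sizes: number of
#' replications (dose+cancer ensembles), dose realizations per replication,
#' cases per replication, true risk coefficients, methods to run, and the
#' master seed. Defaults are the study conditions: 500 replications, 1000
#' realizations, 250 cases, alpha 0.25/Gy, beta 2/Gy^2.
#'
#' @param err an [error_model()].
#' @param n_replications number of dose+cancer replications.
#' @param n_realizations dose realizations per replication.
#' @param n_cases cases per replication.
#' @param alpha_true,beta_true generating risk coefficients.
#' @param methods character vector of method tags to run; any of
#'   `"unadjusted"`, `"regcal"`, `"mcml"`, `"bma"`, or a tag registered via
#'   [register_fit_method()].
#' @param seed master seed; per-replication, per-stream child seeds are
#'   derived with [stream_seed()].
#' @param design a [cohort_design()] (default [default_cohort()]).
#' @param mcmc an [mcmc_settings()] for the BMA method.
#' @param level confidence/credible level.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(err, n_replications = 500, n_realizations = 1000,
                          n_cases = 250, alpha_true = 0.25, beta_true = 2,
                          methods = c("unadjusted", "regcal"),
                          seed = 1, design = default_cohort(),
                          mcmc = mcmc_settings(), level = 0.95) {
  stopifnot(inherits(err, "error_model"), n_replications >= 1,
            n_realizations >= 1, n_cases >= 0)
  structure(list(err = err, n_replications = as.integer(n_replications),
                 n_realizations = as.integer(n_realizations),
                 n_cases = as.integer(n_cases), alpha_true = alpha_true,
                 beta_true = beta_true, methods = methods,
                 seed = as.integer(seed), design = design, mcmc = mcmc,
                 level = level),
            class = "scenario_spec")
}

#' Simulate one dose+cancer replication
#'
#' Draws the true-dose ensemble, one surrogate-dose vector and the case
#' counts for replication `rep` of a scenario, with independently seeded
#' streams for the Berkson draws, the classical draws and the outcome
#' sampling. Realization 1 of the true-dose ensemble is the designated
#' "actual truth" that generates the cases; the full ensemble (including
#' realization 1) is the dosimetry ensemble handed to MCML and BMA.
#'
#' @param spec a [scenario_spec()].
#' @param rep replication index (1-based).
#' @return List with `ensemble` (a `dose_ensemble` with surrogate filled),
#'   `cases` (per-individual counts), `grouped_cases` (per-group sums) and
#'   `kappa` (the normalizing constant of the case probabilities).
#' @export
simulate_replication <- function(spec, rep = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  rep_seed <- stream_seed(spec$seed, "replication", rep)
  ens <- simulate_true_doses(spec$design, spec$err, spec$n_realizations,
                             seed = rep_seed)
  ens$surrogate_doses <- simulate_surrogate_doses(spec$design, spec$err,
                                                  seed = rep_seed)
  truth <- ens$true_doses[, 1L]
  cp <- case_probabilities(truth, spec$alpha_true, spec$beta_true)
  cases <- allocate_cases(cp$probabilities, spec$n_cases, seed = rep_seed)
  grouped_cases <- as.integer(rowsum(as.numeric(cases), ens$group_index,
                                     reorder = TRUE))
  list(ensemble = ens, cases = cases, grouped_cases = grouped_cases,
       kappa = cp$kappa)
}

# ---- method registry -------------------------------------------------------

.method_registry <- new.env(parent = emptyenv())

#' Register a fitting method with the experiment runner
#'
#' A method is a function `fn(ensemble, cases, design, spec)` returning a
#' `fit_result`. The built-in tags `unadjusted`, `regcal`, `mcml` and `bma`
#' are pre-registered; an `erc` (extended regression calibration) slot is
#' reserved for an external likelihood-adjusted implementation and errors
#' until one is registered.
#'
#' @param name method tag.
#' @param fn fitting function.
#' @export
register_fit_method <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .method_registry)
  invisible(name)
}

get_fit_method <- function(name) {
  if (!exists(name, envir = .method_registry))
    stop("no fitting method registered under tag '", name,
         "' (use register_fit_method())")
  get(name, envir = .method_registry)
}

register_builtin_methods <- function() {
  register_fit_method("unadjusted", function(ensemble, cases, design, spec)
    fit_unadjusted(ensemble, cases, design, level = spec$level))
  register_fit_method("regcal", function(ensemble, cases, design, spec)
    fit_regcal(ensemble, cases, design, level = spec$level))
  register_fit_method("mcml", function(ensemble, cases, design, spec) {
    gens <- group_mean_doses(ensemble$true_doses, ensemble$group_index)
    gcases <- as.integer(rowsum(as.numeric(cases), ensemble$group_index,
                                reorder = TRUE))
    fit_mcml(gcases, gens, design$persons, level = spec$level)
  })
  register_fit_method("bma", function(ensemble, cases, design, spec) {
    # data are not collapsed for this method: individual-level likelihood
    rep_seed <- attr(ensemble, "rep_seed")
    fit_bma(cases, ensemble$true_doses, settings = spec$mcmc,
            seed = rep_seed, level = spec$level)
  })
}

# ---- metrics ---------------------------------------------------------------

#' Empirical coverage of a set of intervals
#'
#' @param intervals list of numeric `c(lower, upper)` pairs (closed
#'   intervals; infinite bounds allowed).
#' @param truth true parameter value.
#' @return Percentage (0-100) of intervals containing `truth`; endpoints
#'   count as covered.
#' @examples
#' coverage(list(c(0, 1), c(2, 3)), 0.5)
#' @export
coverage <- function(intervals, truth) {
  if (length(intervals) == 0L) stop("no intervals supplied")
  hit <- vapply(intervals, function(ci)
    !any(is.na(ci)) && ci[1L] <= truth && truth <= ci[2L], logical(1))
  100 * mean(hit)
}

#' Percentage bias in predicted relative risk
#'
#' `100 * [(1 + a*D + b*D^2) / (1 + a0*D + b0*D^2) - 1]`, the percentage by
#' which the relative risk predicted from mean fitted coefficients `(a, b)`
#' at dose `D` deviates from the truth `(a0, b0)`.
#'
#' @param alpha_mean,beta_mean mean fitted coefficients.
#' @param d_pred prediction dose in Gy (the study reports 0.1 and 1 Gy).
#' @param alpha_true,beta_true true coefficients (default 0.25, 2).
#' @return Percentage bias.
#' @examples
#' rr_bias(0.196, 2.061, 0.1)
#' @export
rr_bias <- function(alpha_mean, beta_mean, d_pred,
                    alpha_true = 0.25, beta_true = 2) {
  num <- 1 + alpha_mean * d_pred + beta_mean * d_pred^2
  den <- 1 + alpha_true * d_pred + beta_true * d_pred^2
  if (num <= 0 || den <= 0)
    stop("relative-risk factor must be positive at the prediction dose")
  100 * (num / den - 1)
}

# ---- scenario execution ----------------------------------------------------

#' Run one error scenario of the simulation study
#'
#' For each replication: simulates the dose ensemble, surrogate vector and
#' cases, runs every requested method, and accumulates point estimates and
#' interval-coverage indicators. Replications whose fit fails or does not
#' converge are excluded from that method's summaries and counted in
#' `n_failed` (never silently dropped).
#'
#' @param spec a [scenario_spec()].
#' @param d_pred prediction doses (Gy) for the relative-risk bias columns.
#' @param verbose print per-replication progress.
#' @return An `evaluation_report`: a data frame with one row per method and
#'   columns for the four GSDs, coverage of alpha and beta (%), mean and SD of the
#'   coefficients, RR bias at each prediction dose, the same-group
#'   true-dose correlation of the first replication's ensemble, counts of
#'   used/failed replications, and the scenario sizes.
#' @export
run_scenario <- function(spec, d_pred = c(0.1, 1), verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  methods <- spec$methods
  fns <- lapply(methods, get_fit_method)
  names(fns) <- methods
  rec <- lapply(methods, function(m)
    list(alpha = numeric(0), beta = numeric(0),
         cov_a = logical(0), cov_b = logical(0), failed = 0L))
  names(rec) <- methods
  corr <- NA_real_
  for (r in seq_len(spec$n_replications)) {
    sim <- simulate_replication(spec, r)
    attr(sim$ensemble, "rep_seed") <- stream_seed(spec$seed, "replication", r)
    if (r == 1L) {
      corr <- tryCatch(
        suppressWarnings(shared_dose_correlation(sim$ensemble)),
        error = function(e) NA_real_)
    }
    for (m in methods) {
      fit <- tryCatch(fns[[m]](sim$ensemble, sim$cases, spec$design, spec),
                      error = function(e) NULL)
      if (is.null(fit) || !isTRUE(fit$converged)) {
        rec[[m]]$failed <- rec[[m]]$failed + 1L
        next
      }
      rec[[m]]$alpha <- c(rec[[m]]$alpha, fit$alpha_hat)
      rec[[m]]$beta <- c(rec[[m]]$beta, fit$beta_hat)
      rec[[m]]$cov_a <- c(rec[[m]]$cov_a,
                          !any(is.na(fit$ci_alpha)) &&
                            fit$ci_alpha[1L] <= spec$alpha_true &&
                            spec$alpha_true <= fit$ci_alpha[2L])
      rec[[m]]$cov_b <- c(rec[[m]]$cov_b,
                          !any(is.na(fit$ci_beta)) &&
                            fit$ci_beta[1L] <= spec$beta_true &&
                            spec$beta_true <= fit$ci_beta[2L])
    }
    if (verbose && r %% 25L == 0L)
      message("replication ", r, "/", spec$n_replications)
  }
  rows <- lapply(methods, function(m) {
    x <- rec[[m]]
    n_used <- length(x$alpha)
    am <- if (n_used) mean(x$alpha) else NA_real_
    bm <- if (n_used) mean(x$beta) else NA_real_
    bias <- vapply(d_pred, function(d) {
      if (n_used) rr_bias(am, bm, d, spec$alpha_true, spec$beta_true)
      else NA_real_
    }, numeric(1))
    out <- data.frame(
      sigma_unshare_berkson = spec$err$sigma_unshare_berkson,
      sigma_share_berkson = spec$err$sigma_share_berkson,
      sigma_unshare_class = spec$err$sigma_unshare_class,
      sigma_share_class = spec$err$sigma_share_class,
      method = m,
      coverage_alpha = if (n_used) 100 * mean(x$cov_a) else NA_real_,
      coverage_beta = if (n_used) 100 * mean(x$cov_b) else NA_real_,
      mean_alpha = am, mean_beta = bm,
      sd_alpha = if (n_used > 1) stats::sd(x$alpha) else NA_real_,
      sd_beta = if (n_used > 1) stats::sd(x$beta) else NA_real_,
      dose_correlation = corr,
      n_used = n_used, n_failed = x$failed,
      n_replications = spec$n_replications,
      n_realizations = spec$n_realizations,
      seed = spec$seed,
      stringsAsFactors = FALSE)
    for (i in seq_along(d_pred))
      out[[paste0("rr_bias_", d_pred[i], "Gy")]] <- bias[i]
    out
  })
  report <- do.call(rbind, rows)
  class(report) <- c("evaluation_report", "data.frame")
  report
}

#' Default factorial scenario grid
#'
#' The 20-row grid of the study's tables: Berkson (unshared, shared) GSD
#' pairs (0,0), (0.2,0.2), (0.2,0.5), (0.5,0.2), (0.5,0.5) crossed with
#' classical (unshared, shared) pairs (0.2,0.2), (0.2,0.5), (0.5,0.2),
#' (0.5,0.5).
#'
#' @return List of [error_model()] objects, in table row order.
#' @export
default_scenario_grid <- function() {
  berkson <- list(c(0, 0), c(0.2, 0.2), c(0.2, 0.5), c(0.5, 0.2),
                  c(0.5, 0.5))
  classical <- list(c(0.2, 0.2), c(0.2, 0.5), c(0.5, 0.2), c(0.5, 0.5))
  out <- list()
  for (b in berkson) for (cl in classical) {
    out[[length(out) + 1L]] <- error_model(
      sigma_share_berkson = b[2L], sigma_unshare_berkson = b[1L],
      sigma_share_class = cl[2L], sigma_unshare_class = cl[1L])
  }
  out
}

#' Run the full simulation experiment over a scenario grid
#'
#' @param scenarios list of [error_model()] objects (default the 20-row
#'   grid).
#' @param ... arguments passed to [scenario_spec()] for every scenario
#'   (replications, realizations, methods, seed, ...).
#' @param quick use the reduced profile (50 replications, 100 realizations)
#'   intended for smoke runs.
#' @param verbose print progress.
#' @return A combined `evaluation_report`.
#' @export
run_experiment <- function(scenarios = default_scenario_grid(), ...,
                           quick = FALSE, verbose = FALSE) {
  args <- list(...)
  if (quick) {
    if (is.null(args$n_replications)) args$n_replications <- 50L
    if (is.null(args$n_realizations)) args$n_realizations <- 100L
  }
  reports <- lapply(seq_along(scenarios), function(i) {
    spec <- do.call(scenario_spec, c(list(err = scenarios[[i]]), args))
    if (verbose) message("scenario ", i, "/", length(scenarios))
    run_scenario(spec, verbose = FALSE)
  })
  report <- do.call(rbind, reports)
  class(report) <- c("evaluation_report", "data.frame")
  report
}

# ---- reports ---------------------------------------------------------------

#' Write table-shaped report files
#'
#' Emits four delimited files into `out_dir`: `coverage.tsv` (one scenario
#' row, paired alpha/beta coverage columns per method), `coefficients.tsv`
#' (mean alpha/beta per method), `rr_bias.tsv` (RR bias at the prediction
#' doses per method), a machine-readable `report_long.tsv` holding the full
#' report, and a `manifest.yaml` with seeds, sizes and versions.
#'
#' @param report an `evaluation_report`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scen_cols <- c("sigma_unshare_berkson", "sigma_share_berkson",
                 "sigma_unshare_class", "sigma_share_class")
  wide <- function(value_cols) {
    if (nrow(report) == 0L) {
      return(data.frame(matrix(nrow = 0, ncol = length(scen_cols),
                               dimnames = list(NULL, scen_cols))))
    }
    scen <- unique(report[scen_cols])
    for (m in unique(report$method)) {
      sub <- report[report$method == m, , drop = FALSE]
      idx <- match(interaction(scen[scen_cols]),
                   interaction(sub[scen_cols]))
      for (vc in value_cols)
        scen[[paste(m, vc, sep = "_")]] <- sub[[vc]][idx]
    }
    scen
  }
  bias_cols <- grep("^rr_bias_", names(report), value = TRUE)
  paths <- c(
    coverage = file.path(out_dir, "coverage.tsv"),
    coefficients = file.path(out_dir, "coefficients.tsv"),
    rr_bias = file.path(out_dir, "rr_bias.tsv"),
    long = file.path(out_dir, "report_long.tsv"),
    manifest = file.path(out_dir, "manifest.yaml"))
  utils::write.table(wide(c("coverage_alpha", "coverage_beta")),
                     paths["coverage"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(wide(c("mean_alpha", "mean_beta")),
                     paths["coefficients"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(wide(bias_cols), paths["rr_bias"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report, paths["long"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest <- list(
    package = "doserr",
    package_version = as.character(utils::packageVersion("doserr")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    seeds = unique(report$seed),
    n_replications = unique(report$n_replications),
    n_realizations = unique(report$n_realizations),
    methods = unique(report$method))
  yaml::write_yaml(manifest, paths["manifest"])
  invisible(paths)
}

#' Read back a long-format report file
#'
#' @param path the `report_long.tsv` written by [write_reports()].
#' @return An `evaluation_report` data frame.
#' @export
read_report <- function(path) {
  report <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  report$dose_correlation <- as.numeric(report$dose_correlation)
  class(report) <- c("evaluation_report", "data.frame")
  report
}

# ---- steering-file configuration -------------------------------------------

#' Read a steering (configuration) file
#'
#' A YAML file with optional keys `seed`, `replications`, `realizations`,
#' `cases`, `methods`, `quick`, `out_dir`, `prediction_doses`, `mcmc`
#' (fields of [mcmc_settings()]), and `scenarios` — either the string
#' `"default_grid"` or a list of four-GSD records with keys
#' `sigma_unshare_berkson`, `sigma_share_berkson`, `sigma_unshare_class`,
#' `sigma_share_class`.
#'
#' @param path YAML file path.
#' @return A named list of run settings with defaults filled in.
#' @export
read_steering <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(seed = 1L, replications = 500L, realizations = 1000L,
                   cases = 250L, methods = c("unadjusted", "regcal"),
                   quick = FALSE, out_dir = "doserr_output",
                   prediction_doses = c(0.1, 1), scenarios = "default_grid",
                   mcmc = list())
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}

#' Run the experiment described by a steering file
#'
#' @param path YAML steering file (see [read_steering()]).
#' @param verbose print progress.
#' @return The `evaluation_report`, invisibly; report files are written to
#'   the configured `out_dir`.
#' @export
run_from_config <- function(path, verbose = TRUE) {
  cfg <- read_steering(path)
  scenarios <- if (identical(cfg$scenarios, "default_grid"))
    default_scenario_grid()
  else lapply(cfg$scenarios, function(s)
    error_model(sigma_share_berkson = s$sigma_share_berkson %||% 0,
                sigma_unshare_berkson = s$sigma_unshare_berkson %||% 0,
                sigma_share_class = s$sigma_share_class %||% 0,
                sigma_unshare_class = s$sigma_unshare_class %||% 0))
  mcmc <- do.call(mcmc_settings, cfg$mcmc)
  report <- run_experiment(scenarios,
                           n_replications = cfg$replications,
                           n_realizations = cfg$realizations,
                           n_cases = cfg$cases, methods = cfg$methods,
                           seed = cfg$seed, mcmc = mcmc,
                           quick = isTRUE(cfg$quick), verbose = verbose)
  write_reports(report, cfg$out_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
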