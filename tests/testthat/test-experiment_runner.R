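test_that("coverage counts closed intervals, including endpoints and infinities", {
  expect_equal(coverage(list(c(0, 1), c(0.4, 2), c(1, 3), c(-1, 0.2)), 1),
               75)
  expect_equal(coverage(list(c(-Inf, Inf), c(0, Inf)), 5), 100)
  expect_equal(coverage(list(c(1, 2)), 2), 100)  # endpoint covered
  expect_equal(coverage(list(c(1, 2), c(NA, NA)), 1.5), 50)
  expect_error(coverage(list(), 1), "no intervals")
})

test_that("relative-risk bias follows its defining formula", {
  expect_equal(rr_bias(0.25, 2, 0.1), 0)
  expect_equal(rr_bias(0.25, 2, 1), 0)
  expect_equal(round(rr_bias(0.196, 2.061, 0.1), 2), -0.46)
  expect_equal(round(rr_bias(0.221, 2.278, 0.1), 2), -0.01)
  # direct hand evaluation
  expect_equal(rr_bias(0.3, 1.5, 1),
               100 * ((1 + 0.3 + 1.5) / (1 + 0.25 + 2) - 1))
  expect_error(rr_bias(-3, 0, 1), "positive")
})

test_that("stream seeds are deterministic, distinct, and in integer range", {
  s1 <- stream_seed(1, "replication", 5)
  expect_identical(s1, stream_seed(1, "replication", 5))
  expect_false(s1 == stream_seed(1, "replication", 6))
  expect_false(s1 == stream_seed(2, "replication", 5))
  expect_false(stream_seed(1, "berkson_shared") ==
                 stream_seed(1, "berkson_unshared"))
  seeds <- vapply(1:500, function(r) stream_seed(3, "replication", r),
                  integer(1))
  expect_equal(length(unique(seeds)), 500L)
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("replication simulation is reproducible and conserves cases", {
  spec <- scenario_spec(error_model(0.2, 0.2, 0.2, 0.2),
                        n_replications = 2, n_realizations = 8, seed = 99)
  s1 <- simulate_replication(spec, 1)
  s2 <- simulate_replication(spec, 1)
  expect_identical(s1$grouped_cases, s2$grouped_cases)
  expect_identical(s1$ensemble$true_doses, s2$ensemble$true_doses)
  expect_equal(sum(s1$grouped_cases), 250L)
  s3 <- simulate_replication(spec, 2)
  expect_false(identical(s1$grouped_cases, s3$grouped_cases))
})

test_that("adjusted methods are invariant to the classical error setting", {
  base <- list(n_replications = 3, n_realizations = 50,
               methods = c("unadjusted", "regcal", "mcml"), seed = 17)
  specA <- do.call(scenario_spec, c(list(err = error_model(0.2, 0.2, 0.2, 0.2)),
                                    base))
  specB <- do.call(scenario_spec, c(list(err = error_model(0.2, 0.2, 0.5, 0.5)),
                                    base))
  repA <- run_scenario(specA)
  repB <- run_scenario(specB)
  for (m in c("regcal", "mcml")) {
    a <- repA[repA$method == m, ]
    b <- repB[repB$method == m, ]
    expect_equal(a$mean_alpha, b$mean_alpha)
    expect_equal(a$mean_beta, b$mean_beta)
    expect_equal(a$coverage_beta, b$coverage_beta)
  }
  expect_false(isTRUE(all.equal(
    repA$mean_beta[repA$method == "unadjusted"],
    repB$mean_beta[repB$method == "unadjusted"])))
})

test_that("scenario runs are deterministic and bookkeeping is complete", {
  spec <- scenario_spec(error_model(0, 0, 0.2, 0.2), n_replications = 4,
                        n_realizations = 5, methods = c("regcal"), seed = 23)
  r1 <- run_scenario(spec)
  r2 <- run_scenario(spec)
  expect_identical(r1, r2)
  expect_equal(r1$n_used + r1$n_failed, 4L)
  expect_true(r1$coverage_alpha >= 0 && r1$coverage_alpha <= 100)
})

test_that("reports round-trip and the table-shaped files have paired columns", {
  spec <- scenario_spec(error_model(0, 0, 0.2, 0.2), n_replications = 3,
                        n_realizations = 5,
                        methods = c("unadjusted", "regcal"), seed = 31)
  rep <- run_scenario(spec)
  out <- withr::local_tempdir()
  paths <- write_reports(rep, out)
  expect_true(all(file.exists(paths)))
  back <- read_report(paths[["long"]])
  expect_equal(as.data.frame(back), as.data.frame(rep), tolerance = 1e-12)
  cov <- utils::read.table(paths[["coverage"]], header = TRUE, sep = "\t")
  expect_equal(nrow(cov), 1L)  # one row per scenario
  expect_true(all(c("unadjusted_coverage_alpha", "unadjusted_coverage_beta",
                    "regcal_coverage_alpha", "regcal_coverage_beta")
                  %in% names(cov)))
  manifest <- yaml::read_yaml(paths[["manifest"]])
  expect_equal(manifest$seeds, 31L)
})

test_that("the default grid has the twenty table rows", {
  grid <- default_scenario_grid()
  expect_length(grid, 20L)
  sig <- t(vapply(grid, function(e)
    c(e$sigma_unshare_berkson, e$sigma_share_berkson,
      e$sigma_unshare_class, e$sigma_share_class), numeric(4)))
  expect_equal(nrow(unique(sig)), 20L)
  expect_equal(sig[1, ], c(0, 0, 0.2, 0.2))
  expect_equal(sig[20, ], c(0.5, 0.5, 0.5, 0.5))
})

test_that("the erc method slot is reserved but unimplemented", {
  spec <- scenario_spec(error_model(), n_replications = 1,
                        n_realizations = 2, methods = "erc", seed = 1)
  expect_error(run_scenario(spec), "erc")
  register_fit_method("erc_stub", function(ensemble, cases, design, spec)
    fit_regcal(ensemble, cases, design))
  spec2 <- scenario_spec(error_model(), n_replications = 1,
                         n_realizations = 2, methods = "erc_stub", seed = 1)
  expect_equal(run_scenario(spec2)$method, "erc_stub")
})

test_that("steering files configure and drive a small run", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  out <- withr::local_tempdir()
  writeLines(c(
    "seed: 7",
    "replications: 2",
    "realizations: 5",
    "methods: [regcal]",
    paste0("out_dir: ", out),
    "scenarios:",
    "  - sigma_unshare_berkson: 0.2",
    "    sigma_share_berkson: 0.2",
    "    sigma_unshare_class: 0.2",
    "    sigma_share_class: 0.2"), cfg)
  settings <- read_steering(cfg)
  expect_equal(settings$replications, 2L)
  expect_equal(settings$cases, 250L)  # default filled in
  rep <- run_from_config(cfg, verbose = FALSE)
  expect_equal(nrow(rep), 1L)
  expect_true(file.exists(file.path(out, "report_long.tsv")))
})

test_that("the command-line dispatcher fits a grouped-data file", {
  gd <- noiseless_grouped()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grouped_data(gd, path)
  out <- capture.output(doserr_cli(c("fit", "--data", path)))
  expect_match(out[1], "parameter\testimate")
  est <- utils::read.table(text = out, header = TRUE, sep = "\t")
  expect_equal(est$estimate[est$parameter == "alpha"], 0.25,
               tolerance = 0.25)
})
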