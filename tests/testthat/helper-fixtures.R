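# small designs and helpers used across the test files

# two groups of equal size; correlation and mean-preservation properties do
# not depend on the full cohort, so property tests use this cheap design
small_design <- function(n_per_group = 50L) {
  cohort_design(c(0.1, 1), c(n_per_group, n_per_group))
}

# grouped data with expected counts at the true coefficients and zero error
noiseless_grouped <- function(design = default_cohort(), alpha = 0.25,
                              beta = 2, n_cases = 250) {
  f <- 1 + alpha * design$central_dose + beta * design$central_dose^2
  w <- design$persons * f
  grouped_data(design, round(n_cases * w / sum(w)), design$central_dose)
}

expect_ci_contains <- function(ci, value) {
  expect_true(!any(is.na(ci)) && ci[1] <= value && value <= ci[2],
              label = sprintf("interval [%g, %g] contains %g",
                              ci[1], ci[2], value))
}

pair_correlation_closed_form <- function(s_sh, s_un) {
  (exp(s_sh^2) - 1) / (exp(s_sh^2 + s_un^2) - 1)
}
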