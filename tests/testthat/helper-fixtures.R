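# Shared fixtures. Heavier panels are memoized so test files can share one
# generation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# 769-subject MCI source cohort, the construct-2 reference input
src_mci <- function() memo("src_mci",
  generate_legacy_cohort(cohort_spec_mci(), seed = 20260901))

# 641-subject pooled symptomatic source, the construct-1 reference input
src_sym <- function() memo("src_sym",
  generate_legacy_cohort(cohort_spec_symptomatic(), seed = 20260902))

# large calibrated cohort for distributional checks
big_sym <- function() memo("big_sym",
  generate_legacy_cohort(cohort_spec_symptomatic(10000), seed = 20260903))

# Hand-built 3-subject panel: linear trajectories 10+t/3, 20-t/3, constant
# 30 on the 0/3/6/9/12 grid; all completers. Endpoint changes 4, -4, 0.
hand_panel <- function() {
  sched <- c(0, 3, 6, 9, 12)
  subjects <- data.frame(
    subject_id = c("A", "B", "C"), arm = "unassigned",
    completer = TRUE, dropout_month = NA_real_, covid_dropout = FALSE,
    accrual_month = NA_real_, latent_intercept = c(10, 20, 30),
    latent_slope = c(1 / 3, -1 / 3, 0), stringsAsFactors = FALSE)
  visits <- data.frame(
    subject_id = rep(c("A", "B", "C"), each = 5),
    visit_month = rep(sched, 3),
    adas_cog = c(10 + sched / 3, 20 - sched / 3, rep(30, 5)),
    observed = TRUE, observation_mode = "in_clinic",
    stringsAsFactors = FALSE)
  new_trajectory_panel(subjects, visits, sched, residual_sd = 0)
}

# Noise-free two-arm panel on a given schedule: placebo declines by
# p_slope points/month, active arm scores additionally reduced by
# sep * (t/H)^2 (so the endpoint change difference is exactly sep).
noisefree_trial <- function(n_per_arm = 10, sched = c(0, 3, 6, 12, 18),
                            p_slope = 0.25, sep = 2,
                            baselines = NULL) {
  n <- 2 * n_per_arm
  k <- length(sched)
  H <- max(sched)
  if (is.null(baselines)) baselines <- seq(12, 28, length.out = n)
  arm <- rep(c("placebo", "active"), each = n_per_arm)
  ids <- sprintf("N%03d", seq_len(n))
  subjects <- data.frame(
    subject_id = ids, arm = arm, completer = TRUE,
    dropout_month = NA_real_, covid_dropout = FALSE,
    accrual_month = NA_real_, latent_intercept = baselines,
    latent_slope = p_slope, stringsAsFactors = FALSE)
  y <- as.vector(vapply(seq_len(n), function(i) {
    yy <- baselines[i] + p_slope * sched
    if (arm[i] == "active") yy <- yy - sep * (sched / H)^2
    yy
  }, numeric(k)))
  visits <- data.frame(
    subject_id = rep(ids, each = k), visit_month = rep(sched, n),
    adas_cog = y, observed = TRUE, observation_mode = "in_clinic",
    stringsAsFactors = FALSE)
  new_trajectory_panel(subjects, visits, sched, residual_sd = 0)
}

# construct-2 trial dataset ready for scenario filters (no treatment effect)
c2_trial <- function(n_total = 280, seed = 1, covid = TRUE) {
  d <- stratified_resample(src_mci(), n_total, seed = seed)
  d <- assign_accrual(d, accrual_plan_disease_modification(),
                      seed = seed + 1)
  if (covid) d <- overlay_covid_dropout(d, 0.24, seed = seed + 2)
  d
}

expect_panel_equal <- function(a, b) {
  expect_equal(a$subjects, b$subjects)
  expect_equal(a$visits, b$visits)
}
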