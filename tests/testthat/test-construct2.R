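# construct-2 engine: stratified resampling, accrual, pandemic dropout,
# quadratic effect

test_that("stratified resample: strata counts, arms, fresh ids", {
  d <- stratified_resample(src_mci(), 280, seed = 2)
  expect_equal(n_panel_subjects(d), 280)
  expect_equal(sum(d$subjects$completer), 210)        # 75% of 280
  expect_equal(sum(!d$subjects$completer), 70)
  expect_equal(unname(table(d$subjects$arm)["placebo"]), 140)
  expect_equal(unname(table(d$subjects$arm)["active"]), 140)
  expect_false(anyDuplicated(d$subjects$subject_id) > 0)
  expect_true(all(d$subjects$source_id %in% src_mci()$subjects$subject_id))
  expect_silent(validate_trajectory_panel(d))
  # all-completer sample
  d1 <- stratified_resample(src_mci(), 40, completer_fraction = 1, seed = 3)
  expect_true(all(d1$subjects$completer))
  # empty stratum errors
  allcomp <- panel_subset(src_mci(), which(src_mci()$subjects$completer))
  expect_error(stratified_resample(allcomp, 40, completer_fraction = 0.5),
               "empty dropout stratum")
})

test_that("resampled dropout times follow the source distribution", {
  d <- stratified_resample(src_mci(), 2000, seed = 5)
  src_dm <- src_mci()$subjects$dropout_month
  got_dm <- d$subjects$dropout_month
  expect_true(all(stats::na.omit(got_dm) %in% stats::na.omit(src_dm)))
})

test_that("accrual assignment reproduces the plan counts", {
  plan <- accrual_plan_disease_modification()
  expect_equal(plan$completed_through, c(18, 12, 6, 3, 0))
  # cumulative fractions reproduce 12/25/50/80% completion through 18/12/6/3
  expect_equal(cumsum(plan$fraction), c(0.12, 0.25, 0.50, 0.80, 1.00))
  d <- assign_accrual(stratified_resample(src_mci(), 280, seed = 7), plan,
                      seed = 8)
  tab <- table(d$subjects$accrual_month)
  expect_equal(as.vector(tab[c("0", "3", "6", "12", "18")]),
               c(56, 84, 70, 36, 34))
  # completion-consistent: every stage-m subject has data through month m
  k <- length(panel_schedule(d))
  lom <- tapply(ifelse(d$visits$observed, d$visits$visit_month, -Inf),
                rep(seq_len(280), each = k), max)
  expect_true(all(lom >= d$subjects$accrual_month))
  # single-stage plan
  d1 <- assign_accrual(stratified_resample(src_mci(), 40, seed = 1),
                       accrual_plan(0, 1), seed = 2)
  expect_true(all(d1$subjects$accrual_month == 0))
})

test_that("accrual stage fractions are reproduced at scale", {
  plan <- accrual_plan_disease_modification()
  d <- assign_accrual(stratified_resample(src_mci(), 10000, seed = 3), plan,
                      seed = 4)
  frac <- table(d$subjects$accrual_month)[c("0", "3", "6", "12", "18")] / 10000
  for (j in seq_len(nrow(plan))) {
    f <- plan$fraction[plan$completed_through ==
                         c(0, 3, 6, 12, 18)[j]]
    se <- sqrt(f * (1 - f) / 10000)
    expect_lt(abs(frac[j] - f), 3 * se + 1e-4)
  }
})

test_that("independent accrual mode ignores dropout status", {
  # construct-1 convention: stages assigned regardless of data extent,
  # so some non-completers receive stages beyond their dropout month
  d <- stratified_resample(src_mci(), 2000, completer_fraction = 0.5,
                           seed = 11)
  d <- assign_accrual(d, accrual_plan_disease_modification(), seed = 12,
                      respect_completion = FALSE)
  k <- length(panel_schedule(d))
  lom <- tapply(ifelse(d$visits$observed, d$visits$visit_month, -Inf),
                rep(seq_len(2000), each = k), max)
  expect_gt(sum(lom < d$subjects$accrual_month), 0)
})

test_that("pandemic dropout overlay: count, truncation, no-op cases", {
  d <- c2_trial(280, seed = 21, covid = FALSE)
  dd <- overlay_covid_dropout(d, 0.24, seed = 22)
  expect_equal(sum(dd$subjects$covid_dropout), 67)  # round(0.24 * 280)
  # deletes nothing before or at the pause (the accrual month)
  k <- length(panel_schedule(d))
  am <- rep(dd$subjects$accrual_month, each = k)
  pre <- d$visits$observed & d$visits$visit_month <= am
  expect_equal(dd$visits$observed[pre], d$visits$observed[pre])
  expect_equal(dd$visits$adas_cog[pre], d$visits$adas_cog[pre])
  # and only covid-flagged subjects lose anything
  lost <- d$visits$observed & !dd$visits$observed
  expect_true(all(rep(dd$subjects$covid_dropout, each = k)[lost]))
  # a flagged subject at stage 18 keeps all data (deletion beyond last visit)
  full <- which(dd$subjects$covid_dropout & dd$subjects$accrual_month == 18 &
                  dd$subjects$completer)
  if (length(full)) {
    rows <- (full[1] - 1) * k + seq_len(k)
    expect_equal(dd$visits$observed[rows], d$visits$observed[rows])
  }
  expect_panel_equal(overlay_covid_dropout(d, 0, seed = 1), d)
  expect_error(overlay_covid_dropout(stratified_resample(src_mci(), 20,
                                                         seed = 1), 0.24),
               "accrual")
})

test_that("quadratic treatment effect is exact at the anchors", {
  e <- treatment_effect(1.85, 18)
  expect_equal(effect_at(e, 0), 0)
  expect_equal(effect_at(e, 18), 1.85)
  expect_equal(effect_at(treatment_effect(2, 18), 9), 0.5)  # 2 * (9/18)^2
  tt <- seq(0, 18, by = 0.5)
  expect_true(all(diff(effect_at(e, tt)) >= 0))
})

test_that("injected effect induces exactly delta on a noise-free fixture", {
  p <- noisefree_trial(n_per_arm = 15, sep = 0)   # identical arms
  d <- apply_quadratic_effect(p, treatment_effect(1.85, 18))
  ch <- endpoint_changes(d, 18)
  diff_ <- mean(ch$change[ch$arm == "placebo"]) -
    mean(ch$change[ch$arm == "active"])
  expect_equal(diff_, 1.85, tolerance = 1e-12)
  # placebo untouched
  pl <- d$subjects$arm == "placebo"
  k <- length(panel_schedule(d))
  expect_equal(d$visits$adas_cog[rep(pl, each = k)],
               p$visits$adas_cog[rep(pl, each = k)])
  # standardized effect anchor at the trial SD
  expect_equal(1.85 / 4.7, 0.3936, tolerance = 5e-4)
  expect_error(apply_quadratic_effect(src_mci(), treatment_effect(1, 18)),
               "arms")
})
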