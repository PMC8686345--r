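# disruption scenarios for both constructs

# hand fixture with one subject per accrual stage, no natural dropout
staged_panel <- function(sched, stages) {
  p <- noisefree_trial(n_per_arm = length(stages) / 2, sched = sched,
                       sep = 0)
  p$subjects$accrual_month <- stages
  p
}

test_that("scenario spec defaults and validation", {
  s3c1 <- scenario_spec("symptomatic", 3)
  expect_equal(s3c1$window_extension, 3)
  expect_equal(s3c1$remote_offset, 0)
  s3c2 <- scenario_spec("disease_modification", 3)
  expect_equal(s3c2$remote_offset, 0.5)
  expect_true(s3c2$medication_paused)
  expect_false(scenario_spec("symptomatic", 2)$medication_paused)
  expect_error(scenario_spec("symptomatic", 5), "scenario_id")
  expect_error(scenario_spec("symptomatic", 2, window_extension = 2),
               "window_extension")
  # construct mismatch
  p <- staged_panel(c(0, 3, 6, 9, 12), rep(c(0, 12), 3))
  expect_error(apply_scenario_construct2(p, scenario_spec("symptomatic", 1)),
               "construct")
  expect_error(apply_scenario_construct1(
    p, scenario_spec("disease_modification", 1)), "construct")
})

test_that("symptomatic pause window: open upper bound per stage", {
  sched <- c(0, 3, 6, 9, 12)
  p <- staged_panel(sched, c(0, 3, 6, 9, 12, 12))
  s2 <- apply_scenario_construct1(p, scenario_spec("symptomatic", 2))
  obs <- matrix(s2$visits$observed, ncol = 5, byrow = TRUE)
  colnames(obs) <- sched
  # stage 0 misses month 3 only; stage 3 misses 6; stage 6 misses 9 but
  # keeps 12; stage 9 misses 12; stage 12 keeps everything
  expect_equal(obs[1, ], c(`0` = TRUE, `3` = FALSE, `6` = TRUE, `9` = TRUE,
                           `12` = TRUE))
  expect_equal(unname(obs[2, ]), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(unname(obs[3, ]), c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(unname(obs[4, ]), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(obs[5, ]), rep(TRUE, 5))
  # scenario 1 truncates at the stage; a 12-month completer is unchanged
  s1 <- apply_scenario_construct1(p, scenario_spec("symptomatic", 1))
  obs1 <- matrix(s1$visits$observed, ncol = 5, byrow = TRUE)
  expect_equal(unname(obs1[1, ]), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(unname(obs1[4, ]), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(obs1[5, ]), rep(TRUE, 5))
  # scenario 0 is the identity
  expect_panel_equal(apply_scenario_construct1(
    p, scenario_spec("symptomatic", 0)), p)
})

test_that("symptomatic scenario 3 reschedules missed endpoints into [12,15]", {
  sched <- c(0, 3, 6, 9, 12)
  p <- staged_panel(sched, c(0, 3, 6, 9, 12, 9))
  p2 <- p
  attr(p2, "residual_sd") <- 0
  s3 <- apply_scenario_construct1(p2, scenario_spec("symptomatic", 3),
                                  seed = 5)
  k <- 5
  endrow <- seq_len(6) * k
  # every (non-dropout) subject has an observed endpoint in [12, 15]
  expect_true(all(s3$visits$observed[endrow]))
  em <- s3$visits$visit_month[endrow]
  expect_true(all(em >= 12 & em <= 15))
  # only the stage-9 subjects are rescheduled, to month 15
  expect_equal(em, c(12, 12, 12, 15, 12, 15))
  # noise-free extrapolation follows the latent slope
  i <- 4
  y12 <- p$visits$adas_cog[endrow[i]]
  expect_equal(s3$visits$adas_cog[endrow[i]],
               y12 + 3 * p$subjects$latent_slope[i])
  # mid-pause visits still deleted as in scenario 2
  expect_false(s3$visits$observed[2])  # stage-0 subject's month 3
})

test_that("symptomatic scenario 2 missing-endpoint fraction is ~46%", {
  # 30% dropout plus 23% of non-dropouts at stage 9: 1 - 0.7 * 0.77 = 0.461
  sets <- build_construct1_cell(src_sym(), 360, effect_target(2.6, 6),
                                scenario_id = 2, n_datasets = 3, seed = 31)
  miss <- vapply(sets, function(d)
    1 - nrow(endpoint_changes(d, 12)) / 360, numeric(1))
  expect_lt(abs(mean(miss) - 0.461), 0.05)
})

test_that("disease-modification pause window: half-open upper bound", {
  sched <- c(0, 3, 6, 12, 18)
  p <- staged_panel(sched, c(0, 3, 6, 12, 18, 18))
  s2 <- apply_scenario_construct2(p, scenario_spec("disease_modification", 2))
  obs <- matrix(s2$visits$observed, ncol = 5, byrow = TRUE)
  # stage 0 misses months 3 AND 6; stage 3 misses 6; stage 6 misses 12;
  # stage 12 misses 18; stage 18 intact
  expect_equal(unname(obs[1, ]), c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(obs[2, ]), c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(unname(obs[3, ]), c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(unname(obs[4, ]), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(unname(obs[5, ]), rep(TRUE, 5))
})

test_that("remote assessment keeps in-pause visits shifted by the offset", {
  sched <- c(0, 3, 6, 12, 18)
  p <- staged_panel(sched, c(0, 3, 6, 12, 18, 12))
  s2 <- apply_scenario_construct2(p, scenario_spec("disease_modification", 2))
  s3 <- apply_scenario_construct2(p, scenario_spec("disease_modification", 3))
  remote <- s3$visits$observation_mode == "remote"
  # the remote set is exactly the scenario-2 deleted set
  expect_equal(remote, p$visits$observed & !s2$visits$observed)
  expect_equal(s3$visits$adas_cog[remote], p$visits$adas_cog[remote] + 0.5)
  # with offset 0 the two scenarios differ only by those visits' presence
  s3z <- apply_scenario_construct2(
    p, scenario_spec("disease_modification", 3, remote_offset = 0))
  expect_equal(s3z$visits$adas_cog[!remote], s2$visits$adas_cog[!remote])
  expect_equal(s3z$visits$adas_cog[remote], p$visits$adas_cog[remote])
  # scenario 1: only stage-18 subjects contribute 18-month outcomes
  s1 <- apply_scenario_construct2(p, scenario_spec("disease_modification", 1))
  ch <- endpoint_changes(s1, 18)
  expect_setequal(ch$subject_id,
                  p$subjects$subject_id[p$subjects$accrual_month == 18])
})

test_that("scenario transforms never touch pre-pause data, ordering holds", {
  for (seed in 1:3) {
    d <- c2_trial(280, seed = seed * 100)
    counts <- vapply(0:3, function(sid) {
      out <- apply_scenario_construct2(
        d, scenario_spec("disease_modification", sid))
      # never adds subjects or observations; pre-pause rows untouched
      k <- length(panel_schedule(d))
      am <- rep(d$subjects$accrual_month, each = k)
      pre <- d$visits$visit_month <= am
      expect_equal(out$visits$adas_cog[pre & d$visits$observed],
                   d$visits$adas_cog[pre & d$visits$observed])
      expect_equal(n_panel_subjects(out), 280)
      sum(out$visits$observed)
    }, numeric(1))
    # |S1| <= |S2| <= |S3| <= |S0|
    expect_true(all(diff(counts[c(2, 3, 4, 1)]) >= 0))
  }
  # scenario 1 output is a per-subject time prefix of scenario 0
  d <- c2_trial(280, seed = 7)
  s1 <- apply_scenario_construct2(d, scenario_spec("disease_modification", 1))
  expect_true(all(!s1$visits$observed | d$visits$observed))
})

test_that("disposition report matches hand enumeration on a fixture", {
  sched <- c(0, 3, 6, 12, 18)
  p <- staged_panel(sched, c(0, 3, 6, 12, 18, 12))
  spec2 <- scenario_spec("disease_modification", 2)
  rep2 <- disposition_report(apply_scenario_construct2(p, spec2), spec2)
  # month 18: stages 12 (x2) missed in pause, others observed
  m18 <- rep2[rep2$visit_month == 18, ]
  expect_equal(m18$count[m18$disposition == "missed_in_pause"], 2)
  expect_equal(sum(m18$count), 6)
  # month 3: stage 0 missed, stage 3/6/12/18 completed pre-pause
  m3 <- rep2[rep2$visit_month == 3, ]
  expect_equal(m3$count[m3$disposition == "missed_in_pause"], 1)
  expect_equal(m3$count[m3$disposition == "completed_pre_pause"], 5)
  # scenario 0: everything observed is completed_pre_pause
  spec0 <- scenario_spec("disease_modification", 0)
  rep0 <- disposition_report(p, spec0)
  expect_setequal(unique(rep0$disposition), "completed_pre_pause")
  # on a resampled trial, the stage-12 fraction that misses month 18 is 13%
  d <- c2_trial(280, seed = 3, covid = FALSE)
  expect_equal(sum(d$subjects$accrual_month == 12) / 280, 36 / 280)
  s2 <- apply_scenario_construct2(d, spec2)
  r <- disposition_report(s2, spec2)
  mip18 <- r$count[r$visit_month == 18 & r$disposition == "missed_in_pause"]
  stage12_alive <- sum(d$subjects$accrual_month == 12 & d$subjects$completer)
  expect_equal(mip18, stage12_alive)
})
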