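# construct-1 engine: slopes, weighted splits, effect targeting, dropout

test_that("least-squares slopes match hand computations", {
  sched <- c(0, 6, 12)
  subjects <- data.frame(
    subject_id = c("a", "b", "c"), arm = "unassigned", completer = TRUE,
    dropout_month = NA_real_, covid_dropout = FALSE,
    accrual_month = NA_real_, latent_intercept = 0, latent_slope = 0,
    stringsAsFactors = FALSE)
  visits <- data.frame(
    subject_id = rep(c("a", "b", "c"), each = 3),
    visit_month = rep(sched, 3),
    adas_cog = c(0, 3, 6,      # two... three points on an exact line, slope 0.5
                 5, 5, 5,      # constant, slope 0
                 1, 2, 6),     # OLS closed form: 30/72 = 5/12
    observed = TRUE, observation_mode = "in_clinic",
    stringsAsFactors = FALSE)
  p <- new_trajectory_panel(subjects, visits, sched)
  st <- fit_subject_slopes(p)
  expect_s3_class(st, "slope_table")
  expect_equal(st$slope[st$subject_id == "a"], 0.5)
  expect_equal(st$slope[st$subject_id == "b"], 0)
  expect_equal(st$slope[st$subject_id == "c"], 5 / 12)
  expect_equal(st$rank, 1:3)
  expect_true(!is.unsorted(st$slope))
  # subject with < 2 observed visits is excluded with a warning
  p$visits$observed[2:3] <- FALSE
  p$visits$adas_cog[2:3] <- NA
  expect_warning(st2 <- fit_subject_slopes(p), "excluded")
  expect_false("a" %in% st2$subject_id)
})

test_that("sampling weights are positive, uniform at tilt 0, mirrored", {
  w0 <- weight_vector(sampling_weights(0), 10)
  expect_equal(w0, rep(1, 10))
  wl <- weight_vector(sampling_weights(2, "toward_larger"), 15)
  ws <- weight_vector(sampling_weights(2, "toward_smaller"), 15)
  expect_true(all(wl > 0))
  expect_true(!is.unsorted(wl))
  expect_equal(wl, rev(ws))
  expect_error(sampling_weights(-1), "tilt")
})

test_that("weighted split: sizes, disjointness, exhaustive case, errors", {
  st <- fit_subject_slopes(big_sym())
  st20 <- st[st$rank <= 20, ]
  class(st20) <- class(st)
  st20$rank <- 1:20
  sp <- weighted_split_sample(st20, 20, sampling_weights(3), seed = 4)
  expect_length(sp$placebo, 10)
  expect_length(sp$active, 10)
  expect_length(intersect(sp$placebo, sp$active), 0)
  expect_setequal(c(sp$placebo, sp$active), st20$subject_id)
  expect_error(weighted_split_sample(st20, 19), "even")
  expect_error(weighted_split_sample(st20, 22), "exceeds")
})

test_that("positive tilt stochastically orders the arm slope means", {
  # Monte-Carlo check on a 20-slope fixture: placebo mean slope > active
  slopes <- data.frame(subject_id = sprintf("s%02d", 1:20),
                       slope = seq(-1, 1, length.out = 20), rank = 1:20)
  class(slopes) <- c("slope_table", "data.frame")
  diffs <- vapply(1:400, function(r) {
    sp <- weighted_split_sample(slopes, 10, sampling_weights(4), seed = r)
    mean(slopes$slope[match(sp$placebo, slopes$subject_id)]) -
      mean(slopes$slope[match(sp$active, slopes$subject_id)])
  }, numeric(1))
  expect_gt(mean(diffs), 0.2)
  # and tilt = 0 is exchangeable in expectation
  diffs0 <- vapply(1:400, function(r) {
    sp <- weighted_split_sample(slopes, 10, sampling_weights(0), seed = r)
    mean(slopes$slope[match(sp$placebo, slopes$subject_id)]) -
      mean(slopes$slope[match(sp$active, slopes$subject_id)])
  }, numeric(1))
  expect_lt(abs(mean(diffs0)), 3 * sd(diffs0) / sqrt(400))
})

test_that("effect targeting hits delta and SD within 0.001", {
  tgt <- effect_target(2.6, sd = 6.0)
  d <- build_effect_targeted_dataset(src_sym(), 360, tgt, seed = 17)
  expect_equal(sum(d$subjects$arm == "placebo"), 180)
  expect_equal(sum(d$subjects$arm == "active"), 180)
  expect_false(anyDuplicated(d$subjects$subject_id) > 0)
  ach <- attr(d, "achieved")
  expect_lt(abs(ach["difference"] - 2.6), 0.001)
  expect_lt(abs(ach["pooled_sd"] - 6.0), 0.001)
  expect_gte(attr(d, "iterations"), 1)
  # recompute from the emitted panel itself
  ch <- endpoint_changes(d, 12)
  xp <- ch$change[ch$arm == "placebo"]; xa <- ch$change[ch$arm == "active"]
  expect_lt(abs(mean(xp) - mean(xa) - 2.6), 0.001)
  # baselines untouched by the affine recalibration
  src_base <- src_sym()$visits
  src_base <- src_base[src_base$visit_month == 0, ]
  got <- d$visits[d$visits$visit_month == 0, ]
  expect_equal(got$adas_cog,
               src_base$adas_cog[match(got$subject_id, src_base$subject_id)])
})

test_that("null target gives exchangeable arms; literal mode works", {
  tgt0 <- effect_target(0, sd = 6.0)
  d0 <- build_effect_targeted_dataset(src_sym(), 100, tgt0, seed = 3)
  ach <- attr(d0, "achieved")
  expect_lt(abs(ach["difference"]), 0.001)
  r <- ttest_change(d0, 12)
  expect_lt(abs(r$statistic), 0.001)
  # literal accept/reject mode at a loose tolerance
  tgt <- effect_target(2.0, sd = 6.0, tolerance = 0.4)
  dl <- build_effect_targeted_dataset(src_sym(), 100, tgt, seed = 3,
                                      mode = "resample_only")
  ach <- attr(dl, "achieved")
  expect_lt(abs(ach["difference"] - 2.0), 0.4)
  # infeasible target errors with the best discrepancy
  bad <- effect_target(40, sd = 6.0, max_iterations = 30)
  expect_error(build_effect_targeted_dataset(src_sym(), 100, bad, seed = 3),
               "best discrepancy")
})

test_that("monotonicity: larger targets separate the arm slopes more", {
  sep <- vapply(c(0, 2, 4), function(delta) {
    d <- build_effect_targeted_dataset(src_sym(), 200,
                                       effect_target(delta, 6), seed = 5)
    s <- d$subjects
    mean(s$latent_slope[s$arm == "placebo"]) -
      mean(s$latent_slope[s$arm == "active"])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})

test_that("uniform dropout filter: exact count, timing, baseline kept", {
  d <- build_effect_targeted_dataset(src_sym(), 360,
                                     effect_target(2.6, 6), seed = 21)
  dd <- apply_dropout_uniform(d, 0.30, seed = 8)
  expect_equal(sum(!dd$subjects$completer), 108)  # round(0.3 * 360)
  expect_silent(validate_trajectory_panel(dd))
  expect_true(all(dd$visits$observed[dd$visits$visit_month == 0]))
  expect_panel_equal(apply_dropout_uniform(d, 0, seed = 8), d)
  # dropout-time uniformity on (0, 12) over many simulated dropouts
  dm <- unlist(lapply(1:40, function(s)
    apply_dropout_uniform(d, 0.9, seed = s)$subjects$dropout_month))
  dm <- dm[!is.na(dm)]
  expect_gt(length(dm), 10000)
  ks <- suppressWarnings(ks.test(dm, "punif", 0, 12))
  expect_gt(ks$p.value, 0.001)
  expect_error(apply_dropout_uniform(d, 1.2), "rate")
})
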