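# Power estimation.
#
# Construct 1: 20 effect-calibrated datasets per cell are each submitted to
# a bootstrap with (by default) 1000 replicates apportioned round-robin;
# the rejection proportion at two-sided alpha = 0.05 is the power estimate.
# Construct 2: power per cell is the rejection proportion over n_sim
# independent runs of the full resampling pipeline. A closed-form
# noncentral-t reference for the endpoint t test is provided, as is the
# probit-link binomial smoother used for power curves.

#' Power estimate container
#'
#' @param construct,scenario_id,method,delta,n_total Cell labels.
#' @param replicates,rejections Replicate and rejection counts.
#' @param seed Master seed of the cell.
#' @param n_nonconverged Replicates whose fit failed (counted as
#'   non-rejections).
#' @return Object of class `power_estimate` with `power` and its binomial
#'   Monte-Carlo standard error `mc_se`.
#' @export
power_estimate <- function(construct, scenario_id, method, delta, n_total,
                           replicates, rejections, seed,
                           n_nonconverged = 0L) {
  power <- rejections / replicates
  structure(list(construct = construct, scenario_id = scenario_id,
                 method = method, delta = delta, n_total = n_total,
                 replicates = replicates, rejections = rejections,
                 power = power,
                 mc_se = sqrt(power * (1 - power) / replicates),
                 n_nonconverged = n_nonconverged, seed = seed),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> %s S%d %s delta=%.3g n=%d: power %.3f (MC SE %.3f, %d/%d)\n",
              x$construct, x$scenario_id, x$method, x$delta, x$n_total,
              x$power, x$mc_se, x$rejections, x$replicates))
  invisible(x)
}

#' Exact power of the two-sample endpoint t test
#'
#' Closed-form two-sided power from the noncentral t distribution with
#' noncentrality `delta / sd * sqrt(n_per_arm / 2)` and
#' `2 * n_per_arm - 2` degrees of freedom.
#'
#' @param delta Between-arm difference in endpoint change (points).
#' @param sd Pooled change-score SD (points).
#' @param n_per_arm Complete cases per arm (>= 2).
#' @param alpha Two-sided significance level.
#' @return Power as a proportion.
#' @export
analytic_ttest_power <- function(delta, sd, n_per_arm, alpha = 0.05) {
  stopifnot(sd > 0, n_per_arm >= 2)
  df <- 2 * n_per_arm - 2
  ncp <- delta / sd * sqrt(n_per_arm / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}

#' Bootstrap power for construct-1 datasets
#'
#' The scenario- and dropout-filtered datasets of one cell (20 in the
#' reference design) are cycled round-robin over `n_boot` replicates; each
#' replicate resamples subjects (with replacement by default, or an 80%
#' subsample without replacement for the literal reading) and records
#' rejection of the chosen method at `alpha`. Non-converged fits count as
#' non-rejections.
#'
#' @param datasets List of `trajectory_panel`s.
#' @param method Analysis backend (see [fit_method()]).
#' @param n_boot Number of bootstrap replicates.
#' @param alpha Two-sided significance level.
#' @param seed Integer seed.
#' @param scenario_id Label recorded in the result.
#' @param resample `"bootstrap"` (with replacement, full size) or
#'   `"subsample"` (without replacement, `subsample_fraction` of subjects).
#' @param subsample_fraction Fraction for `resample = "subsample"`.
#' @param endpoint_month Nominal endpoint month (default 12).
#' @return A `power_estimate`.
#' @export
bootstrap_power_construct1 <- function(datasets, method = "t_test",
                                       n_boot = 1000, alpha = 0.05, seed = 1,
                                       scenario_id = NA_integer_,
                                       resample = c("bootstrap", "subsample"),
                                       subsample_fraction = 0.8,
                                       endpoint_month = 12) {
  stopifnot(length(datasets) >= 1)
  resample <- match.arg(resample)
  nd <- length(datasets)
  rej <- 0L
  nonconv <- 0L
  delta <- NA_real_
  n_total <- n_panel_subjects(datasets[[1]])
  for (r in seq_len(n_boot)) {
    d0 <- datasets[[((r - 1) %% nd) + 1]]
    n <- n_panel_subjects(d0)
    set.seed(substream_seed(seed, "boot", r))
    if (resample == "bootstrap") {
      idx <- sample.int(n, n, replace = TRUE)
    } else {
      idx <- sample.int(n, round(subsample_fraction * n))
    }
    b <- panel_subset(d0, idx, sprintf("B%05d", seq_along(idx)))
    res <- fit_method(b, method, endpoint_month)
    if (!res$converged || is.na(res$p_value)) nonconv <- nonconv + 1L
    else if (res$p_value < alpha) rej <- rej + 1L
  }
  if (nonconv == n_boot) stop("all bootstrap replicates failed to converge")
  power_estimate("symptomatic", scenario_id, method, delta, n_total,
                 n_boot, rej, seed, nonconv)
}

#' Run the construct-1 cell pipeline
#'
#' Builds the effect-calibrated datasets for one (delta, n) cell, applies
#' the uniform dropout filter, assigns accrual stages (independently of
#' dropout, per the symptomatic construct convention) and the scenario
#' filter.
#'
#' @param source Source cohort panel (e.g. from
#'   `generate_legacy_cohort(cohort_spec_symptomatic(), seed)`).
#' @param n_total Trial size (default 360).
#' @param target An [effect_target()].
#' @param scenario_id Scenario 0-3.
#' @param n_datasets Number of calibrated datasets (reference design: 20).
#' @param dropout_rate Uniform dropout proportion (default 0.30).
#' @param plan Accrual plan (default [accrual_plan_symptomatic()]).
#' @param seed Integer seed.
#' @param ... Passed to [build_effect_targeted_dataset()].
#' @return List of filtered `trajectory_panel`s.
#' @export
build_construct1_cell <- function(source, n_total = 360, target,
                                  scenario_id = 0, n_datasets = 20,
                                  dropout_rate = 0.30,
                                  plan = accrual_plan_symptomatic(),
                                  seed = 1, ...) {
  spec <- scenario_spec("symptomatic", scenario_id)
  lapply(seq_len(n_datasets), function(j) {
    s <- substream_seed(seed, "c1cell", j)
    d <- build_effect_targeted_dataset(source, n_total, target,
                                       seed = substream_seed(s, "build"), ...)
    d <- apply_dropout_uniform(d, dropout_rate, seed = substream_seed(s, "drop"))
    d <- assign_accrual(d, plan, seed = substream_seed(s, "accr"),
                        respect_completion = FALSE)
    apply_scenario_construct1(d, spec, seed = substream_seed(s, "scen"))
  })
}

#' Simulated power for the disease-modification construct
#'
#' Runs `n_sim` independent replicates of the construct-2 pipeline
#' (stratified resample, accrual assignment, pandemic dropout overlay for
#' scenarios 1-3, quadratic treatment effect, scenario filter) and fits the
#' chosen method; the rejection proportion at `alpha` is the power
#' estimate.
#'
#' @param source Source MCI cohort panel (e.g. from
#'   `generate_legacy_cohort(cohort_spec_mci(), seed)`).
#' @param scenario_id Scenario 0-3.
#' @param method Analysis backend.
#' @param delta Target 18-month between-arm change difference (points).
#' @param n_total Trial size (reference design 280).
#' @param n_sim Number of simulation replicates (reference design 1000).
#' @param alpha Two-sided significance level.
#' @param seed Integer seed.
#' @param completer_fraction Completer stratum proportion.
#' @param covid_rate Pandemic dropout proportion (scenarios 1-3).
#' @param plan Accrual plan.
#' @param remote_offset Remote-assessment worsening (scenario 3).
#' @param endpoint_month Endpoint month (default 18).
#' @return A `power_estimate`.
#' @export
simulate_power_construct2 <- function(source, scenario_id = 0,
                                      method = "t_test", delta = 1.85,
                                      n_total = 280, n_sim = 1000,
                                      alpha = 0.05, seed = 1,
                                      completer_fraction = 0.75,
                                      covid_rate = 0.24,
                                      plan = accrual_plan_disease_modification(),
                                      remote_offset = 0.5,
                                      endpoint_month = 18) {
  stopifnot(is_trajectory_panel(source))
  if (!scenario_id %in% 0:3) stop("scenario_id must be 0-3")
  if (delta < 0) stop("delta must be >= 0")
  spec <- scenario_spec("disease_modification", scenario_id,
                        remote_offset = remote_offset)
  eff <- treatment_effect(delta, endpoint_month)
  rej <- 0L
  nonconv <- 0L
  for (r in seq_len(n_sim)) {
    s <- substream_seed(seed, "c2", scenario_id, method, delta, n_total, r)
    d <- stratified_resample(source, n_total, completer_fraction,
                             seed = substream_seed(s, "rs"))
    d <- assign_accrual(d, plan, seed = substream_seed(s, "ac"))
    if (scenario_id >= 1 && covid_rate > 0)
      d <- overlay_covid_dropout(d, covid_rate, seed = substream_seed(s, "cv"))
    if (delta > 0) d <- apply_quadratic_effect(d, eff)
    d <- apply_scenario_construct2(d, spec)
    res <- fit_method(d, method, endpoint_month)
    if (!res$converged || is.na(res$p_value)) nonconv <- nonconv + 1L
    else if (res$p_value < alpha) rej <- rej + 1L
  }
  power_estimate("disease_modification", scenario_id, method, delta, n_total,
                 n_sim, rej, seed, nonconv)
}

#' Probit-smoothed power curve
#'
#' Binomial regression of rejection counts on effect size with a probit
#' link, mirroring the smoothing used for the power figures. Complete
#' separation (or any non-finite fit) falls back to a step function through
#' the raw proportions, with a warning.
#'
#' @param points Data frame with columns `delta`, `rejections`,
#'   `replicates`.
#' @param grid Effect sizes at which to evaluate the smoothed curve
#'   (default: 101 points spanning the observed deltas).
#' @return A list of class `power_curve` with `points`, `grid` (data frame
#'   of `delta`, `power`), `coefficients`, and `fallback` flag.
#' @export
smooth_power_curve <- function(points, grid = NULL) {
  stopifnot(all(c("delta", "rejections", "replicates") %in% names(points)))
  if (length(unique(points$delta)) < 2)
    stop("need at least 2 distinct deltas")
  if (is.null(grid))
    grid <- seq(min(points$delta), max(points$delta), length.out = 101)
  fit <- tryCatch(suppressWarnings(
    stats::glm(cbind(rejections, replicates - rejections) ~ delta,
               family = stats::binomial(link = "probit"), data = points)),
    error = function(e) NULL)
  fallback <- is.null(fit) || !all(is.finite(stats::coef(fit))) ||
    !fit$converged
  if (fallback) {
    warning("probit fit failed (separation?); returning step-function fallback")
    raw <- points[order(points$delta), ]
    f <- stats::stepfun(raw$delta, c(raw$rejections[1] / raw$replicates[1],
                                     raw$rejections / raw$replicates))
    power <- f(grid)
    coefs <- c(NA_real_, NA_real_)
  } else {
    power <- stats::predict(fit, data.frame(delta = grid), type = "response")
    coefs <- stats::coef(fit)
  }
  structure(list(points = points,
                 grid = data.frame(delta = grid, power = as.numeric(power)),
                 coefficients = coefs, fallback = fallback),
            class = "power_curve")
}
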