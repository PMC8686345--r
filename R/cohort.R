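# Synthetic legacy cohorts.
#
# The two resampling engines need source populations with the statistical
# structure of the legacy trial datasets: a pooled mild-to-moderate AD cohort
# (n = 641, visits 0/3/6/9/12 months, 12-month change-score pooled SD 6.0)
# and an MCI cohort (n = 769, visits 0/3/6/12/18 months, ~75% completers,
# 18-month change-score pooled SD 4.7). Trajectories follow a linear
# random-intercept / random-slope Gaussian model with independent residual
# noise, which makes the per-subject least-squares slope (the construct-1
# sampling statistic) a sufficient summary of progression.

#' Specify a synthetic source cohort
#'
#' Parameters of the random-intercept/random-slope generator. The implied
#' endpoint change-score SD of the model is
#' `sqrt((H * slope_sd)^2 + 2 * residual_sd^2)` where `H` is the last
#' scheduled month; [calibrate_change_sd()] rescales `slope_sd` and
#' `residual_sd` proportionally so this matches `target_change_sd`.
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param visit_schedule Strictly increasing visit months, first element 0.
#' @param baseline_mean,baseline_sd ADAS-cog baseline distribution (points).
#' @param slope_mean,slope_sd Latent decline rate distribution (points/month;
#'   positive mean = worsening).
#' @param residual_sd Within-visit measurement noise SD (points).
#' @param completer_fraction Proportion of subjects completing the schedule.
#' @param dropout_time_distribution Probability weights over the
#'   `length(visit_schedule) - 1` inter-visit intervals in which dropout
#'   occurs; default uniform.
#' @param target_change_sd Optional endpoint change-score SD the cohort
#'   should be calibrated to.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, visit_schedule,
                        baseline_mean = 25, baseline_sd = 8,
                        slope_mean = 0.45, slope_sd = 0.25,
                        residual_sd = 3, completer_fraction = 1,
                        dropout_time_distribution = NULL,
                        target_change_sd = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 0) stop("n_subjects must be >= 0")
  if (length(visit_schedule) < 2) stop("visit_schedule needs >= 2 visits")
  if (visit_schedule[1] != 0) stop("visit_schedule must start at month 0")
  if (is.unsorted(visit_schedule, strictly = TRUE))
    stop("visit_schedule must be strictly increasing")
  for (nm in c("baseline_sd", "slope_sd", "residual_sd")) {
    val <- get(nm)
    if (!is.finite(val) || val < 0) stop(nm, " must be a finite SD >= 0")
  }
  if (completer_fraction < 0 || completer_fraction > 1)
    stop("completer_fraction must lie in [0, 1]")
  ni <- length(visit_schedule) - 1
  if (is.null(dropout_time_distribution))
    dropout_time_distribution <- rep(1 / ni, ni)
  if (length(dropout_time_distribution) != ni ||
      any(dropout_time_distribution < 0) ||
      abs(sum(dropout_time_distribution) - 1) > 1e-8)
    stop("dropout_time_distribution must be ", ni,
         " non-negative weights summing to 1")
  structure(list(n_subjects = n_subjects,
                 visit_schedule = as.numeric(visit_schedule),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 residual_sd = residual_sd,
                 completer_fraction = completer_fraction,
                 dropout_time_distribution = dropout_time_distribution,
                 target_change_sd = target_change_sd),
            class = "cohort_spec")
}

#' Implied endpoint change-score SD of a cohort spec
#'
#' Closed form for the random-slope model: the change from baseline to the
#' last scheduled month `H` is `H * b1 + e_H - e_0`, so its SD is
#' `sqrt((H * slope_sd)^2 + 2 * residual_sd^2)`.
#'
#' @param spec A `cohort_spec`.
#' @return SD in ADAS-cog points.
#' @export
implied_change_sd <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  H <- max(spec$visit_schedule)
  sqrt((H * spec$slope_sd)^2 + 2 * spec$residual_sd^2)
}

#' Calibrate a cohort spec to its target change-score SD
#'
#' Rescales `slope_sd` and `residual_sd` by a common factor so the implied
#' endpoint change-score SD equals `spec$target_change_sd` (the pooled SDs
#' the power analyses fix at 6.0 and 4.7 points for the two constructs).
#'
#' @param spec A `cohort_spec` with a positive `target_change_sd`.
#' @return A calibrated `cohort_spec`.
#' @export
calibrate_change_sd <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  target <- spec$target_change_sd
  if (is.null(target) || !is.finite(target) || target <= 0)
    stop("target_change_sd must be a positive number")
  cur <- implied_change_sd(spec)
  if (cur == 0)
    stop("infeasible target: slope_sd and residual_sd are both zero")
  f <- target / cur
  spec$slope_sd <- f * spec$slope_sd
  spec$residual_sd <- f * spec$residual_sd
  spec
}

#' Preset cohort specs for the two trial constructs
#'
#' `cohort_spec_symptomatic()` emulates the pooled mild-to-moderate AD
#' source (641 completers, visits 0/3/6/9/12, 12-month change SD calibrated
#' to 6.0). `cohort_spec_mci()` emulates the MCI source (769 subjects,
#' visits 0/3/6/12/18, 75% completers, 18-month change SD calibrated to
#' 4.7). Location/scale defaults other than the calibrated change SD are
#' conventions; see the methods vignette.
#'
#' @param n_subjects Cohort size override.
#' @return A calibrated `cohort_spec`.
#' @export
cohort_spec_symptomatic <- function(n_subjects = 641) {
  calibrate_change_sd(cohort_spec(
    n_subjects, c(0, 3, 6, 9, 12),
    baseline_mean = 25, baseline_sd = 8,
    slope_mean = 0.45, slope_sd = 0.25, residual_sd = 3,
    completer_fraction = 1, target_change_sd = 6.0))
}

#' @rdname cohort_spec_symptomatic
#' @export
cohort_spec_mci <- function(n_subjects = 769) {
  calibrate_change_sd(cohort_spec(
    n_subjects, c(0, 3, 6, 12, 18),
    baseline_mean = 18, baseline_sd = 6.5,
    slope_mean = 0.15, slope_sd = 0.18, residual_sd = 2.5,
    completer_fraction = 0.75, target_change_sd = 4.7))
}

#' Generate a synthetic legacy cohort
#'
#' Draws `spec$n_subjects` ADAS-cog trajectories from the random-intercept /
#' random-slope model on the scheduled visit grid, together with completer /
#' dropout status. Each subject consumes an independent, counter-based
#' substream of `seed` (see [substream_seed()]), so the draw for subject i
#' is unchanged by adding or removing other subjects.
#'
#' When `spec$target_change_sd` is set and `standardize = TRUE` (default),
#' the realized cohort is additionally standardized so its *empirical*
#' complete-case endpoint change SD equals the target exactly: the legacy
#' datasets' pooled change SDs are fixed quantities of those datasets, and a
#' finite synthetic stand-in would otherwise carry an extra ±2-3% SD
#' sampling wobble into every downstream power estimate. Standardization
#' rescales every subject's within-trajectory deviations
#' (`y(t) <- y(0) + f * (y(t) - y(0))`) by a single factor f.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @param standardize Pin the empirical endpoint change SD at
#'   `spec$target_change_sd` (ignored when no target is set).
#' @return A `trajectory_panel` with latent intercepts/slopes stored and all
#'   arms `"unassigned"`.
#' @export
generate_legacy_cohort <- function(spec, seed, standardize = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  sched <- spec$visit_schedule
  k <- length(sched)
  if (n == 0)
    return(new_trajectory_panel(empty_subjects(), empty_visits(), sched,
                                spec$residual_sd))
  cw <- cumsum(spec$dropout_time_distribution)
  b0 <- numeric(n); b1 <- numeric(n)
  comp <- logical(n); dm <- rep(NA_real_, n)
  E <- matrix(0, n, k)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, "cohort", i))
    z <- stats::rnorm(2 + k)
    u <- stats::runif(3)
    b0[i] <- spec$baseline_mean + spec$baseline_sd * z[1]
    b1[i] <- spec$slope_mean + spec$slope_sd * z[2]
    E[i, ] <- spec$residual_sd * z[3:(2 + k)]
    comp[i] <- u[1] <= spec$completer_fraction
    if (!comp[i]) {
      j <- which(u[2] <= cw + 1e-12)[1]
      dm[i] <- sched[j] + u[3] * (sched[j + 1] - sched[j])
    }
  }
  ids <- sprintf("C%04d", seq_len(n))
  subjects <- data.frame(
    subject_id = ids, arm = "unassigned", completer = comp,
    dropout_month = dm, covid_dropout = FALSE, accrual_month = NA_real_,
    latent_intercept = b0, latent_slope = b1, stringsAsFactors = FALSE)
  tmat <- matrix(sched, n, k, byrow = TRUE)
  y <- b0 + outer(b1, sched) + E
  vm <- as.vector(t(tmat))
  yv <- as.vector(t(y))
  dmv <- rep(dm, each = k)
  observed <- is.na(dmv) | vm <= dmv
  visits <- data.frame(
    subject_id = rep(ids, each = k),
    visit_month = vm,
    adas_cog = ifelse(observed, yv, NA_real_),
    observed = observed,
    observation_mode = ifelse(observed, "in_clinic", "missing"),
    stringsAsFactors = FALSE)
  out <- new_trajectory_panel(subjects, visits, sched, spec$residual_sd)
  if (standardize && !is.null(spec$target_change_sd) &&
      is.finite(spec$target_change_sd)) {
    ch <- endpoint_changes(out, max(sched))
    if (nrow(ch) >= 2 && stats::sd(ch$change) > 0) {
      f <- spec$target_change_sd / stats::sd(ch$change)
      base <- rep(out$visits$adas_cog[out$visits$visit_month == 0], each = k)
      out$visits$adas_cog <- base + f * (out$visits$adas_cog - base)
      out$subjects$latent_slope <- f * out$subjects$latent_slope
      attr(out, "residual_sd") <- f * spec$residual_sd
    }
  }
  validate_trajectory_panel(out)
  out
}

#' Summarize a cohort panel
#'
#' Per-visit observed counts, completer fraction, and endpoint change-score
#' mean/SD (complete cases at the last scheduled month).
#'
#' @param panel A `trajectory_panel`.
#' @return A list of class `cohort_summary` with elements `per_visit`
#'   (data frame), `n_subjects`, `completer_fraction`,
#'   `endpoint_change_mean`, `endpoint_change_sd`.
#' @export
summarize_cohort <- function(panel) {
  stopifnot(is_trajectory_panel(panel))
  sched <- panel_schedule(panel)
  n <- n_panel_subjects(panel)
  if (n == 0) {
    return(structure(list(
      per_visit = data.frame(visit_month = numeric(0),
                             n_observed = integer(0),
                             fraction_observed = numeric(0)),
      n_subjects = 0L, completer_fraction = NA_real_,
      endpoint_change_mean = NA_real_, endpoint_change_sd = NA_real_),
      class = "cohort_summary"))
  }
  ch <- endpoint_changes(panel, panel_horizon(panel))
  v <- panel$visits
  per_visit <- do.call(rbind, lapply(sched, function(m) {
    o <- sum(v$observed[v$visit_month == m])
    data.frame(visit_month = m, n_observed = o, fraction_observed = o / n)
  }))
  structure(list(
    per_visit = per_visit,
    n_subjects = n,
    completer_fraction = mean(panel$subjects$completer),
    endpoint_change_mean = if (nrow(ch)) mean(ch$change) else NA_real_,
    endpoint_change_sd = if (nrow(ch) > 1) stats::sd(ch$change) else NA_real_),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d, completers = %.1f%%\n", x$n_subjects,
              100 * x$completer_fraction))
  cat(sprintf("endpoint change: mean %.2f, SD %.2f\n",
              x$endpoint_change_mean, x$endpoint_change_sd))
  print(x$per_visit, row.names = FALSE)
  invisible(x)
}
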