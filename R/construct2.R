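# Construct-2 engine: disease-modification-trial datasets.
#
# The 18-month construct resamples trial datasets from the MCI source by
# stratified sampling with replacement (75% completers), assigns each
# subject an accrual stage (how far through the schedule they were when the
# stay-at-home order hit), overlays a 24% pandemic dropout at the pause
# date, and injects a quadratic-in-time treatment effect into the active
# arm.

#' Accrual plan
#'
#' Stage fractions describing how far subjects had progressed through the
#' visit schedule at the pause. `completed_through` is the last visit month
#' a stage had completed; fractions must sum to 1.
#'
#' @param completed_through Stage months, one per stage.
#' @param fraction Stage proportions summing to 1.
#' @return A data frame of class `accrual_plan`, sorted by descending month.
#' @export
accrual_plan <- function(completed_through, fraction) {
  if (length(completed_through) != length(fraction))
    stop("completed_through and fraction must have equal length")
  if (any(fraction < 0) || abs(sum(fraction) - 1) > 1e-8)
    stop("fractions must be non-negative and sum to 1")
  o <- order(completed_through, decreasing = TRUE)
  out <- data.frame(completed_through = completed_through[o],
                    fraction = fraction[o])
  class(out) <- c("accrual_plan", "data.frame")
  out
}

#' Preset accrual plans
#'
#' Stage fractions at the stay-at-home order. For the disease-modification
#' construct the cumulative completion fractions 80/50/25/12% through
#' months 3/6/12/18 give exclusive stages 20/30/25/13/12% for months
#' 0/3/6/12/18. For the symptomatic construct, 97.5/67/45/22% through
#' months 3/6/9/12 give 2.5/30.5/22/23/22% for months 0/3/6/9/12.
#'
#' @return An `accrual_plan`.
#' @export
accrual_plan_disease_modification <- function() {
  accrual_plan(c(18, 12, 6, 3, 0), c(0.12, 0.13, 0.25, 0.30, 0.20))
}

#' @rdname accrual_plan_disease_modification
#' @export
accrual_plan_symptomatic <- function() {
  accrual_plan(c(12, 9, 6, 3, 0), c(0.22, 0.23, 0.22, 0.305, 0.025))
}

#' Stratified resampling with replacement
#'
#' Draws a trial dataset of `n_total` subjects from the source cohort:
#' `round(completer_fraction * n_total)` from completers and the remainder
#' from pre-endpoint dropouts (whose dropout times therefore match the
#' source distribution). Resampled subjects receive fresh ids and are
#' randomized 1:1 to the two arms.
#'
#' @param panel Source `trajectory_panel` with completer flags.
#' @param n_total Trial size.
#' @param completer_fraction Completer stratum proportion (default 0.75).
#' @param seed Integer seed.
#' @return A `trajectory_panel` with arms assigned and `source_id` recorded.
#' @export
stratified_resample <- function(panel, n_total, completer_fraction = 0.75,
                                seed = 1) {
  stopifnot(is_trajectory_panel(panel))
  comp <- which(panel$subjects$completer)
  drop_ <- which(!panel$subjects$completer)
  n_comp <- round(completer_fraction * n_total)
  n_drop <- n_total - n_comp
  if (n_comp > 0 && length(comp) == 0) stop("empty completer stratum")
  if (n_drop > 0 && length(drop_) == 0) stop("empty dropout stratum")
  set.seed(substream_seed(seed, "resample"))
  idx <- c(comp[sample.int(length(comp), n_comp, replace = TRUE)],
           if (n_drop > 0) drop_[sample.int(length(drop_), n_drop,
                                            replace = TRUE)])
  idx <- idx[sample.int(n_total)]
  out <- panel_subset(panel, idx, sprintf("S%05d", seq_len(n_total)))
  arm <- rep(c("placebo", "active"), length.out = n_total)
  out$subjects$arm <- arm[sample.int(n_total)]
  out
}

#' Assign accrual stages
#'
#' Labels each subject with the last visit month completed at the pause.
#' Stage counts are the plan fractions times `n` (largest-remainder
#' rounding). With `respect_completion = TRUE` (the disease-modification
#' default) a stage can only be assigned to subjects whose observed data
#' actually extend through the stage month, so "12% completed the 18-month
#' endpoint" means those subjects have endpoint data; with `FALSE`
#' (construct-1 convention) stages are assigned independently of dropout.
#'
#' @param panel A `trajectory_panel`.
#' @param plan An `accrual_plan`.
#' @param seed Integer seed.
#' @param respect_completion Constrain stages to subjects with data through
#'   the stage month.
#' @return The panel with `accrual_month` filled in.
#' @export
assign_accrual <- function(panel, plan, seed = 1, respect_completion = TRUE) {
  stopifnot(is_trajectory_panel(panel), inherits(plan, "accrual_plan"))
  n <- n_panel_subjects(panel)
  if (n == 0) return(panel)
  raw <- plan$fraction * n
  cnt <- floor(raw)
  shortfall <- n - sum(cnt)
  if (shortfall > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(shortfall)]] <- cnt[o[seq_len(shortfall)]] + 1
  }
  k <- length(panel_schedule(panel))
  v <- panel$visits
  lom <- tapply(ifelse(v$observed, v$visit_month, -Inf),
                rep(seq_len(n), each = k), max)
  set.seed(substream_seed(seed, "accrual"))
  stage <- rep(NA_real_, n)
  remaining <- seq_len(n)
  carry <- 0
  for (j in seq_len(nrow(plan))) {
    want <- cnt[j] + carry
    if (j == nrow(plan)) {
      pick <- remaining
    } else {
      elig <- if (respect_completion)
        remaining[lom[remaining] >= plan$completed_through[j] - 1e-9]
      else remaining
      take <- min(want, length(elig))
      pick <- if (take > 0) elig[sample.int(length(elig), take)] else integer(0)
    }
    carry <- want - length(pick)
    if (j == nrow(plan)) carry <- 0
    stage[pick] <- plan$completed_through[j]
    remaining <- setdiff(remaining, pick)
  }
  panel$subjects$accrual_month <- stage
  panel
}

#' Overlay pandemic dropout at the pause
#'
#' Selects `round(rate * n)` subjects uniformly from all subjects and
#' deletes their observations after the last pre-pause visit (their accrual
#' month). For subjects who had already completed the schedule this is a
#' no-op deletion. The `covid_dropout` flag keeps pandemic-attributed and
#' natural dropout distinguishable.
#'
#' @param panel A `trajectory_panel` with accrual assigned.
#' @param rate Proportion discontinuing at the pause (default 0.24).
#' @param seed Integer seed.
#' @return A `trajectory_panel`.
#' @export
overlay_covid_dropout <- function(panel, rate = 0.24, seed = 1) {
  stopifnot(is_trajectory_panel(panel))
  if (anyNA(panel$subjects$accrual_month))
    stop("accrual must be assigned before the pandemic dropout overlay")
  n <- n_panel_subjects(panel)
  n_drop <- round(rate * n)
  if (n_drop == 0) return(panel)
  set.seed(substream_seed(seed, "covid"))
  pick <- sample.int(n, n_drop)
  panel$subjects$covid_dropout[pick] <- TRUE
  k <- length(panel_schedule(panel))
  flag <- logical(n); flag[pick] <- TRUE
  am <- rep(panel$subjects$accrual_month, each = k)
  del <- rep(flag, each = k) & panel$visits$visit_month > am + 1e-9
  panel$visits$observed[del] <- FALSE
  panel$visits$adas_cog[del] <- NA_real_
  panel$visits$observation_mode[del] <- "missing"
  panel
}

#' Quadratic treatment effect
#'
#' The disease-modification effect grows quadratically with time on
#' treatment: `effect(t) = delta * (t / horizon)^2`, so it is 0 at baseline
#' and exactly `delta` at the endpoint.
#'
#' @param delta Between-arm difference in endpoint change (points).
#' @param horizon Endpoint month (default 18).
#' @return An object of class `treatment_effect`.
#' @export
treatment_effect <- function(delta, horizon = 18) {
  if (!is.finite(delta) || delta < 0) stop("delta must be >= 0")
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  structure(list(delta = delta, horizon = horizon), class = "treatment_effect")
}

#' @rdname treatment_effect
#' @param effect A `treatment_effect`.
#' @param t Months on treatment.
#' @return `effect_at()`: the score reduction (points) at time `t`.
#' @export
effect_at <- function(effect, t) {
  stopifnot(inherits(effect, "treatment_effect"))
  effect$delta * (t / effect$horizon)^2
}

#' Inject the treatment effect into the active arm
#'
#' Lowers (improves) the active arm's raw ADAS-cog score at month t by
#' `effect_at(effect, t)`; placebo scores are untouched. Because the effect
#' is 0 at baseline, this induces exactly the intended between-arm
#' difference in endpoint change scores.
#'
#' @param panel A `trajectory_panel` with arms assigned.
#' @param effect A `treatment_effect`.
#' @return A `trajectory_panel`.
#' @export
apply_quadratic_effect <- function(panel, effect) {
  stopifnot(is_trajectory_panel(panel), inherits(effect, "treatment_effect"))
  if (all(panel$subjects$arm == "unassigned"))
    stop("arms must be assigned before applying the treatment effect")
  k <- length(panel_schedule(panel))
  active <- rep(panel$subjects$arm == "active", each = k)
  panel$visits$adas_cog[active] <- panel$visits$adas_cog[active] -
    effect_at(effect, panel$visits$visit_month[active])
  panel
}
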