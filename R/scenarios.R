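# Disruption scenarios.
#
# A 6-month pause in in-clinic visits hits each subject at their accrual
# stage m (last visit month completed). Calendar mechanics are mapped to
# each subject's study clock as follows, the only mapping consistent with
# every completion statement in the scenario definitions:
#   symptomatic construct        : visits due in the OPEN interval
#     (m, m + 6) fall in the pause (a visit due exactly at m + 6 lands at
#     pause end and is kept, e.g. the stage-6 group keeps month 12);
#   disease-modification construct: visits due in the HALF-OPEN interval
#     (m, m + 6] fall in the pause (e.g. the stage-12 group misses month 18,
#     the stage-0 group misses months 3 and 6).
# Scenario 1 truncates at the pause; scenario 2 deletes in-pause visits and
# resumes afterwards; scenario 3 extends the endpoint window by 3 months
# (symptomatic) or assesses in-pause visits remotely with a +0.5-point
# worsening offset (disease modification).

#' Specify a disruption scenario
#'
#' @param construct `"symptomatic"` (12-month construct) or
#'   `"disease_modification"` (18-month construct).
#' @param scenario_id 0 (as planned), 1 (truncate at pause), 2 (pause and
#'   resume, fixed windows), 3 (window extension / remote assessment).
#' @param pause_duration Pause length in months (default 6).
#' @param window_extension Endpoint window extension in months; only used by
#'   the symptomatic scenario 3 (default 3 there, else 0). Must be 0 or 3.
#' @param remote_offset Score worsening applied to remotely assessed visits;
#'   only used by the disease-modification scenario 3 (default 0.5 there).
#' @param medication_paused Whether study medication stops during the pause
#'   (informational; no efficacy-washout model is applied — see the methods
#'   vignette).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(construct = c("symptomatic", "disease_modification"),
                          scenario_id, pause_duration = 6,
                          window_extension = NULL, remote_offset = NULL,
                          medication_paused = NULL) {
  construct <- match.arg(construct)
  if (!scenario_id %in% 0:3) stop("scenario_id must be one of 0, 1, 2, 3")
  if (pause_duration < 0) stop("pause_duration must be >= 0")
  if (is.null(window_extension))
    window_extension <- if (construct == "symptomatic" && scenario_id == 3) 3 else 0
  if (!window_extension %in% c(0, 3)) stop("window_extension must be 0 or 3")
  if (is.null(remote_offset))
    remote_offset <- if (construct == "disease_modification" && scenario_id == 3)
      0.5 else 0
  if (is.null(medication_paused))
    medication_paused <- construct == "disease_modification" && scenario_id %in% 2:3
  structure(list(construct = construct, scenario_id = as.integer(scenario_id),
                 pause_duration = pause_duration,
                 window_extension = window_extension,
                 remote_offset = remote_offset,
                 medication_paused = medication_paused),
            class = "scenario_spec")
}

delete_rows <- function(panel, del) {
  panel$visits$observed[del] <- FALSE
  panel$visits$adas_cog[del] <- NA_real_
  panel$visits$observation_mode[del] <- "missing"
  panel
}

require_accrual <- function(panel) {
  if (anyNA(panel$subjects$accrual_month))
    stop("accrual stages must be assigned before applying a scenario")
}

#' Apply a disruption scenario to a symptomatic-construct dataset
#'
#' Scenario 0 returns the dataset unchanged. Scenario 1 deletes all
#' observations after each subject's accrual month. Scenario 2 deletes
#' visits due strictly inside the pause window (see the pause-window
#' convention at the top of this file). Scenario 3 additionally reschedules
#' a missed endpoint to `min(m + pause, horizon + window_extension)` months,
#' generating the rescheduled value by extrapolating the subject's latent
#' trajectory from the endpoint with fresh residual noise.
#'
#' @param panel A `trajectory_panel` with accrual assigned (and, in the
#'   intended pipeline, the uniform dropout filter already applied).
#' @param spec A `scenario_spec` with `construct = "symptomatic"`.
#' @param seed Integer seed for the rescheduled-assessment noise.
#' @return A `trajectory_panel`.
#' @export
apply_scenario_construct1 <- function(panel, spec, seed = 1) {
  stopifnot(is_trajectory_panel(panel), inherits(spec, "scenario_spec"))
  if (spec$construct != "symptomatic")
    stop("scenario spec is for the ", spec$construct, " construct")
  if (spec$scenario_id == 0) return(panel)
  require_accrual(panel)
  k <- length(panel_schedule(panel))
  H <- panel_horizon(panel)
  v <- panel$visits
  m <- rep(panel$subjects$accrual_month, each = k)
  if (spec$scenario_id == 1)
    return(delete_rows(panel, v$observed & v$visit_month > m + 1e-9))
  in_pause <- v$observed & v$visit_month > m + 1e-9 &
    v$visit_month < m + spec$pause_duration - 1e-9
  if (spec$scenario_id == 2) return(delete_rows(panel, in_pause))
  # scenario 3: rescue endpoints missed in the pause before deleting
  sm <- panel$subjects$accrual_month
  endpoint_row <- seq_len(n_panel_subjects(panel)) * k  # last grid row
  missed_end <- sm > H - spec$pause_duration + 1e-9 & sm < H - 1e-9 &
    v$observed[endpoint_row]
  if (any(missed_end)) {
    rs <- attr(panel, "residual_sd")
    if (!is.finite(rs)) rs <- 0
    rows <- endpoint_row[missed_end]
    new_month <- pmin(sm[missed_end] + spec$pause_duration,
                      H + spec$window_extension)
    set.seed(substream_seed(seed, "reschedule"))
    newval <- v$adas_cog[rows] +
      panel$subjects$latent_slope[missed_end] * (new_month - H) +
      stats::rnorm(length(rows), 0, rs)
    in_pause[rows] <- FALSE
    panel$visits$visit_month[rows] <- new_month
    panel$visits$adas_cog[rows] <- newval
  }
  delete_rows(panel, in_pause)
}

#' Apply a disruption scenario to a disease-modification dataset
#'
#' Scenario 0 returns the dataset unchanged (the intended pipeline also
#' omits the pandemic dropout overlay for scenario 0). Scenario 1 truncates
#' at the pause. Scenario 2 deletes visits due in the half-open pause window
#' `(m, m + 6]`. Scenario 3 keeps those visits but marks them remote and
#' worsens their scores by `remote_offset` points.
#'
#' @param panel A `trajectory_panel` with accrual (and for scenarios 1-3
#'   the pandemic dropout overlay) applied.
#' @param spec A `scenario_spec` with `construct = "disease_modification"`.
#' @return A `trajectory_panel`.
#' @export
apply_scenario_construct2 <- function(panel, spec) {
  stopifnot(is_trajectory_panel(panel), inherits(spec, "scenario_spec"))
  if (spec$construct != "disease_modification")
    stop("scenario spec is for the ", spec$construct, " construct")
  if (spec$scenario_id == 0) return(panel)
  require_accrual(panel)
  k <- length(panel_schedule(panel))
  v <- panel$visits
  m <- rep(panel$subjects$accrual_month, each = k)
  if (spec$scenario_id == 1)
    return(delete_rows(panel, v$observed & v$visit_month > m + 1e-9))
  in_pause <- v$observed & v$visit_month > m + 1e-9 &
    v$visit_month <= m + spec$pause_duration + 1e-9
  if (spec$scenario_id == 2) return(delete_rows(panel, in_pause))
  panel$visits$observation_mode[in_pause] <- "remote"
  panel$visits$adas_cog[in_pause] <- panel$visits$adas_cog[in_pause] +
    spec$remote_offset
  panel
}

#' @rdname apply_scenario_construct1
#' @export
apply_scenario <- function(panel, spec, seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$construct == "symptomatic")
    apply_scenario_construct1(panel, spec, seed)
  else apply_scenario_construct2(panel, spec)
}

#' Visit disposition report
#'
#' Classifies every (subject, scheduled visit) record of a scenario-filtered
#' dataset relative to the pause window and tabulates counts per visit slot:
#' `completed_pre_pause`, `remote`, `rescheduled_extended`,
#' `resumed_post_pause`, `missed_in_pause` (due in the pause and not
#' observed), and `missing_other` (natural or pandemic dropout, or deleted
#' outside the pause window).
#'
#' @param panel A scenario-filtered `trajectory_panel` with accrual set.
#' @param spec The `scenario_spec` that produced it.
#' @return A data frame with columns `visit_month` (nominal slot),
#'   `disposition`, `count`, `fraction` (of subjects).
#' @export
disposition_report <- function(panel, spec) {
  stopifnot(is_trajectory_panel(panel), inherits(spec, "scenario_spec"))
  n <- n_panel_subjects(panel)
  k <- length(panel_schedule(panel))
  H <- panel_horizon(panel)
  v <- panel$visits
  m <- rep(panel$subjects$accrual_month, each = k)
  slot <- rep(panel_schedule(panel), times = n)  # nominal grid slot
  open_upper <- spec$construct == "symptomatic"
  due_in_pause <- if (spec$scenario_id == 0) rep(FALSE, nrow(v)) else if (open_upper)
    slot > m + 1e-9 & slot < m + spec$pause_duration - 1e-9
  else slot > m + 1e-9 & slot <= m + spec$pause_duration + 1e-9
  dm <- rep(panel$subjects$dropout_month, each = k)
  cv <- rep(panel$subjects$covid_dropout, each = k)
  dropped <- (!is.na(dm) & slot > dm) | (cv & slot > m + 1e-9)
  cls <- ifelse(!v$observed,
                ifelse(!dropped & due_in_pause, "missed_in_pause",
                       "missing_other"),
                ifelse(v$observation_mode == "remote", "remote",
                       ifelse(v$visit_month > H + 1e-9, "rescheduled_extended",
                              ifelse(spec$scenario_id > 0 & slot > m + 1e-9,
                                     "resumed_post_pause",
                                     "completed_pre_pause"))))
  tab <- as.data.frame(table(visit_month = slot, disposition = cls),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab$visit_month <- as.numeric(tab$visit_month)
  tab <- tab[tab$count > 0, , drop = FALSE]
  tab$fraction <- tab$count / n
  tab <- tab[order(tab$visit_month, tab$disposition), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
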