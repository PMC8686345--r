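# Long-format container for simulated ADAS-cog trial data.
#
# A trajectory_panel holds two aligned tables:
#   $subjects - one row per subject (id, arm, completer, dropout_month,
#               covid_dropout, accrual_month, latent_intercept, latent_slope)
#   $visits   - one row per (subject, scheduled visit), sorted in subjects
#               order with exactly length(schedule) rows per subject.
# Unobserved visits keep their grid row with observed = FALSE and an NA
# score, so subject blocks are directly indexable. Construct-1 scenario 3
# may move the endpoint row to a later month, but never changes row counts.

#' Construct a trajectory panel
#'
#' Low-level constructor for the package's universal longitudinal dataset
#' carrier. Most users obtain panels from [generate_legacy_cohort()] and the
#' construct engines rather than calling this directly.
#'
#' @param subjects Data frame with one row per subject; must contain
#'   `subject_id`, `arm`, `completer`, `dropout_month`, `covid_dropout`,
#'   `accrual_month`, `latent_intercept`, `latent_slope`.
#' @param visits Data frame with one row per (subject, scheduled visit),
#'   sorted by subject (in `subjects` order) then month; must contain
#'   `subject_id`, `visit_month`, `adas_cog`, `observed`, `observation_mode`.
#' @param schedule Numeric vector of scheduled visit months (first element 0).
#' @param residual_sd Residual SD of the generating model, carried along so
#'   scenario transforms can draw fresh measurement noise.
#' @return An object of class `trajectory_panel`.
#' @export
new_trajectory_panel <- function(subjects, visits, schedule,
                                 residual_sd = NA_real_) {
  structure(list(subjects = subjects, visits = visits),
            schedule = as.numeric(schedule),
            residual_sd = residual_sd,
            class = "trajectory_panel")
}

#' @rdname new_trajectory_panel
#' @param x Object to test.
#' @export
is_trajectory_panel <- function(x) inherits(x, "trajectory_panel")

#' Panel accessors
#'
#' @param panel A `trajectory_panel`.
#' @return `panel_schedule()` the scheduled visit months; `panel_horizon()`
#'   the endpoint month (last scheduled visit); `n_panel_subjects()` the
#'   number of subjects.
#' @export
panel_schedule <- function(panel) attr(panel, "schedule")

#' @rdname panel_schedule
#' @export
panel_horizon <- function(panel) {
  s <- panel_schedule(panel)
  if (length(s)) max(s) else NA_real_
}

#' @rdname panel_schedule
#' @export
n_panel_subjects <- function(panel) nrow(panel$subjects)

empty_subjects <- function() {
  data.frame(subject_id = character(0), arm = character(0),
             completer = logical(0), dropout_month = numeric(0),
             covid_dropout = logical(0), accrual_month = numeric(0),
             latent_intercept = numeric(0), latent_slope = numeric(0),
             stringsAsFactors = FALSE)
}

empty_visits <- function() {
  data.frame(subject_id = character(0), visit_month = numeric(0),
             adas_cog = numeric(0), observed = logical(0),
             observation_mode = character(0), stringsAsFactors = FALSE)
}

#' Validate trajectory panel invariants
#'
#' Checks structural invariants: unique subject ids, a fixed visit grid
#' (one row per scheduled visit per subject), an observed baseline for every
#' subject, finite observed scores, and no observed record after a subject's
#' dropout month (natural or pandemic-attributed).
#'
#' @param panel A `trajectory_panel`.
#' @return `panel`, invisibly; stops on violation.
#' @export
validate_trajectory_panel <- function(panel) {
  stopifnot(is_trajectory_panel(panel))
  s <- panel$subjects
  v <- panel$visits
  k <- length(panel_schedule(panel))
  if (anyDuplicated(s$subject_id)) stop("duplicate subject ids")
  if (nrow(v) != nrow(s) * k) stop("visit grid is not n_subjects x schedule")
  if (nrow(s) == 0) return(invisible(panel))
  if (!identical(v$subject_id, rep(s$subject_id, each = k)))
    stop("visits are not in subject-block order")
  base <- v[v$visit_month == 0, , drop = FALSE]
  if (!all(base$observed)) stop("baseline visit not observed for all subjects")
  if (any(!is.finite(v$adas_cog[v$observed]))) stop("non-finite observed score")
  dm <- rep(s$dropout_month, each = k)
  bad <- v$observed & !is.na(dm) & v$visit_month > dm + 1e-9
  if (any(bad)) stop("observed record after dropout month")
  invisible(panel)
}

#' Subset or resample subjects of a panel
#'
#' Builds a new panel from subject row indices (possibly with duplicates, as
#' in bootstrap resampling). Visit blocks are carried over by grid position.
#'
#' @param panel A `trajectory_panel`.
#' @param idx Integer vector of subject row indices (duplicates allowed).
#' @param new_ids Optional character vector of replacement subject ids, one
#'   per entry of `idx`; required when `idx` contains duplicates.
#' @return A `trajectory_panel`.
#' @export
panel_subset <- function(panel, idx, new_ids = NULL) {
  k <- length(panel_schedule(panel))
  s <- panel$subjects[idx, , drop = FALSE]
  vi <- rep((idx - 1L) * k, each = k) + seq_len(k)
  v <- panel$visits[vi, , drop = FALSE]
  if (is.null(new_ids) && anyDuplicated(idx))
    stop("new_ids required when resampling with duplicates")
  if (!is.null(new_ids)) {
    if (!("source_id" %in% names(s))) s$source_id <- s$subject_id
    s$subject_id <- new_ids
    v$subject_id <- rep(new_ids, each = k)
  }
  rownames(s) <- NULL
  rownames(v) <- NULL
  new_trajectory_panel(s, v, panel_schedule(panel), attr(panel, "residual_sd"))
}

#' @export
print.trajectory_panel <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("<trajectory_panel> %d subjects, schedule [%s] months\n",
              nrow(s), paste(panel_schedule(x), collapse = ", ")))
  if (nrow(s)) {
    cat(sprintf("  arms: %s\n",
                paste(sprintf("%s=%d", names(table(s$arm)), table(s$arm)),
                      collapse = ", ")))
    cat(sprintf("  completers: %.1f%%; observed records: %d\n",
                100 * mean(s$completer), sum(x$visits$observed)))
  }
  invisible(x)
}

#' Serialize a panel to long-format CSV
#'
#' Writes one row per (subject, scheduled visit) with columns `subject_id`,
#' `arm`, `accrual_index`, `visit_month`, `adas_cog`, `observed`,
#' `observation_mode`, `dropout_month`, `completer`. Missing numeric fields
#' are written empty. [read_panel_csv()] reconstructs a panel from such a
#' file; latent trajectory fields are not part of the interchange format and
#' are dropped on round-trip.
#'
#' @param panel A `trajectory_panel`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  s <- panel$subjects
  k <- length(panel_schedule(panel))
  v <- panel$visits
  out <- data.frame(
    subject_id = v$subject_id,
    arm = rep(s$arm, each = k),
    accrual_index = rep(s$accrual_month, each = k),
    visit_month = v$visit_month,
    adas_cog = v$adas_cog,
    observed = v$observed,
    observation_mode = v$observation_mode,
    dropout_month = rep(s$dropout_month, each = k),
    completer = rep(s$completer, each = k),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @param residual_sd Residual SD to attach to the reconstructed panel.
#' @export
read_panel_csv <- function(path, residual_sd = NA_real_) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  # grid months taken from the first subject's block (rescheduled endpoint
  # months of later subjects do not alter the nominal schedule)
  schedule <- d$visit_month[d$subject_id == d$subject_id[1]]
  if (is.unsorted(schedule)) schedule <- sort(schedule)
  first <- d[!duplicated(d$subject_id), , drop = FALSE]
  subjects <- data.frame(
    subject_id = first$subject_id,
    arm = first$arm,
    completer = as.logical(first$completer),
    dropout_month = as.numeric(first$dropout_month),
    covid_dropout = FALSE,
    accrual_month = as.numeric(first$accrual_index),
    latent_intercept = NA_real_, latent_slope = NA_real_,
    stringsAsFactors = FALSE)
  visits <- data.frame(
    subject_id = d$subject_id,
    visit_month = d$visit_month,
    adas_cog = as.numeric(d$adas_cog),
    observed = as.logical(d$observed),
    observation_mode = d$observation_mode,
    stringsAsFactors = FALSE)
  new_trajectory_panel(subjects, visits, schedule, residual_sd)
}
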