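# Analysis backends.
#
# Every (construct, scenario) dataset is analyzed by three procedures:
#   t_test            - two-sided pooled-variance t test on endpoint change
#                       scores (complete cases);
#   mixed_categorical - ML linear mixed model with categorical visit, random
#                       subject intercept; Wald z test of the treatment
#                       contrast at the endpoint visit (MMRM-style);
#   mixed_continuous  - ML fit with continuous time and an unstructured
#                       within-subject covariance over the scheduled
#                       visits; Wald z test of the treatment-by-time slope
#                       difference.
# Fixed effects follow the trial analysis plan: centred baseline score,
# treatment, baseline x treatment, visit (categorical or continuous) and
# visit x treatment. The mixed models take change-from-baseline scores at
# the post-baseline visits as response, with baseline as a free covariate
# (baseline rows are excluded from the response vector), matching the
# "difference at 18 months" contrast framing. No small-sample degrees-of-freedom correction is applied
# (normal reference for Wald statistics).

#' Endpoint change scores
#'
#' Per-subject change from baseline to the endpoint assessment: the observed
#' visit at or after `endpoint_month` (a rescheduled endpoint within an
#' extended window counts as the endpoint).
#'
#' @param panel A `trajectory_panel`.
#' @param endpoint_month Nominal endpoint month.
#' @return Data frame with columns `subject_id`, `arm`, `change`.
#' @export
endpoint_changes <- function(panel, endpoint_month = panel_horizon(panel)) {
  s <- panel$subjects
  v <- panel$visits
  k <- length(panel_schedule(panel))
  base <- v$adas_cog[v$visit_month == 0]
  is_end <- v$observed & v$visit_month >= endpoint_month - 1e-9
  idx <- rep(seq_len(nrow(s)), each = k)[is_end]
  out <- data.frame(subject_id = s$subject_id[idx], arm = s$arm[idx],
                    change = v$adas_cog[is_end] - base[idx],
                    stringsAsFactors = FALSE)
  out[!is.na(out$change), , drop = FALSE]
}

#' Analysis result container
#'
#' @param method One of `"t_test"`, `"mixed_categorical"`,
#'   `"mixed_continuous"`.
#' @param estimate Endpoint contrast, or slope difference times the horizon
#'   (points; positive favours active treatment).
#' @param standard_error Standard error of the estimate.
#' @param statistic Test statistic (t or Wald z).
#' @param p_value Two-sided p value.
#' @param converged Did the fit succeed.
#' @param n_used Number of subjects contributing.
#' @return An object of class `analysis_result`.
#' @export
analysis_result <- function(method, estimate = NA_real_,
                            standard_error = NA_real_, statistic = NA_real_,
                            p_value = NA_real_, converged = FALSE,
                            n_used = 0L) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0, 1]")
  structure(list(method = method, estimate = unname(estimate),
                 standard_error = unname(standard_error),
                 statistic = unname(statistic), p_value = unname(p_value),
                 converged = converged, n_used = n_used),
            class = "analysis_result")
}

#' @export
print.analysis_result <- function(x, ...) {
  cat(sprintf("<analysis_result> %s: estimate %.3f (SE %.3f), %s = %.3f, p = %.4g%s, n = %d\n",
              x$method, x$estimate, x$standard_error,
              if (x$method == "t_test") "t" else "z",
              x$statistic, x$p_value,
              if (!x$converged) " [not converged]" else "", x$n_used))
  invisible(x)
}

#' Endpoint t test on change scores
#'
#' Two-sided two-sample pooled-variance t test comparing endpoint change
#' scores between arms; subjects without an observed endpoint are excluded
#' (complete-case). An arm with fewer than two complete cases yields a
#' non-converged result.
#'
#' @param panel A `trajectory_panel` with arms assigned.
#' @param endpoint_month Nominal endpoint month.
#' @param alpha Unused; retained for interface symmetry.
#' @return An `analysis_result`.
#' @export
ttest_change <- function(panel, endpoint_month = panel_horizon(panel),
                         alpha = 0.05) {
  ch <- endpoint_changes(panel, endpoint_month)
  xp <- ch$change[ch$arm == "placebo"]
  xa <- ch$change[ch$arm == "active"]
  n1 <- length(xp); n2 <- length(xa)
  if (n1 < 2 || n2 < 2) return(analysis_result("t_test", n_used = n1 + n2))
  est <- mean(xp) - mean(xa)
  sp2 <- ((n1 - 1) * stats::var(xp) + (n2 - 1) * stats::var(xa)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    stat <- 0; p <- 1
  } else {
    stat <- est / se
    p <- 2 * stats::pt(-abs(stat), n1 + n2 - 2)
  }
  analysis_result("t_test", est, se, stat, p, TRUE, n1 + n2)
}

# Long-format model data: observed post-baseline rows with change scores
# as response, centred baseline as covariate, 0/1 treatment, the actual
# month, and the nominal visit slot (a rescheduled endpoint maps back to
# the endpoint slot).
mmrm_data <- function(panel, endpoint_month) {
  s <- panel$subjects
  v <- panel$visits
  k <- length(panel_schedule(panel))
  post <- setdiff(panel_schedule(panel), 0)
  base <- v$adas_cog[v$visit_month == 0]
  keep <- v$observed & v$visit_month > 0
  idx <- rep(seq_len(nrow(s)), each = k)[keep]
  slot_num <- pmin(v$visit_month[keep], endpoint_month)
  # snap to the nearest scheduled slot (guards against extended windows)
  slot_num <- post[pmax(1, findInterval(slot_num + 1e-9, post))]
  d <- data.frame(
    id = factor(s$subject_id[idx], levels = unique(s$subject_id[idx])),
    trt = as.numeric(s$arm[idx] == "active"),
    bl = base[idx],
    month = v$visit_month[keep],
    slot = factor(slot_num, levels = post),
    pos = match(slot_num, post),
    resp = v$adas_cog[keep] - base[idx],
    stringsAsFactors = FALSE)
  d$blc <- d$bl - mean(d$bl[!duplicated(d$id)])
  d
}

wald_from_fit <- function(method, beta, V, name_opts, scale = 1, n_used) {
  nm <- intersect(name_opts, names(beta))
  if (!length(nm) || is.na(beta[nm[1]]))
    return(analysis_result(method, n_used = n_used))
  b <- beta[nm[1]]
  se <- sqrt(V[nm[1], nm[1]])
  z <- b / se
  analysis_result(method, estimate = -b * scale,
                  standard_error = se * abs(scale), statistic = z,
                  p_value = 2 * stats::pnorm(-abs(z)), converged = TRUE,
                  n_used = n_used)
}

#' Mixed model with categorical time
#'
#' ML fit of `change ~ baseline_c * treatment + visit * treatment` with a
#' random subject intercept (marginal covariance: compound symmetry over the
#' visit grid), using all available post-baseline observations with no
#' complete-case restriction. The visit factor is parameterized with the
#' endpoint as reference level, so the treatment coefficient is the
#' between-arm contrast at the endpoint, tested with a Wald z statistic.
#' Estimation failures yield `converged = FALSE`.
#'
#' @inheritParams ttest_change
#' @return An `analysis_result`.
#' @export
fit_mixed_categorical <- function(panel, endpoint_month = panel_horizon(panel)) {
  d <- mmrm_data(panel, endpoint_month)
  n_used <- length(unique(d$id))
  post <- setdiff(panel_schedule(panel), 0)
  k <- length(post)
  # the endpoint contrast needs endpoint-slot data
  if (!any(d$pos == k) || nrow(d) == 0)
    return(analysis_result("mixed_categorical", n_used = n_used))
  fit <- mmrm_ml(d, k, post, kind = "categorical",
                 covariance = "random_intercept")
  if (!isTRUE(fit$converged))
    return(analysis_result("mixed_categorical", n_used = n_used))
  wald_from_fit("mixed_categorical", fit$beta, fit$vcov, "trt", 1, n_used)
}

#' Mixed model with continuous time
#'
#' ML fit of `change ~ baseline_c * treatment + month * treatment` with an
#' unstructured within-subject covariance across the scheduled
#' post-baseline visits (all variances and correlations free, positive
#' definiteness enforced through a Cholesky parameterization). The
#' treatment-by-month coefficient is the slope difference; the reported
#' estimate is the slope difference scaled to the endpoint horizon, and the
#' Wald z statistic tests the slope difference itself. If the unstructured
#' fit fails, the compound-symmetry (random-intercept) covariance is tried
#' before giving up with `converged = FALSE`.
#'
#' @inheritParams ttest_change
#' @return An `analysis_result`.
#' @export
fit_mixed_continuous <- function(panel, endpoint_month = panel_horizon(panel)) {
  d <- mmrm_data(panel, endpoint_month)
  n_used <- length(unique(d$id))
  post <- setdiff(panel_schedule(panel), 0)
  k <- length(post)
  if (length(unique(d$month)) < 2 || nrow(d) == 0)
    return(analysis_result("mixed_continuous", n_used = n_used))
  fit <- mmrm_ml(d, k, post, kind = "continuous",
                 covariance = "unstructured")
  if (!isTRUE(fit$converged))
    fit <- mmrm_ml(d, k, post, kind = "continuous",
                   covariance = "random_intercept")
  if (!isTRUE(fit$converged))
    return(analysis_result("mixed_continuous", n_used = n_used))
  wald_from_fit("mixed_continuous", fit$beta, fit$vcov,
                c("trt:month", "month:trt"), endpoint_month, n_used)
}

#' Dispatch an analysis method
#'
#' @param panel A `trajectory_panel`.
#' @param method `"t_test"`, `"mixed_categorical"` or `"mixed_continuous"`.
#' @param endpoint_month Nominal endpoint month.
#' @return An `analysis_result`.
#' @export
fit_method <- function(panel, method = c("t_test", "mixed_categorical",
                                         "mixed_continuous"),
                       endpoint_month = panel_horizon(panel)) {
  method <- match.arg(method)
  switch(method,
         t_test = ttest_change(panel, endpoint_month),
         mixed_categorical = fit_mixed_categorical(panel, endpoint_month),
         mixed_continuous = fit_mixed_continuous(panel, endpoint_month))
}
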