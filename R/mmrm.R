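# Direct maximum-likelihood MMRM engine.
#
# Both mixed models are Gaussian marginal models on the scheduled
# post-baseline visit grid: y_i ~ N(X_i beta, V[S_i, S_i]) where S_i is
# subject i's observed visit subset and V is a k x k covariance over the
# grid, either
#   random_intercept : V = sigma_b^2 11' + sigma_e^2 I   (2 parameters)
#   unstructured     : V = L L', L lower-triangular       (k(k+1)/2 params)
# with the unstructured factorization guaranteeing positive definiteness.
# The design matrix of both models factorizes as X_i = T B_i where T is a
# small time-profile basis on the grid (intercept + slot indicators for
# categorical time; intercept + month for continuous time) and B_i depends
# only on subject scalars (baseline, treatment). All subjects sharing an
# observation pattern therefore contribute through a handful of
# precomputable moment matrices, making each likelihood evaluation O(number
# of patterns) regardless of n. beta is profiled out by generalized least
# squares at each covariance iterate; the covariance parameters are
# maximized with BFGS from a pairwise-moment start.

# Collapse model data into per-pattern sufficient statistics.
# Scalars per subject: s = (1, blc, trt, blc*trt).
mmrm_pattern_stats <- function(d, k) {
  rows <- split(seq_len(nrow(d)), d$id)
  pat <- new.env(parent = emptyenv())
  for (rr in rows) {
    S <- d$pos[rr]
    key <- paste(S, collapse = ",")
    y <- d$resp[rr]
    blc <- d$blc[rr[1]]
    trt <- d$trt[rr[1]]
    s <- c(1, blc, trt, blc * trt)
    g <- pat[[key]]
    if (is.null(g)) {
      kg <- length(S)
      g <- list(S = S, n = 0L, M = matrix(0, 4, 4), P = matrix(0, 4, kg),
                Y2 = matrix(0, kg, kg), t = d$month[rr])
    }
    g$n <- g$n + 1L
    g$M <- g$M + tcrossprod(s)
    g$P <- g$P + tcrossprod(s, y)
    g$Y2 <- g$Y2 + tcrossprod(y)
    pat[[key]] <- g
  }
  as.list(pat)
}

# Model column selection in the kron(profile, scalar) coefficient space.
# Profiles: categorical -> (1, e_1, ..., e_{k-1}) with the endpoint slot
# (pos k) as reference; continuous -> (1, month).
mmrm_design <- function(kind, k, slot_months) {
  if (kind == "categorical") {
    Tf <- cbind(1, diag(k)[, seq_len(k - 1), drop = FALSE])
    sel <- c(1, 2, 3, 4,
             as.vector(vapply(seq_len(k - 1),
                              function(j) c(j * 4 + 1, j * 4 + 3),
                              numeric(2))))
    nm <- c("(Intercept)", "blc", "trt", "blc:trt",
            as.vector(vapply(seq_len(k - 1), function(j)
              c(sprintf("slot%g", slot_months[j]),
                sprintf("trt:slot%g", slot_months[j])), character(2))))
  } else {
    Tf <- cbind(1, slot_months)
    sel <- c(1, 2, 3, 4, 5, 7)
    nm <- c("(Intercept)", "blc", "trt", "blc:trt", "month", "trt:month")
  }
  list(Tf = Tf, sel = sel, names = nm)
}

mmrm_cov <- function(theta, kind, k) {
  if (kind == "random_intercept") {
    vb <- exp(2 * theta[1])
    ve <- exp(2 * theta[2])
    matrix(vb, k, k) + diag(ve, k)
  } else {
    L <- matrix(0, k, k)
    L[lower.tri(L, diag = TRUE)] <- theta
    diag(L) <- exp(pmin(diag(L), 20))
    tcrossprod(L)
  }
}

# -2 log likelihood with beta profiled out; returns +Inf off the feasible
# set so optim can roam freely.
mmrm_neg2ll <- function(theta, kind_cov, pats, des, k, n_obs, want_beta = FALSE) {
  V <- mmrm_cov(theta, kind_cov, k)
  A <- 0; r <- 0; ydot <- 0; ld <- 0
  for (g in pats) {
    Vg <- V[g$S, g$S, drop = FALSE]
    ch <- tryCatch(chol(Vg), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    Vi <- chol2inv(ch)
    Tg <- des$Tf[g$S, , drop = FALSE]
    W <- Vi %*% Tg
    A <- A + kronecker(crossprod(Tg, W), g$M)
    r <- r + as.vector(t(crossprod(W, t(g$P))))
    ydot <- ydot + sum(Vi * g$Y2)
    ld <- ld + g$n * 2 * sum(log(diag(ch)))
  }
  Am <- A[des$sel, des$sel, drop = FALSE]
  rm_ <- r[des$sel]
  sol <- tryCatch(solve(Am, rm_), error = function(e) NULL)
  if (is.null(sol)) return(Inf)
  val <- n_obs * log(2 * pi) + ld + ydot - sum(rm_ * sol)
  if (!is.finite(val)) return(Inf)
  if (!want_beta) return(val)
  Vb <- tryCatch(solve(Am), error = function(e) NULL)
  list(neg2ll = val, beta = stats::setNames(sol, des$names), vcov = Vb)
}

# Pairwise-moment start: OLS residuals pooled into a grid covariance.
mmrm_start_cov <- function(d, pats, des, k) {
  ident <- if (k == 1) diag(1) else diag(k)
  base <- mmrm_neg2ll(rep(0, 2), "random_intercept",
                      pats, des, k, nrow(d), want_beta = TRUE)
  # V = 2I at theta (0,0); GLS under exchangeable V equals a valid start beta
  beta <- if (is.list(base)) base$beta else NULL
  S <- matrix(0, k, k); Np <- matrix(0, k, k)
  if (!is.null(beta)) {
    full <- rep(0, ncol(des$Tf) * 4)
    full[des$sel] <- beta
    Bm <- matrix(full, nrow = 4)  # scalar x profile
    for (rr in split(seq_len(nrow(d)), d$id)) {
      S_i <- d$pos[rr]
      s <- c(1, d$blc[rr[1]], d$trt[rr[1]], d$blc[rr[1]] * d$trt[rr[1]])
      mu <- des$Tf[S_i, , drop = FALSE] %*% crossprod(Bm, s)
      e <- d$resp[rr] - as.vector(mu)
      S[S_i, S_i] <- S[S_i, S_i] + tcrossprod(e)
      Np[S_i, S_i] <- Np[S_i, S_i] + 1
    }
  }
  S <- ifelse(Np > 0, S / pmax(Np, 1), 0)
  dg <- diag(S)
  dg[dg <= 0] <- max(dg, 1)
  diag(S) <- dg
  # missing pairs: moderate positive correlation keeps the start PD-ish
  off <- Np == 0 & row(S) != col(S)
  S[off] <- 0.5 * sqrt(tcrossprod(dg))[off]
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-3 * max(ev$values))
  ev$vectors %*% (lam * t(ev$vectors))
}

#' Fit a marginal MMRM by direct maximum likelihood
#'
#' Internal engine behind [fit_mixed_categorical()] and
#' [fit_mixed_continuous()]; see those for the model definitions.
#'
#' @param d Model frame from the package's internal long-format builder.
#' @param k Number of post-baseline slots on the grid.
#' @param slot_months Months of the slots.
#' @param kind `"categorical"` or `"continuous"` time.
#' @param covariance `"random_intercept"` or `"unstructured"`.
#' @return List with `beta`, `vcov`, `logLik`, `converged`.
#' @keywords internal
mmrm_ml <- function(d, k, slot_months,
                    kind = c("categorical", "continuous"),
                    covariance = c("random_intercept", "unstructured")) {
  kind <- match.arg(kind)
  covariance <- match.arg(covariance)
  des <- mmrm_design(kind, k, slot_months)
  pats <- mmrm_pattern_stats(d, k)
  n_obs <- nrow(d)
  S0 <- mmrm_start_cov(d, pats, des, k)
  if (covariance == "random_intercept") {
    vb0 <- mean(S0[row(S0) != col(S0)])
    vb0 <- max(vb0, 1e-3 * mean(diag(S0)))
    ve0 <- max(mean(diag(S0)) - vb0, 1e-3 * mean(diag(S0)))
    theta0 <- 0.5 * log(c(vb0, ve0))
  } else {
    L <- t(chol(S0))
    theta0 <- numeric(k * (k + 1) / 2)
    lt <- lower.tri(L, diag = TRUE)
    M <- L
    diag(M) <- log(diag(L))
    theta0 <- M[lt]
  }
  obj <- function(th) mmrm_neg2ll(th, covariance, pats, des, k, n_obs)
  if (!is.finite(obj(theta0)))
    return(list(converged = FALSE))
  op <- tryCatch(
    stats::optim(theta0, obj, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-9)),
    error = function(e) NULL)
  if (is.null(op) || !is.finite(op$value))
    return(list(converged = FALSE))
  fin <- mmrm_neg2ll(op$par, covariance, pats, des, k, n_obs,
                     want_beta = TRUE)
  if (!is.list(fin) || is.null(fin$vcov))
    return(list(converged = FALSE))
  dimnames(fin$vcov) <- list(des$names, des$names)
  list(beta = fin$beta, vcov = fin$vcov, logLik = -fin$neg2ll / 2,
       converged = op$convergence == 0)
}
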