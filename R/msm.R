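# Working marginal-structural-model projection of the conditional
# counterfactual mean E(Y_g | Z) onto g(Z; theta) = expit(s(Z)' theta),
# with Z a subvector (or transformation) of the baseline covariates L.
# theta is the least-false parameter: the projection minimiser even when
# the working model is wrong.

#' Marginal structural working-model specification
#'
#' @param formula one-sided formula over columns of `L` defining the
#'   linear predictor `s(Z)`, e.g. `~ L2` for `expit(theta0 + theta1 L2)`.
#' @return object of class `msm_spec`.
#' @export
msm_spec <- function(formula) {
  stopifnot(inherits(formula, "formula"), length(formula) == 2)
  structure(list(formula = formula), class = "msm_spec")
}

msm_design <- function(msm, obs) {
  S <- stats::model.matrix(msm$formula, data = obs$L)
  if (qr(S)$rank < ncol(S))
    stop("MSM design matrix is rank deficient on these data")
  S
}

# Newton solver for score equations of the form
#   0 = mean_i( s_i * w_i * (r_i - expit(off_i + s_i' theta)) )
# with Hessian -mean( s s' w g (1-g) ). Used for the projection step
# (w = 1, r = pseudo-outcome), the IPW-MSM fit (w = W, r = Y), and the
# p-dimensional fluctuation (w = W, r = Y, off = logit mhat).
msm_newton <- function(S, r, w = NULL, offset = NULL, tol = 1e-10,
                       maxit = 100) {
  n <- nrow(S)
  p <- ncol(S)
  if (is.null(w)) w <- rep(1, n)
  if (is.null(offset)) offset <- rep(0, n)
  if (sum(w) <= 0) stop("all weights are zero")
  theta <- rep(0, p)
  score_norm <- Inf
  for (it in seq_len(maxit)) {
    g <- stats::plogis(offset + drop(S %*% theta))
    sc <- drop(crossprod(S, w * (r - g))) / n
    score_norm <- max(abs(sc))
    if (score_norm < tol) break
    H <- crossprod(S * (w * g * (1 - g)), S) / n
    step <- tryCatch(solve(H, sc), error = function(e)
      stop("singular information in MSM Newton step; check design rank"))
    for (h in 0:30) {
      cand <- theta + step / 2^h
      g2 <- stats::plogis(offset + drop(S %*% cand))
      sc2 <- drop(crossprod(S, w * (r - g2))) / n
      if (max(abs(sc2)) < score_norm) { theta <- cand; break }
      if (h == 30) stop("MSM Newton line search failed")
    }
  }
  if (score_norm >= 1e-8)
    stop("MSM estimating equation did not converge (score norm ",
         score_norm, " after ", it, " iterations)")
  list(theta = theta, score_norm = score_norm, iterations = it)
}

#' Sandwich covariance for MSM parameter estimates
#'
#' Computes the empirical sandwich
#' \deqn{\hat C^{-1}\, P_n[s(Z)s(Z)^T \tilde\phi^2]\, \hat C^{-T} / n}
#' with \eqn{\hat C = P_n[s(Z)s(Z)^T g(1-g)]} for the logistic link, and
#' \eqn{\tilde\phi} the per-record scalar residual of the estimating
#' equation that defined `theta`.
#'
#' @param S design matrix `s(Z)` (n x p).
#' @param phi numeric vector of per-record scalar residuals.
#' @param theta parameter value at which the derivative is evaluated.
#' @return p x p covariance matrix (already scaled by 1/n).
#' @export
msm_sandwich <- function(S, phi, theta) {
  n <- nrow(S)
  g <- stats::plogis(drop(S %*% theta))
  C <- crossprod(S * (g * (1 - g)), S) / n
  Ci <- tryCatch(solve(C), error = function(e)
    stop("singular C-hat in sandwich; check design rank"))
  M <- crossprod(S * phi, S * phi) / n
  V <- Ci %*% M %*% t(Ci) / n
  V <- (V + t(V)) / 2
  # the sandwich is PSD by construction; clip eigenvalue roundoff (an
  # exactly-zero residual direction can land at -1e-30 numerically)
  ev <- eigen(V, symmetric = TRUE)
  V2 <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  dimnames(V2) <- dimnames(V)
  V2
}

msm_estimate <- function(estimator, theta, S, phi, epsilon = NULL,
                         diagnostics = list()) {
  V <- msm_sandwich(S, phi, theta)
  se <- sqrt(diag(V))
  z <- stats::qnorm(0.975)
  nm <- colnames(S)
  names(theta) <- nm
  names(se) <- nm
  list(estimator = estimator, theta = theta, vcov = V, se = se,
       ci = cbind(lower = theta - z * se, upper = theta + z * se),
       phi = phi, design = S, epsilon = epsilon,
       diagnostics = diagnostics)
}

est_msm_ore <- function(obs, nuis, msm, spec) {
  S <- msm_design(msm, obs)
  fit <- msm_newton(S, nuis$mhat_int)
  g <- stats::plogis(drop(S %*% fit$theta))
  phi <- nuis$mhat_int - g  # residual of the ORE estimating equation
  msm_estimate("ore", fit$theta, S, phi,
               diagnostics = list(score_norm = fit$score_norm,
                                  se_flavour = "naive"))
}

est_msm_ipw <- function(obs, nuis, msm, spec, weights = NULL) {
  if (is.null(weights)) weights <- substitution_weights(obs, nuis, spec)
  S <- msm_design(msm, obs)
  fit <- msm_newton(S, obs$Y, w = weights$W)
  g <- stats::plogis(drop(S %*% fit$theta))
  phi <- weights$W * (obs$Y - g)
  msm_estimate("ipw", fit$theta, S, phi,
               diagnostics = list(score_norm = fit$score_norm,
                                  se_flavour = "naive",
                                  n_truncated = weights$n_truncated))
}

est_msm_tmle <- function(obs, nuis, msm, spec, weights = NULL) {
  if (is.null(weights)) weights <- substitution_weights(obs, nuis, spec)
  S <- msm_design(msm, obs)
  W <- weights$W
  eta_obs <- stats::qlogis(bound01(nuis$mhat_obs))
  eta_int <- stats::qlogis(bound01(nuis$mhat_int))
  # p-dimensional fluctuation along s(Z), weighted by W, offset logit mhat
  fl <- msm_newton(S, obs$Y, w = W, offset = eta_obs)
  eps <- fl$theta
  shift <- drop(S %*% eps)
  mstar_obs <- stats::plogis(eta_obs + shift)
  mstar_int <- stats::plogis(eta_int + shift)
  # projection of the targeted augmentation term onto the working model
  pr <- msm_newton(S, mstar_int)
  g <- stats::plogis(drop(S %*% pr$theta))
  phi <- W * (obs$Y - mstar_obs) + mstar_int - g
  msm_estimate("tmle", pr$theta, S, phi, epsilon = eps,
               diagnostics = list(fluct_score_norm = fl$score_norm,
                                  proj_score_norm = pr$score_norm,
                                  se_flavour = "eif",
                                  n_truncated = weights$n_truncated))
}
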