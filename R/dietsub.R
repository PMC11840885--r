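#' Estimate the causal effect of a capped substitution strategy
#'
#' Fits one of three estimators of the counterfactual mean
#' \eqn{\mu_g = E(Y_g)} under the strategy that sets the replaced
#' exposure to zero and the substitute exposure to
#' \eqn{\min(A + B, x)}: the outcome-regression estimator (`"ore"`), the
#' inverse-probability-weighted estimator (`"ipw"`), or the doubly robust
#' targeted maximum likelihood estimator (`"tmle"`). The risk difference
#' \eqn{\Delta = E(Y) - \mu_g} is always reported alongside. When an
#' `msm` design is supplied, the corresponding working
#' marginal-structural-model projection of \eqn{E(Y_g \mid Z)} onto
#' `expit(s(Z)' theta)` is also estimated, with the sandwich covariance.
#'
#' TMLE standard errors come from the efficient influence function; ORE
#' and IPW standard errors treat the fitted nuisances as fixed and are
#' labelled naive (a nonparametric bootstrap is available via `boot`).
#'
#' @param data a data.frame or an [observed_data] object.
#' @param a,b,c_cols,l_cols,y column roles, passed to [observed_data]
#'   when `data` is a data.frame.
#' @param x positive integer cap on the substitute intake; default
#'   `max(B)` observed.
#' @param estimator `"tmle"` (default), `"ore"`, or `"ipw"`.
#' @param outcome outcome-regression specification ([outcome_spec] or
#'   formula with response `Y`); default a logistic main-effects model in
#'   `A`, `B` and all `C`/`L` columns.
#' @param exposure_a,exposure_b exposure pmf specifications
#'   ([exposure_spec] or formula); defaults are multinomial models of `A`
#'   on `(C, L)` and of `B` on `(A, C, L)`.
#' @param msm optional one-sided formula over `L` columns (or an
#'   [msm_spec]) requesting the MSM projection.
#' @param folds cross-fitting folds for the nuisance fits (1 = none).
#' @param seed integer seed used for the fold split and the bootstrap.
#' @param weight_floor lower truncation for estimated denominator
#'   densities in the weights.
#' @param boot logical; if `TRUE`, replace the naive ORE/IPW standard
#'   errors by a nonparametric bootstrap (nuisances refit per resample).
#' @param boot_reps bootstrap resamples.
#' @return an object of class `dietsub` with components `mu_g`, `delta`,
#'   `se_mu`, `se_delta`, `ci_mu`, `ci_delta`, `if_values`, `epsilon`,
#'   `msm` (when requested), `nuisances`, `weights`, `call`. Methods:
#'   `print`, `summary`, `coef`, `vcov`, `confint`, `residuals`.
#' @examples
#' d <- generate_study1(500, seed = 1)
#' fit <- dietsub(d, x = 3, estimator = "tmle",
#'                outcome = Y ~ A + B + C + L,
#'                exposure_a = exposure_spec(A ~ C + L, "saturated"),
#'                exposure_b = exposure_spec(B ~ A + C + L, "saturated"))
#' fit
#' @export
dietsub <- function(data, a = "A", b = "B", c_cols = "C", l_cols = "L",
                    y = "Y", x = NULL,
                    estimator = c("tmle", "ore", "ipw"),
                    outcome = NULL, exposure_a = NULL, exposure_b = NULL,
                    msm = NULL, folds = 1L, seed = NULL,
                    weight_floor = 1e-6, boot = FALSE, boot_reps = 500L) {
  cl <- match.call()
  estimator <- match.arg(estimator)
  obs <- if (inherits(data, "observed_data")) data else
    observed_data(data, a = a, b = b, c_cols = c_cols, l_cols = l_cols,
                  y = y)
  if (is.null(x)) x <- max(obs$support_B)
  spec <- substitution(x)

  cn <- colnames(obs$C)
  ln <- colnames(obs$L)
  rhs <- function(vars) paste(c(vars, "1")[seq_len(max(1, length(vars)))],
                              collapse = " + ")
  if (is.null(outcome))
    outcome <- stats::as.formula(paste("Y ~ A + B +", rhs(c(cn, ln))))
  if (is.null(exposure_a))
    exposure_a <- stats::as.formula(paste("A ~", rhs(c(cn, ln))))
  if (is.null(exposure_b))
    exposure_b <- stats::as.formula(paste("B ~ A +", rhs(c(cn, ln))))
  if (!is.null(msm) && inherits(msm, "formula")) msm <- msm_spec(msm)

  need_weights <- estimator %in% c("ipw", "tmle")
  nuis <- fit_nuisances(obs, spec, outcome,
                        exposure_a = if (need_weights) exposure_a,
                        exposure_b = if (need_weights) exposure_b,
                        folds = folds, seed = seed)
  weights <- if (need_weights)
    substitution_weights(obs, nuis, spec, floor = weight_floor) else NULL

  scalar <- switch(estimator,
    ore  = est_ore(obs, nuis, spec),
    ipw  = est_ipw(obs, nuis, spec, weights),
    tmle = est_tmle(obs, nuis, spec, weights))

  msm_fit <- if (!is.null(msm)) switch(estimator,
    ore  = est_msm_ore(obs, nuis, msm, spec),
    ipw  = est_msm_ipw(obs, nuis, msm, spec, weights),
    tmle = est_msm_tmle(obs, nuis, msm, spec, weights)) else NULL

  out <- c(scalar, list(msm = msm_fit, msm_formula =
                          if (!is.null(msm)) msm$formula else NULL,
                        x = spec$x, spec = spec, obs = obs,
                        nuisances = nuis, weights = weights,
                        folds = folds, seed = seed, call = cl))

  if (boot && estimator %in% c("ore", "ipw")) {
    bs <- bootstrap_se(obs, spec, outcome, exposure_a, exposure_b,
                       estimator, reps = boot_reps,
                       seed = if (is.null(seed)) 1L else seed,
                       weight_floor = weight_floor)
    out$se_mu <- bs$se_mu
    out$se_delta <- bs$se_delta
    z <- stats::qnorm(0.975)
    out$ci_mu <- c(out$mu_g - z * bs$se_mu, out$mu_g + z * bs$se_mu)
    out$ci_delta <- c(out$delta - z * bs$se_delta,
                      out$delta + z * bs$se_delta)
    out$diagnostics$se_flavour <- "bootstrap"
    out$diagnostics$boot_reps <- boot_reps
  }
  class(out) <- "dietsub"
  out
}

bootstrap_se <- function(obs, spec, outcome, exposure_a, exposure_b,
                         estimator, reps, seed, weight_floor) {
  d <- model_frame(obs)
  cn <- colnames(obs$C)
  ln <- colnames(obs$L)
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    set.seed((seed + r * 9973L) %% .Machine$integer.max)
    idx <- sample.int(obs$n, replace = TRUE)
    ob <- observed_data(d[idx, , drop = FALSE], a = "A", b = "B",
                        c_cols = cn, l_cols = ln, y = "Y")
    fit <- tryCatch({
      nu <- fit_nuisances(ob, spec, outcome, exposure_a, exposure_b)
      if (estimator == "ore") est_ore(ob, nu, spec) else
        est_ipw(ob, nu, spec)
    }, error = function(e) NULL)
    if (!is.null(fit)) est[r, ] <- c(fit$mu_g, fit$delta)
  }
  list(se_mu = stats::sd(est[, 1], na.rm = TRUE),
       se_delta = stats::sd(est[, 2], na.rm = TRUE))
}

#' @export
print.dietsub <- function(x, digits = 4, ...) {
  cat(sprintf("Capped substitution effect (%s), cap x = %d\n",
              toupper(x$estimator), x$x))
  cat(sprintf("  mu_g  = %.*f (SE %.*f, 95%% CI %.*f to %.*f)\n",
              digits, x$mu_g, digits, x$se_mu,
              digits, x$ci_mu[1], digits, x$ci_mu[2]))
  cat(sprintf("  delta = %.*f (SE %.*f, 95%% CI %.*f to %.*f)\n",
              digits, x$delta, digits, x$se_delta,
              digits, x$ci_delta[1], digits, x$ci_delta[2]))
  if (!is.null(x$msm)) {
    cat("  MSM projection expit(s(Z)'theta):\n")
    m <- x$msm
    for (j in seq_along(m$theta))
      cat(sprintf("    %-12s %.*f (SE %.*f)\n", names(m$theta)[j],
                  digits, m$theta[j], digits, m$se[j]))
  }
  invisible(x)
}

#' @export
summary.dietsub <- function(object, ...) {
  z <- stats::qnorm(0.975)
  tab <- rbind(
    mu_g = c(object$mu_g, object$se_mu, object$ci_mu),
    delta = c(object$delta, object$se_delta, object$ci_delta))
  colnames(tab) <- c("estimate", "se", "ci_lower", "ci_upper")
  msm_tab <- NULL
  if (!is.null(object$msm)) {
    m <- object$msm
    msm_tab <- cbind(estimate = m$theta, se = m$se,
                     ci_lower = m$ci[, 1], ci_upper = m$ci[, 2])
  }
  structure(list(estimator = object$estimator, x = object$x,
                 scalar = tab, msm = msm_tab,
                 epsilon = object$epsilon,
                 diagnostics = object$diagnostics,
                 n = object$obs$n,
                 n_truncated = if (!is.null(object$weights))
                   object$weights$n_truncated else 0L),
            class = "summary.dietsub")
}

#' @export
print.summary.dietsub <- function(x, digits = 4, ...) {
  cat(sprintf("Estimator: %s; cap x = %d; n = %d\n", toupper(x$estimator),
              x$x, x$n))
  cat("\nScalar estimands:\n")
  print(round(x$scalar, digits))
  if (!is.null(x$msm)) {
    cat("\nMSM working-model parameters:\n")
    print(round(x$msm, digits))
  }
  if (!is.na(x$epsilon[1]) && length(x$epsilon))
    cat(sprintf("\nfluctuation epsilon: %s\n",
                paste(signif(x$epsilon, 4), collapse = ", ")))
  if (x$n_truncated > 0)
    cat(sprintf("weights truncated at floor: %d record(s)\n",
                x$n_truncated))
  if (!is.null(x$diagnostics$se_flavour))
    cat(sprintf("standard errors: %s\n", x$diagnostics$se_flavour))
  invisible(x)
}

#' @export
coef.dietsub <- function(object, ...) {
  if (!is.null(object$msm)) object$msm$theta else
    c(mu_g = object$mu_g, delta = object$delta)
}

#' @export
vcov.dietsub <- function(object, ...) {
  if (!is.null(object$msm)) return(object$msm$vcov)
  n <- object$obs$n
  v <- stats::var(cbind(object$if_values, object$if_delta)) / n
  dimnames(v) <- list(c("mu_g", "delta"), c("mu_g", "delta"))
  v
}

#' @export
confint.dietsub <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- coef(object)
  se <- sqrt(diag(vcov(object)))
  ci <- cbind(est - z * se, est + z * se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                         " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.dietsub <- function(object, type = c("if", "if_delta"), ...) {
  type <- match.arg(type)
  if (type == "if") object$if_values else object$if_delta
}

#' @export
plot.dietsub <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (!is.null(x$weights)) {
    wpos <- x$weights$W[x$weights$W > 0]
    graphics::hist(wpos, breaks = 30, main = "Weights (A = 0 records)",
                   xlab = "W")
  } else {
    graphics::plot.new(); graphics::title("no weights (ORE)")
  }
  graphics::hist(x$if_values, breaks = 30,
                 main = "Influence-function values", xlab = "IF")
  invisible(x)
}
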