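#' Learner specification for the outcome regression
#'
#' The outcome regression `m(A, B, C, L) = E(Y | A, B, C, L)` can be fit
#' parametrically (logistic regression via [stats::glm]) or flexibly
#' (penalised spline smooths via [mgcv::gam]). In formulas, refer to the
#' exposures by the canonical names `A` and `B` and to the `C`/`L`
#' columns by their original names; the response is `Y`.
#'
#' @param formula model formula with response `Y`.
#' @param backend `"glm"` for parametric logistic regression, `"gam"`
#'   for a flexible smooth model.
#' @return object of class `outcome_spec`.
#' @export
outcome_spec <- function(formula, backend = c("glm", "gam")) {
  backend <- match.arg(backend)
  stopifnot(inherits(formula, "formula"))
  structure(list(formula = formula, backend = backend),
            class = "outcome_spec")
}

#' Learner specification for a discrete exposure pmf
#'
#' Conditional pmfs of the discrete exposures over their finite supports
#' can be estimated by three back-ends: `"multinomial"` (multinomial
#' logistic regression over the support via [nnet::multinom]; spline terms
#' such as `splines::ns()` in the formula give a flexible fit),
#' `"binomial"` (Binomial-logistic with size `max(support)`), or
#' `"saturated"` (empirical conditional pmfs within exact cells of the
#' conditioning variables -- the nonparametric MLE, suitable when all
#' conditioning variables are discrete with few levels).
#'
#' @param formula formula whose LHS is the exposure (`A` or `B`) and whose
#'   RHS lists the conditioning variables.
#' @param backend one of `"multinomial"`, `"binomial"`, `"saturated"`.
#' @return object of class `exposure_spec`.
#' @export
exposure_spec <- function(formula,
                          backend = c("multinomial", "binomial",
                                      "saturated")) {
  backend <- match.arg(backend)
  stopifnot(inherits(formula, "formula"))
  structure(list(formula = formula, backend = backend),
            class = "exposure_spec")
}

bound01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# ---- outcome model -------------------------------------------------------

fit_outcome_backend <- function(spec, frame) {
  yname <- all.vars(spec$formula[[2]])
  yy <- frame[[yname]]
  if (stats::var(yy) == 0) {
    # degenerate constant outcome: every calibrated fit is the constant
    return(structure(list(constant = mean(yy)), class = "constant_fit"))
  }
  if (spec$backend == "glm") {
    fit <- stats::glm(spec$formula, data = frame,
                      family = stats::binomial())
    if (!fit$converged) stop("outcome logistic regression did not converge")
  } else {
    fit <- mgcv::gam(spec$formula, data = frame,
                     family = stats::binomial(), method = "REML")
  }
  fit
}

predict_outcome <- function(fit, newframe) {
  if (inherits(fit, "constant_fit"))
    return(rep(fit$constant, nrow(newframe)))
  p <- as.numeric(stats::predict(fit, newdata = newframe,
                                 type = "response"))
  bound01(p)
}

#' Fit the outcome regression model
#'
#' @param obs an [observed_data] object.
#' @param spec an [outcome_spec] (a bare formula is promoted to a
#'   parametric logistic specification).
#' @return object of class `outcome_model` wrapping the fit, with a
#'   `predict` method taking a data frame of `(A, B, C, L)` values.
#' @export
fit_outcome_model <- function(obs, spec) {
  if (inherits(spec, "formula")) spec <- outcome_spec(spec)
  stopifnot(inherits(spec, "outcome_spec"))
  frame <- model_frame(obs)
  fit <- fit_outcome_backend(spec, frame)
  structure(list(fit = fit, spec = spec),
            class = "outcome_model")
}

#' @export
predict.outcome_model <- function(object, newdata, ...) {
  predict_outcome(object$fit, newdata)
}

# ---- exposure models -----------------------------------------------------

fit_exposure_backend <- function(spec, frame, response, support) {
  size <- max(support)
  if (spec$backend == "binomial") {
    yy <- frame[[response]]
    f <- stats::update(spec$formula, cbind(.succ, .fail) ~ .)
    frame$.succ <- yy
    frame$.fail <- size - yy
    fit <- stats::glm(f, data = frame, family = stats::binomial())
    list(backend = "binomial", fit = fit, size = size)
  } else if (spec$backend == "multinomial") {
    frame$.resp <- factor(frame[[response]], levels = support)
    f <- stats::update(spec$formula, .resp ~ .)
    fit <- nnet::multinom(f, data = frame, trace = FALSE, maxit = 500)
    list(backend = "multinomial", fit = fit)
  } else { # saturated: empirical conditional pmfs on exact cells
    rhs <- all.vars(spec$formula[[3]])
    key <- interaction(frame[rhs], drop = TRUE, lex.order = TRUE)
    yy <- factor(frame[[response]], levels = support)
    tab <- table(key, yy)
    probs <- prop.table(tab, 1)
    marg <- prop.table(table(yy))
    list(backend = "saturated", rhs = rhs, probs = unclass(probs),
         keys = rownames(probs), marginal = as.numeric(marg))
  }
}

predict_exposure_pmf <- function(model, newframe, support) {
  n <- nrow(newframe)
  k <- length(support)
  if (model$backend == "binomial") {
    ph <- as.numeric(stats::predict(model$fit, newdata = newframe,
                                    type = "response"))
    out <- vapply(support, function(v) stats::dbinom(v, model$size, ph),
                  numeric(n))
    if (is.null(dim(out))) out <- matrix(out, nrow = n)
  } else if (model$backend == "multinomial") {
    pr <- stats::predict(model$fit, newdata = newframe, type = "probs")
    if (is.null(dim(pr))) {
      if (k == 2) pr <- cbind(1 - pr, pr) else pr <- matrix(pr, nrow = 1)
    }
    out <- matrix(pr, nrow = n, ncol = k)
  } else {
    key <- as.character(interaction(newframe[model$rhs], drop = FALSE,
                                    lex.order = TRUE))
    idx <- match(key, model$keys)
    out <- matrix(rep(model$marginal, each = n), nrow = n)
    seen <- !is.na(idx)
    out[seen, ] <- model$probs[idx[seen], , drop = FALSE]
  }
  # guard: renormalise tiny numerical drift
  out / rowSums(out)
}

#' Fit conditional pmf models for both exposures
#'
#' Fits `p(A = a | C, L)` and `p(B = b | A, C, L)` over their finite
#' supports.
#'
#' @param obs an [observed_data] object.
#' @param spec_a,spec_b [exposure_spec] objects (bare formulas are
#'   promoted to multinomial specifications). The `B` model should
#'   condition on `A`.
#' @return list with classed elements `expA` and `expB`, each carrying
#'   the backend fit, its support, and a `pmf(newdata)` closure.
#' @export
fit_exposure_models <- function(obs, spec_a, spec_b) {
  if (inherits(spec_a, "formula")) spec_a <- exposure_spec(spec_a)
  if (inherits(spec_b, "formula")) spec_b <- exposure_spec(spec_b)
  frame <- model_frame(obs)
  ma <- fit_exposure_backend(spec_a, frame, "A", obs$support_A)
  mb <- fit_exposure_backend(spec_b, frame, "B", obs$support_B)
  list(
    expA = structure(list(model = ma, spec = spec_a,
                          support = obs$support_A),
                     class = "exposure_model"),
    expB = structure(list(model = mb, spec = spec_b,
                          support = obs$support_B),
                     class = "exposure_model")
  )
}

#' @export
predict.exposure_model <- function(object, newdata, ...) {
  predict_exposure_pmf(object$model, newdata, object$support)
}

# ---- assembled nuisance set ---------------------------------------------

#' Fit all nuisance functions, optionally cross-fitted
#'
#' Fits the outcome regression and both exposure pmf models and stores the
#' per-record evaluations the estimators need: `m(A, B, C, L)` at the
#' observed exposures, `m(0, d(A,B), C, L)` at the intervened exposures,
#' `p(A = a | C, L)` for every support value, and `p(B = b | a, C, L)` for
#' every `(a, b)` support pair. With `folds > 1` the data are split into
#' deterministic folds given `seed` and every record's evaluations come
#' from models fit on the other folds.
#'
#' @param obs an [observed_data] object.
#' @param spec an [substitution] strategy (supplies the cap for the
#'   intervened evaluation).
#' @param outcome an [outcome_spec] or formula.
#' @param exposure_a,exposure_b [exposure_spec]s or formulas; both `NULL`
#'   skips the exposure fits (sufficient for the pure outcome-regression
#'   estimator).
#' @param folds integer >= 1; 1 means full-sample fitting.
#' @param seed integer seed controlling the fold split (required when
#'   `folds > 1`).
#' @return object of class `nuisance_set`.
#' @export
fit_nuisances <- function(obs, spec, outcome, exposure_a = NULL,
                          exposure_b = NULL, folds = 1L, seed = NULL) {
  stopifnot(inherits(obs, "observed_data"), inherits(spec, "substitution"))
  if (inherits(outcome, "formula")) outcome <- outcome_spec(outcome)
  if (inherits(exposure_a, "formula")) exposure_a <- exposure_spec(exposure_a)
  if (inherits(exposure_b, "formula")) exposure_b <- exposure_spec(exposure_b)
  with_exposures <- !is.null(exposure_a) || !is.null(exposure_b)
  if (with_exposures && (is.null(exposure_a) || is.null(exposure_b)))
    stop("supply both exposure specifications or neither")
  n <- obs$n
  folds <- as.integer(folds)
  if (folds < 1 || folds > n) stop("folds must be in 1..n")

  frame <- model_frame(obs)
  int_frame <- frame
  int_frame$A <- 0L
  int_frame$B <- substitute_dose(obs$A, obs$B, spec$x)

  sa <- obs$support_A
  sb <- obs$support_B

  if (folds == 1L) {
    fold_id <- rep(1L, n)
    train_sets <- list(seq_len(n))
    test_sets <- list(seq_len(n))
  } else {
    if (is.null(seed)) stop("seed is required when folds > 1")
    fold_id <- local({
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
      sample(rep_len(seq_len(folds), n))
    })
    train_sets <- lapply(seq_len(folds), function(k) which(fold_id != k))
    test_sets <- lapply(seq_len(folds), function(k) which(fold_id == k))
  }

  mhat_obs <- numeric(n)
  mhat_int <- numeric(n)
  pA <- if (with_exposures) matrix(NA_real_, n, length(sa)) else NULL
  pB_given_a <- if (with_exposures) lapply(seq_along(sa), function(i)
    matrix(NA_real_, n, length(sb))) else NULL
  models <- vector("list", length(train_sets))

  for (k in seq_along(train_sets)) {
    tr <- train_sets[[k]]
    te <- test_sets[[k]]
    obs_k <- obs
    obs_k$A <- obs$A[tr]; obs_k$B <- obs$B[tr]
    obs_k$C <- obs$C[tr, , drop = FALSE]
    obs_k$L <- obs$L[tr, , drop = FALSE]
    obs_k$Y <- obs$Y[tr]; obs_k$n <- length(tr)

    om <- fit_outcome_model(obs_k, outcome)
    mhat_obs[te] <- predict(om, frame[te, , drop = FALSE])
    mhat_int[te] <- predict(om, int_frame[te, , drop = FALSE])
    models[[k]] <- list(outcome = om)
    if (with_exposures) {
      em <- fit_exposure_models(obs_k, exposure_a, exposure_b)
      models[[k]]$expA <- em$expA
      models[[k]]$expB <- em$expB
      pA[te, ] <- predict(em$expA, frame[te, , drop = FALSE])
      for (ai in seq_along(sa)) {
        fa <- frame[te, , drop = FALSE]
        fa$A <- sa[ai]
        pB_given_a[[ai]][te, ] <- predict(em$expB, fa)
      }
    }
  }

  structure(list(
    mhat_obs = mhat_obs, mhat_int = mhat_int,
    pA = pA, pB_given_a = pB_given_a,
    support_A = sa, support_B = sb,
    folds = folds, fold_id = fold_id, seed = seed,
    models = models,
    specs = list(outcome = outcome, exposure_a = exposure_a,
                 exposure_b = exposure_b)
  ), class = "nuisance_set")
}

#' @export
print.nuisance_set <- function(x, ...) {
  cat("Nuisance set\n")
  cat(sprintf("  outcome backend: %s\n", x$specs$outcome$backend))
  if (!is.null(x$specs$exposure_a))
    cat(sprintf("  exposure A backend: %s; exposure B backend: %s\n",
                x$specs$exposure_a$backend, x$specs$exposure_b$backend))
  else cat("  exposure models: not fitted\n")
  cat(sprintf("  cross-fitting folds: %d\n", x$folds))
  invisible(x)
}
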