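# Synthetic data generators for the two simulation designs, the
# misspecification scenario registry, numerical oracles for the true
# counterfactual mean and the least-false MSM parameters, Monte Carlo
# cross-checks of those oracles, and the replication harness.

expit <- stats::plogis

# run code under a local RNG state so generators do not disturb the
# caller's random stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

study1_laws <- list(
  pa = function(L, U) expit(-2 + L + U),
  pb = function(L, U) expit(1 - 2 * L + U),
  pc = function(L, U) expit(-1 + L + U),
  m  = function(A, B, C, L) expit(-1 - A + B + C - 2 * L)
)

study2_laws <- list(
  pa = function(L1, L2, U) expit(-2 + 0.75 * L1 + 0.5 * L2 + U),
  pb = function(L1, L2, U) expit(-1 + 0.5 * L1 - 0.25 * exp(L2) + U),
  pc = function(L1, L2, U) expit(-1 + L1 + U),
  m  = function(A, B, C, L1, L2)
    expit(-1 - A + B + C - 2 * L1 + L2 - 0.25 * exp(L2) + 0.25 * L1 * L2)
)

#' Generate data from simulation design 1
#'
#' Binary confounder `L ~ Ber(0.5)`, shared latent factor
#' `U ~ Unif(0,1)` (not emitted), exposures
#' `A ~ Bin(3, expit(-2 + L + U))`, `B ~ Bin(3, expit(1 - 2L + U))`,
#' `C ~ Bin(3, expit(-1 + L + U))`, outcome
#' `Y ~ Ber(expit(-1 - A + B + C - 2L))`.
#'
#' @param n sample size.
#' @param seed integer seed; the generator is deterministic given it.
#' @return an [observed_data] object with columns `L, A, B, C, Y`.
#' @export
generate_study1 <- function(n, seed) {
  d <- with_seed(seed, {
    U <- stats::runif(n)
    L <- stats::rbinom(n, 1, 0.5)
    A <- stats::rbinom(n, 3, study1_laws$pa(L, U))
    B <- stats::rbinom(n, 3, study1_laws$pb(L, U))
    C <- stats::rbinom(n, 3, study1_laws$pc(L, U))
    Y <- stats::rbinom(n, 1, study1_laws$m(A, B, C, L))
    data.frame(L = L, A = A, B = B, C = C, Y = Y)
  })
  observed_data(d, a = "A", b = "B", c_cols = "C", l_cols = "L", y = "Y")
}

#' Generate data from simulation design 2
#'
#' Adds a continuous effect modifier: `L1 ~ Ber(0.5)`, `L2 ~ Unif(0,2)`,
#' latent `U ~ Unif(0,1)`, exposures
#' `A ~ Bin(3, expit(-2 + 0.75 L1 + 0.5 L2 + U))`,
#' `B ~ Bin(3, expit(-1 + 0.5 L1 - 0.25 exp(L2) + U))`,
#' `C ~ Bin(3, expit(-1 + L1 + U))`, outcome
#' `Y ~ Ber(expit(-1 - A + B + C - 2 L1 + L2 - 0.25 exp(L2)
#' + 0.25 L1 L2))`.
#'
#' @inheritParams generate_study1
#' @return an [observed_data] object with columns `L1, L2, A, B, C, Y`.
#' @export
generate_study2 <- function(n, seed) {
  d <- with_seed(seed, {
    U <- stats::runif(n)
    L1 <- stats::rbinom(n, 1, 0.5)
    L2 <- stats::runif(n, 0, 2)
    A <- stats::rbinom(n, 3, study2_laws$pa(L1, L2, U))
    B <- stats::rbinom(n, 3, study2_laws$pb(L1, L2, U))
    C <- stats::rbinom(n, 3, study2_laws$pc(L1, L2, U))
    Y <- stats::rbinom(n, 1, study2_laws$m(A, B, C, L1, L2))
    data.frame(L1 = L1, L2 = L2, A = A, B = B, C = C, Y = Y)
  })
  observed_data(d, a = "A", b = "B", c_cols = "C", l_cols = c("L1", "L2"),
                y = "Y")
}

#' Nuisance specifications for the simulation scenarios
#'
#' Returns the learner specifications for the three arms of simulation
#' design 1 and the flexible-learner arm of design 2.
#'
#' * `"correct"` (design 1): true logistic outcome model
#'   `Y ~ A + B + C + L`; exposures fit by saturated empirical
#'   conditional pmfs over the observed covariate cells (the
#'   nonparametric MLE -- the exposures depend on the latent factor `U`,
#'   so their observed-covariate conditionals are not Binomial, and a
#'   saturated fit is the rich specification consistent for them).
#' * `"mis_outcome"` (design 1): outcome working model
#'   `expit(b0 + b1 A + b2 BL + b3 CL)`; exposures as in `"correct"`.
#' * `"mis_exposure"` (design 1): Binomial-logistic exposure working
#'   models `expit(ab0 + ab1 A + ab2 C)` for `B` and
#'   `expit(aa0 + aa1 C)` for `A`; outcome correct.
#' * design 2 (any scenario): flexible learners -- smooth additive model
#'   for the outcome, multinomial logistic with natural-spline basis in
#'   `L2` for the exposures.
#'
#' @param study 1 or 2.
#' @param scenario `"correct"`, `"mis_outcome"`, or `"mis_exposure"`
#'   (design 1 only).
#' @return list with elements `outcome`, `exposure_a`, `exposure_b`.
#' @export
scenario_specs <- function(study,
                           scenario = c("correct", "mis_outcome",
                                        "mis_exposure")) {
  scenario <- match.arg(scenario)
  if (study == 1) {
    correct_a <- exposure_spec(A ~ C + L, "saturated")
    correct_b <- exposure_spec(B ~ A + C + L, "saturated")
    correct_y <- outcome_spec(Y ~ A + B + C + L)
    switch(scenario,
      correct = list(outcome = correct_y, exposure_a = correct_a,
                     exposure_b = correct_b),
      mis_outcome = list(outcome = outcome_spec(Y ~ A + B:L + C:L),
                         exposure_a = correct_a, exposure_b = correct_b),
      mis_exposure = list(outcome = correct_y,
                          exposure_a = exposure_spec(A ~ C, "binomial"),
                          exposure_b = exposure_spec(B ~ A + C,
                                                     "binomial")))
  } else if (study == 2) {
    list(
      outcome = outcome_spec(
        Y ~ A + B + C + L1 + s(L2) + s(L2, by = L1), backend = "gam"),
      exposure_a = exposure_spec(
        A ~ L1 + splines::ns(L2, 4), "multinomial"),
      exposure_b = exposure_spec(
        B ~ A + L1 + splines::ns(L2, 4), "multinomial"))
  } else stop("study must be 1 or 2")
}

# ---- deterministic oracles ----------------------------------------------

# exposure-and-outcome enumeration for one covariate point: returns
# E[m(0, d(A,B), C, L) | L] and the joint pieces, integrating U by
# Gauss-Legendre quadrature. pa/pb/pc are probability functions of U.
enum_point <- function(pa_fun, pb_fun, pc_fun, m_int, nodes, x = 3) {
  grid <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  bd <- pmin(grid$a + grid$b, x)
  mval <- m_int(bd, grid$c)
  xi <- 0
  for (k in seq_along(nodes$x)) {
    u <- nodes$x[k]
    p <- stats::dbinom(grid$a, 3, pa_fun(u)) *
      stats::dbinom(grid$b, 3, pb_fun(u)) *
      stats::dbinom(grid$c, 3, pc_fun(u))
    xi <- xi + nodes$w[k] * sum(mval * p)
  }
  xi
}

gauss_nodes <- function(n, a, b) {
  g <- pracma::gaussLegendre(n, a, b)
  list(x = g$x, w = g$w)
}

# conditional counterfactual mean xi(L) = E[m(0, d(A,B), C, L) | L] and
# observed mean E[Y | L], per design
xi_fun <- function(study, nodes_u, x = 3) {
  if (study == 1) {
    function(l) enum_point(
      function(u) study1_laws$pa(l, u),
      function(u) study1_laws$pb(l, u),
      function(u) study1_laws$pc(l, u),
      function(bd, cc) study1_laws$m(0, bd, cc, l),
      nodes_u, x)
  } else {
    function(l1, l2) enum_point(
      function(u) study2_laws$pa(l1, l2, u),
      function(u) study2_laws$pb(l1, l2, u),
      function(u) study2_laws$pc(l1, l2, u),
      function(bd, cc) study2_laws$m(0, bd, cc, l1, l2),
      nodes_u, x)
  }
}

ey_point <- function(study, l, l2 = NULL, nodes_u) {
  grid <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  if (study == 1) {
    mval <- study1_laws$m(grid$a, grid$b, grid$c, l)
    pa <- function(u) study1_laws$pa(l, u)
    pb <- function(u) study1_laws$pb(l, u)
    pc <- function(u) study1_laws$pc(l, u)
  } else {
    mval <- study2_laws$m(grid$a, grid$b, grid$c, l, l2)
    pa <- function(u) study2_laws$pa(l, l2, u)
    pb <- function(u) study2_laws$pb(l, l2, u)
    pc <- function(u) study2_laws$pc(l, l2, u)
  }
  s <- 0
  for (k in seq_along(nodes_u$x)) {
    u <- nodes_u$x[k]
    p <- stats::dbinom(grid$a, 3, pa(u)) * stats::dbinom(grid$b, 3, pb(u)) *
      stats::dbinom(grid$c, 3, pc(u))
    s <- s + nodes_u$w[k] * sum(mval * p)
  }
  s
}

#' Deterministic oracle for the true counterfactual mean
#'
#' Computes the true \eqn{\mu_g} (and the observed mean `E(Y)`, hence the
#' true risk difference) under either simulation design by exact
#' enumeration of the discrete exposures and Gauss-Legendre quadrature
#' over the latent factor `U` (and over `L2` for design 2). Accuracy is
#' verified internally by node doubling.
#'
#' @param study 1 or 2.
#' @param nodes quadrature nodes per dimension (minimum 16).
#' @param x cap; the designs use `x = 3`, the maximum of the support of
#'   `B`.
#' @return list with `mu_g`, `ey`, `delta`, and `quad_error` (the change
#'   under node doubling).
#' @export
true_mu_oracle <- function(study, nodes = 64, x = 3) {
  if (nodes < 16) stop("at least 16 quadrature nodes are required")
  val <- function(nn) {
    nu <- gauss_nodes(nn, 0, 1)
    if (study == 1) {
      xi <- xi_fun(1, nu, x)
      mu <- 0.5 * (xi(0) + xi(1))
      ey <- 0.5 * (ey_point(1, 0, nodes_u = nu) +
                   ey_point(1, 1, nodes_u = nu))
    } else {
      nl2 <- gauss_nodes(nn, 0, 2)
      xi <- xi_fun(2, nu, x)
      mu <- 0; ey <- 0
      for (k in seq_along(nl2$x)) {
        l2 <- nl2$x[k]
        w <- nl2$w[k] / 2   # Unif(0,2) density
        mu <- mu + w * 0.5 * (xi(0, l2) + xi(1, l2))
        ey <- ey + w * 0.5 * (ey_point(2, 0, l2, nu) +
                              ey_point(2, 1, l2, nu))
      }
    }
    c(mu, ey)
  }
  v1 <- val(nodes)
  v2 <- val(2 * nodes)
  err <- max(abs(v2 - v1))
  if (err > 1e-8)
    warning("quadrature not converged to 1e-8; increase nodes")
  list(mu_g = v2[1], ey = v2[2], delta = v2[2] - v2[1], quad_error = err)
}

#' Deterministic oracle for the least-false MSM parameters
#'
#' Solves the population projection score
#' \eqn{0 = E[s(Z)\{\xi(L) - \mathrm{expit}(s(Z)'\theta)\}]}
#' where \eqn{\xi(L) = E[m(0, d(A,B), C, L) \mid L]} is computed by exact
#' enumeration of the discrete exposures with quadrature over the latent
#' factor `U` (design 2 additionally integrates the continuous modifier
#' `L2`). The design is `s(Z) = (1, L)` for design 1 and `(1, L2)` for
#' design 2.
#'
#' @inheritParams true_mu_oracle
#' @return list with `theta` (length 2), `score_norm`, and `quad_error`.
#' @export
least_false_oracle <- function(study, nodes = 64, x = 3) {
  if (nodes < 16) stop("at least 16 quadrature nodes are required")
  solve_proj <- function(z, w, xi) {
    S <- cbind(1, z)
    theta <- c(0, 0)
    for (it in 1:100) {
      g <- expit(drop(S %*% theta))
      sc <- drop(crossprod(S, w * (xi - g)))
      if (max(abs(sc)) < 1e-12) break
      H <- crossprod(S * (w * g * (1 - g)), S)
      theta <- theta - solve(-H, sc)
    }
    list(theta = unname(theta), score_norm = max(abs(sc)))
  }
  val <- function(nn) {
    nu <- gauss_nodes(nn, 0, 1)
    if (study == 1) {
      xi <- xi_fun(1, nu, x)
      solve_proj(z = c(0, 1), w = c(0.5, 0.5), xi = c(xi(0), xi(1)))
    } else {
      nl2 <- gauss_nodes(nn, 0, 2)
      xi <- xi_fun(2, nu, x)
      xiv <- c(vapply(nl2$x, function(l2) xi(0, l2), numeric(1)),
               vapply(nl2$x, function(l2) xi(1, l2), numeric(1)))
      solve_proj(z = rep(nl2$x, 2), w = rep(nl2$w / 2 * 0.5, 2),
                 xi = xiv)
    }
  }
  v1 <- val(nodes)
  v2 <- val(2 * nodes)
  err <- max(abs(v2$theta - v1$theta))
  list(theta = v2$theta, score_norm = v2$score_norm, quad_error = err)
}

# ---- Monte Carlo cross-checks -------------------------------------------

#' Monte Carlo cross-check of the counterfactual-mean oracle
#'
#' Simulates the counterfactual world directly: draws the natural
#' variables from the design, sets exposures to
#' `(0, min(A + B, x), C)`, draws the counterfactual outcome from the
#' true outcome law, and averages. Serves as an oracle independent of
#' the enumeration-plus-quadrature route.
#'
#' @param study 1 or 2.
#' @param n draws.
#' @param seed integer seed.
#' @param x cap.
#' @return list with `mu_g`, `se` (Monte Carlo), `ey`, `se_ey`.
#' @export
mc_counterfactual_mean <- function(study, n = 1e7, seed = 1, x = 3) {
  with_seed(seed, {
    chunk <- 1e6
    tot <- 0; toty <- 0; m <- 0
    while (m < n) {
      nn <- min(chunk, n - m)
      U <- stats::runif(nn)
      if (study == 1) {
        L <- stats::rbinom(nn, 1, 0.5)
        A <- stats::rbinom(nn, 3, study1_laws$pa(L, U))
        B <- stats::rbinom(nn, 3, study1_laws$pb(L, U))
        C <- stats::rbinom(nn, 3, study1_laws$pc(L, U))
        Yg <- stats::rbinom(nn, 1, study1_laws$m(0, pmin(A + B, x), C, L))
        Y <- stats::rbinom(nn, 1, study1_laws$m(A, B, C, L))
      } else {
        L1 <- stats::rbinom(nn, 1, 0.5)
        L2 <- stats::runif(nn, 0, 2)
        A <- stats::rbinom(nn, 3, study2_laws$pa(L1, L2, U))
        B <- stats::rbinom(nn, 3, study2_laws$pb(L1, L2, U))
        C <- stats::rbinom(nn, 3, study2_laws$pc(L1, L2, U))
        Yg <- stats::rbinom(nn, 1,
                            study2_laws$m(0, pmin(A + B, x), C, L1, L2))
        Y <- stats::rbinom(nn, 1, study2_laws$m(A, B, C, L1, L2))
      }
      tot <- tot + sum(Yg)
      toty <- toty + sum(Y)
      m <- m + nn
    }
    mu <- tot / n
    ey <- toty / n
    list(mu_g = mu, se = sqrt(mu * (1 - mu) / n),
         ey = ey, se_ey = sqrt(ey * (1 - ey) / n))
  })
}

#' Monte Carlo cross-check of the least-false oracle
#'
#' Draws the natural variables, forms the counterfactual pseudo-outcome
#' `m(0, min(A + B, x), C, L)` from the true outcome law, and solves the
#' empirical projection score onto `expit(s(Z)' theta)`. The sandwich
#' standard errors quantify the Monte Carlo uncertainty.
#'
#' @inheritParams mc_counterfactual_mean
#' @return list with `theta` and `se` (Monte Carlo standard errors).
#' @export
mc_least_false <- function(study, n = 1e7, seed = 1, x = 3) {
  with_seed(seed, {
    U <- stats::runif(n)
    if (study == 1) {
      L <- stats::rbinom(n, 1, 0.5)
      A <- stats::rbinom(n, 3, study1_laws$pa(L, U))
      B <- stats::rbinom(n, 3, study1_laws$pb(L, U))
      C <- stats::rbinom(n, 3, study1_laws$pc(L, U))
      ps <- study1_laws$m(0, pmin(A + B, x), C, L)
      z <- L
    } else {
      L1 <- stats::rbinom(n, 1, 0.5)
      L2 <- stats::runif(n, 0, 2)
      A <- stats::rbinom(n, 3, study2_laws$pa(L1, L2, U))
      B <- stats::rbinom(n, 3, study2_laws$pb(L1, L2, U))
      C <- stats::rbinom(n, 3, study2_laws$pc(L1, L2, U))
      ps <- study2_laws$m(0, pmin(A + B, x), C, L1, L2)
      z <- L2
    }
    S <- cbind(1, z)
    fit <- msm_newton(S, ps)
    V <- msm_sandwich(S, ps - expit(drop(S %*% fit$theta)), fit$theta)
    list(theta = unname(fit$theta), se = unname(sqrt(diag(V))))
  })
}

# ---- replication harness -------------------------------------------------

#' Run a Monte Carlo replication study
#'
#' Generates `reps` datasets from a simulation design, applies the
#' requested estimators to each, and aggregates bias, empirical standard
#' error, mean squared error, and 95% Wald CI coverage against the
#' design's oracle values (the deterministic [true_mu_oracle] for the
#' scalar estimand, [least_false_oracle] for the MSM parameters).
#' Replicate seeds are derived from the master seed by a counter scheme
#' so each replicate is independently re-runnable.
#'
#' @param study 1 or 2.
#' @param n per-replicate sample size.
#' @param reps number of replicates (>= 2).
#' @param scenario misspecification arm, see [scenario_specs].
#' @param estimators character subset of `c("ore", "ipw", "tmle")`.
#' @param seed master integer seed.
#' @param target `"msm"` (default; MSM design `~ L` for design 1,
#'   `~ L2` for design 2) or `"scalar"` (mu_g).
#' @return object of class `simulation_result`: a list with `summary`
#'   (data.frame of bias/se/mse/coverage per estimator and parameter),
#'   `estimates` (per-replicate values), `truth`, `n_failed`, and the
#'   run settings.
#' @export
run_replications <- function(study, n, reps, scenario = "correct",
                             estimators = c("ore", "ipw", "tmle"),
                             seed = 1, target = c("msm", "scalar")) {
  stopifnot(reps >= 2)
  target <- match.arg(target)
  specs <- scenario_specs(study, scenario)
  msm_f <- if (study == 1) ~ L else ~ L2
  if (target == "msm") {
    orc <- least_false_oracle(study)
    truth <- orc$theta
    par_names <- c("theta0", "theta1")
  } else {
    truth <- true_mu_oracle(study)$mu_g
    par_names <- "mu_g"
  }
  npar <- length(truth)

  res <- vector("list", length(estimators))
  names(res) <- estimators
  for (e in estimators)
    res[[e]] <- list(est = matrix(NA_real_, reps, npar),
                     lo = matrix(NA_real_, reps, npar),
                     hi = matrix(NA_real_, reps, npar))
  n_failed <- 0L

  for (r in seq_len(reps)) {
    rs <- (seed + r * 9973L) %% .Machine$integer.max
    d <- if (study == 1) generate_study1(n, rs) else generate_study2(n, rs)
    ok <- TRUE
    for (e in estimators) {
      fit <- tryCatch(
        dietsub(d, x = 3, estimator = e,
                outcome = specs$outcome,
                exposure_a = specs$exposure_a,
                exposure_b = specs$exposure_b,
                msm = if (target == "msm") msm_f else NULL),
        error = function(err) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      if (target == "msm") {
        res[[e]]$est[r, ] <- fit$msm$theta
        res[[e]]$lo[r, ] <- fit$msm$ci[, 1]
        res[[e]]$hi[r, ] <- fit$msm$ci[, 2]
      } else {
        res[[e]]$est[r, ] <- fit$mu_g
        res[[e]]$lo[r, ] <- fit$ci_mu[1]
        res[[e]]$hi[r, ] <- fit$ci_mu[2]
      }
    }
    if (!ok) n_failed <- n_failed + 1L
  }
  if (n_failed / reps >= 0.01)
    stop("more than 1% of replicates failed (", n_failed, "/", reps, ")")

  rows <- list()
  for (e in estimators) {
    keep <- stats::complete.cases(res[[e]]$est)
    for (j in seq_len(npar)) {
      est <- res[[e]]$est[keep, j]
      bias <- mean(est) - truth[j]
      se <- stats::sd(est)
      mse <- mean((est - truth[j])^2)
      cov <- mean(res[[e]]$lo[keep, j] <= truth[j] &
                    truth[j] <= res[[e]]$hi[keep, j])
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = e, parameter = par_names[j], bias = bias, se = se,
        mse = mse, coverage = cov, reps = sum(keep), n = n,
        scenario = scenario, seed = seed)
    }
  }
  structure(list(summary = do.call(rbind, rows), estimates = res,
                 truth = truth, n_failed = n_failed, study = study,
                 n = n, reps = reps, scenario = scenario, seed = seed,
                 target = target),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Replication study (design %d, scenario %s, n = %d, reps = %d)\n",
    x$study, x$scenario, x$n, x$reps))
  cat(sprintf("truth: %s\n",
              paste(signif(x$truth, 4), collapse = ", ")))
  df <- x$summary
  df[c("bias", "se", "mse", "coverage")] <-
    lapply(df[c("bias", "se", "mse", "coverage")], round, digits)
  print(df, row.names = FALSE)
  if (x$n_failed) cat(sprintf("failed replicates: %d\n", x$n_failed))
  invisible(x)
}

#' Synthetic cohort resembling a nutritional epidemiology study
#'
#' Generates a small synthetic table shaped like a food-frequency cohort
#' (age, body-mass index, smoking, exercise; weekly servings of a
#' processed-meat exposure, a poultry substitute, and two other food
#' groups; a rare binary death outcome). Purely synthetic: the
#' coefficients are invented for demonstration and match no real cohort.
#'
#' @param n sample size.
#' @param seed integer seed.
#' @return data.frame with columns `age, bmi, smoker, exercise,
#'   proc_meat, poultry, fish, legumes, death`.
#' @export
simulate_nhs_like <- function(n = 200, seed = 7) {
  with_seed(seed, {
    age <- round(stats::runif(n, 60, 79))
    bmi <- round(stats::rnorm(n, 26, 4), 1)
    smoker <- stats::rbinom(n, 1, 0.12)
    exercise <- round(stats::rexp(n, 1 / 3), 1)
    pref <- stats::runif(n)  # latent dietary preference
    proc_meat <- stats::rpois(n, lambda = 1.2 + 1.5 * pref)
    poultry <- pmin(stats::rpois(n, lambda = 1 + 2 * pref), 10L)
    fish <- stats::rpois(n, 1.5)
    legumes <- stats::rpois(n, 2)
    lp <- -2.4 + 0.05 * (age - 70) + 0.03 * (bmi - 26) + 0.8 * smoker -
      0.1 * exercise + 0.2 * proc_meat - 0.05 * poultry - 0.05 * fish
    death <- stats::rbinom(n, 1, expit(lp))
    data.frame(age, bmi, smoker, exercise, proc_meat, poultry, fish,
               legumes, death)
  })
}
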