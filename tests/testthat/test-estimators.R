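test_that("ORE reduces to the sample mean in degenerate settings", {
  obs <- generate_study1(2000, seed = 8)
  # constant outcome model: mu_g equals the outcome mean
  f <- dietsub(obs, x = 3, estimator = "ore", outcome = Y ~ 1)
  expect_equal(f$mu_g, mean(obs$Y))

  # everyone at A = 0 with a non-binding cap: the intervention is a no-op
  # and an intercept-containing logistic fit averages back to ybar
  d <- as.data.frame(obs)
  d$A <- 0L
  obs0 <- observed_data(d, "A", "B", "C", "L", y = "Y")
  f0 <- dietsub(obs0, x = max(obs0$support_B), estimator = "ore",
                outcome = Y ~ B + C + L)
  expect_equal(f0$mu_g, mean(obs0$Y), tolerance = 1e-10)
  expect_equal(f0$delta, 0, tolerance = 1e-10)
})

test_that("IPW solves its estimating equation on constructed data", {
  # equal weights among A = 0 records: weighted mean collapses to the
  # subgroup mean of Y
  dgp <- known_pmf_dgp(500, seed = 12)
  obs <- observed_data(dgp$data, "A", "B", "C", "L", y = "Y")
  nuis <- known_nuisance_set(obs, dgp)
  est <- dietsub:::est_ipw(obs, nuis, substitution(2))
  W <- substitution_weights(obs, nuis, substitution(2))$W
  expect_equal(est$mu_g, sum(W * obs$Y) / sum(W))
  # root of 0 = Pn[W(Y - mu)]
  expect_lt(abs(mean(W * (obs$Y - est$mu_g))), 1e-12)

  # single-record hand computation: mu = Y of the lone A = 0 record
  d <- data.frame(A = c(0L, 1L), B = c(1L, 0L), C = 0L, L = 0,
                  Y = c(1L, 0L))
  obs1 <- observed_data(d, "A", "B", "C", "L", y = "Y")
  nu <- list(pA = matrix(rep(c(.5, .5), each = 2), 2), support_A = 0:1,
             support_B = 0:1,
             pB_given_a = list(matrix(rep(c(.5, .5), each = 2), 2),
                               matrix(rep(c(.5, .5), each = 2), 2)),
             mhat_obs = c(.5, .5), mhat_int = c(.5, .5))
  class(nu) <- "nuisance_set"
  est1 <- dietsub:::est_ipw(obs1, nu, substitution(2))
  expect_equal(est1$mu_g, 1)
})

test_that("influence-function values follow the stated decomposition", {
  dgp <- known_pmf_dgp(300, seed = 2)
  obs <- observed_data(dgp$data, "A", "B", "C", "L", y = "Y")
  nuis <- known_nuisance_set(obs, dgp)
  spec <- substitution(2)
  mu <- mean(nuis$mhat_int)
  phi <- eif_values(obs, nuis, spec, mu)
  # records with A != 0: the weight kills the residual term
  off <- obs$A != 0
  expect_equal(phi[off], nuis$mhat_int[off] - mu)
  # centring at the augmentation mean with zero residuals sums to zero
  phi0 <- eif_values(obs, nuis, spec, mu,
                     mhat_obs = obs$Y)  # zero residuals
  expect_equal(sum(phi0), 0, tolerance = 1e-10)
})

test_that("TMLE solves the EIF equation and collapses to ORE when the
           fluctuation score is already zero", {
  dgp <- known_pmf_dgp(2000, seed = 17)
  obs <- observed_data(dgp$data, "A", "B", "C", "L", y = "Y")
  spec <- substitution(2)
  nuis <- known_nuisance_set(obs, dgp)
  est <- dietsub:::est_tmle(obs, nuis, spec)
  expect_lt(abs(mean(est$if_values)), 1e-8)
  expect_equal(sd(est$if_values) / sqrt(obs$n), est$se_mu)

  # build an outcome fit that already solves the weighted score: an
  # intercept-only logistic fit with the substitution weights as prior
  # weights; then epsilon is zero and TMLE equals ORE on the same fit
  W <- substitution_weights(obs, nuis, spec)$W
  g <- suppressWarnings(glm(obs$Y ~ 1, family = binomial, weights = W))
  mh <- rep(fitted(g)[1], obs$n)
  nuis2 <- known_nuisance_set(obs, dgp, mhat_obs = mh, mhat_int = mh)
  est2 <- dietsub:::est_tmle(obs, nuis2, spec)
  expect_lt(abs(est2$epsilon), 1e-8)
  expect_equal(est2$mu_g, mean(mh), tolerance = 1e-10)
})

test_that("the contrast is the outcome mean minus the counterfactual mean", {
  obs <- generate_study1(3000, seed = 23)
  sp <- scenario_specs(1, "correct")
  f <- dietsub(obs, x = 3, estimator = "tmle", outcome = sp$outcome,
               exposure_a = sp$exposure_a, exposure_b = sp$exposure_b)
  expect_equal(f$delta, mean(obs$Y) - f$mu_g)
  expect_equal(f$if_delta, (obs$Y - mean(obs$Y)) - f$if_values)

  # degenerate outcome: everything collapses to zero risk
  d <- as.data.frame(obs); d$Y <- 0L
  f0 <- dietsub(d, x = 3, estimator = "ore", outcome = Y ~ 1)
  expect_equal(f0$mu_g, 0)
  expect_equal(f0$delta, 0)
})

test_that("all three estimators agree at the truth with true nuisances", {
  dgp <- known_pmf_dgp(50000, seed = 29)
  obs <- observed_data(dgp$data, "A", "B", "C", "L", y = "Y")
  spec <- substitution(2)
  nuis <- known_nuisance_set(obs, dgp)
  mu_true <- known_dgp_mu(dgp)
  for (fn in list(dietsub:::est_ore, dietsub:::est_ipw,
                  dietsub:::est_tmle)) {
    est <- fn(obs, nuis, spec)
    tol <- 3 * max(est$se_mu, 0.004)
    expect_lt(abs(est$mu_g - mu_true), tol)
  }
})

test_that("bootstrap standard errors replace the naive ones on request", {
  obs <- generate_study1(600, seed = 83)
  sp <- scenario_specs(1, "correct")
  f <- dietsub(obs, x = 3, estimator = "ore", outcome = sp$outcome,
               boot = TRUE, boot_reps = 20, seed = 4)
  expect_equal(f$diagnostics$se_flavour, "bootstrap")
  expect_true(is.finite(f$se_mu) && f$se_mu > 0)
  # deterministic given the seed
  f2 <- dietsub(obs, x = 3, estimator = "ore", outcome = sp$outcome,
                boot = TRUE, boot_reps = 20, seed = 4)
  expect_identical(f$se_mu, f2$se_mu)
})

test_that("error paths surface informative failures", {
  # no A = 0 records: IPW and TMLE must refuse
  d <- data.frame(A = c(1L, 2L), B = c(0L, 1L), C = 0L, L = 0,
                  Y = c(0L, 1L))
  obs <- observed_data(d, "A", "B", "C", "L", y = "Y")
  nu <- list(pA = matrix(rep(c(.2, .4, .4), each = 2), 2),
             support_A = 0:2, support_B = 0:1,
             pB_given_a = rep(list(matrix(rep(c(.5, .5), each = 2), 2)),
                              3),
             mhat_obs = c(.5, .5), mhat_int = c(.5, .5))
  class(nu) <- "nuisance_set"
  expect_error(dietsub:::est_ipw(obs, nu, substitution(2)),
               "no records with A = 0")
})
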