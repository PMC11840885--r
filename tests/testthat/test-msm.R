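fit_all_msm <- function(obs, specs, msm_formula) {
  lapply(c(ore = "ore", ipw = "ipw", tmle = "tmle"), function(e)
    dietsub(obs, x = 3, estimator = e, outcome = specs$outcome,
            exposure_a = specs$exposure_a, exposure_b = specs$exposure_b,
            msm = msm_formula))
}

test_that("intercept-only projections reproduce the scalar estimators", {
  obs <- generate_study1(2000, seed = 41)
  specs <- scenario_specs(1, "correct")
  fits <- fit_all_msm(obs, specs, ~ 1)
  for (f in fits)
    expect_equal(plogis(unname(f$msm$theta[1])), f$mu_g,
                 tolerance = 1e-10)
})

test_that("a constant outcome fit projects onto a flat working model", {
  obs <- generate_study1(1500, seed = 43)
  f <- dietsub(obs, x = 3, estimator = "ore", outcome = Y ~ 1,
               msm = ~ L)
  cc <- mean(obs$Y)
  expect_equal(unname(f$msm$theta),
               c(qlogis(cc), 0), tolerance = 1e-8)
})

test_that("the targeted MSM solves both empirical score equations", {
  obs <- generate_study1(4000, seed = 47)
  specs <- scenario_specs(1, "correct")
  f <- dietsub(obs, x = 3, estimator = "tmle", outcome = specs$outcome,
               exposure_a = specs$exposure_a,
               exposure_b = specs$exposure_b, msm = ~ L)
  m <- f$msm
  S <- m$design
  W <- f$weights$W
  eta_obs <- qlogis(pmin(pmax(f$nuisances$mhat_obs, 1e-6), 1 - 1e-6))
  eta_int <- qlogis(pmin(pmax(f$nuisances$mhat_int, 1e-6), 1 - 1e-6))
  shift <- drop(S %*% m$epsilon)
  mstar_obs <- plogis(eta_obs + shift)
  mstar_int <- plogis(eta_int + shift)
  g <- plogis(drop(S %*% m$theta))
  # fluctuation score and projection score both vanish
  expect_lt(max(abs(colMeans(S * W * (obs$Y - mstar_obs)))), 1e-8)
  expect_lt(max(abs(colMeans(S * (mstar_int - g)))), 1e-8)
  # hence the empirical mean of the full EIF bracket vanishes too
  expect_lt(max(abs(colMeans(S * m$phi))), 1e-8)
})

test_that("sandwich covariance is symmetric PSD and order-invariant", {
  obs <- generate_study1(3000, seed = 53)
  specs <- scenario_specs(1, "correct")
  f <- dietsub(obs, x = 3, estimator = "tmle", outcome = specs$outcome,
               exposure_a = specs$exposure_a,
               exposure_b = specs$exposure_b, msm = ~ L)
  V <- f$msm$vcov
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE)$values >= 0))

  # permuting records leaves the covariance unchanged
  d <- as.data.frame(obs)
  set.seed(1); d2 <- d[sample(nrow(d)), ]
  f2 <- dietsub(d2, x = 3, estimator = "tmle", outcome = specs$outcome,
                exposure_a = specs$exposure_a,
                exposure_b = specs$exposure_b, msm = ~ L)
  expect_equal(f2$msm$vcov, V, tolerance = 1e-8)

  # all-zero residuals give the zero matrix
  S <- f$msm$design
  expect_equal(msm_sandwich(S, rep(0, nrow(S)), f$msm$theta),
               matrix(0, 2, 2), ignore_attr = TRUE)
})

test_that("intercept-only sandwich matches the scalar delta-method", {
  obs <- generate_study1(2500, seed = 59)
  specs <- scenario_specs(1, "correct")
  f <- dietsub(obs, x = 3, estimator = "tmle", outcome = specs$outcome,
               exposure_a = specs$exposure_a,
               exposure_b = specs$exposure_b, msm = ~ 1)
  # Var(theta0) maps to Var(mu) through the logistic derivative g(1-g)
  mu <- f$mu_g
  # sd() uses the n-1 denominator, the sandwich the raw second moment,
  # so agreement is to O(1/n)
  se_theta_mapped <- sqrt(f$msm$vcov[1, 1]) * mu * (1 - mu)
  expect_equal(se_theta_mapped, f$se_mu, tolerance = 1e-3)
})

test_that("MSM estimators recover the least-false parameters with
           rich nuisance fits", {
  orc <- least_false_oracle(1)
  obs <- generate_study1(50000, seed = 61)
  specs <- scenario_specs(1, "correct")
  fits <- fit_all_msm(obs, specs, ~ L)
  for (f in fits) {
    se <- f$msm$se
    expect_lt(max(abs(f$msm$theta - orc$theta) / pmax(se, 0.01)), 3.5)
  }
})

test_that("rank-deficient designs are refused", {
  obs <- generate_study1(500, seed = 67)
  d <- as.data.frame(obs)
  d$L2 <- d$L  # duplicated column
  expect_error(
    dietsub(d, c_cols = "C", l_cols = c("L", "L2"), x = 3,
            estimator = "ore", outcome = Y ~ A + B + C + L,
            msm = ~ L + L2),
    "rank")
})
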