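test_that("the capped dose map adds then caps", {
  expect_equal(substitute_dose(2, 1, 7), 3)
  expect_equal(substitute_dose(0, 5, 7), 5)
  expect_equal(substitute_dose(4, 6, 7), 7)
  expect_equal(substitute_dose(c(2, 0, 4), c(1, 5, 6), 7), c(3, 5, 7))
  expect_error(substitute_dose(-1, 0, 7), "non-negative")
  expect_error(substitution(0), "positive integer")
})

test_that("applying the strategy zeroes A, caps B, leaves C alone", {
  d <- data.frame(A = 2L, B = 1L, C = 4L, L = 0, Y = 0L)
  obs <- observed_data(d, "A", "B", "C", "L", y = "Y")
  out <- apply_intervention(obs, substitution(7))
  expect_equal(out$A_int, 0L)
  expect_equal(out$B_int, 3)
  expect_equal(out$C, 4L)

  # no-op on B when everyone already has A = 0 and the cap is not binding
  d <- data.frame(A = 0L, B = c(0L, 2L, 3L), C = 0L, L = 0,
                  Y = c(0L, 1L, 0L))
  obs <- observed_data(d, "A", "B", "C", "L", y = "Y")
  out <- apply_intervention(obs, substitution(3))
  expect_equal(out$B_int, obs$B)

  # cap binds: (A=3, B=3) with x = 3 lands at 3
  d <- data.frame(A = 3L, B = 3L, C = 0L, L = 0, Y = 0L)
  obs <- observed_data(d, "A", "B", "C", "L", y = "Y")
  expect_equal(apply_intervention(obs, substitution(3))$B_int, 3)
})

test_that("the intervened-dose kernel is a consistent point mass", {
  expect_equal(q_pointmass(3, 2, 1, 7), 1L)
  expect_equal(q_pointmass(2, 2, 1, 7), 0L)
  expect_equal(q_pointmass(7, 4, 6, 7), 1L)
  # degenerate kernel sums to 1 over doses, and matches the dose map
  for (a in 0:4) for (b in 0:4) {
    x <- 3
    expect_equal(sum(q_pointmass(0:x, a, b, x)), 1)
    expect_equal(which(q_pointmass(0:x, a, b, x) == 1) - 1,
                 substitute_dose(a, b, x))
  }
})

test_that("qtilde matches hand-derived values on simple laws", {
  # A, B iid uniform on {0,1}, cap 2: dose = A + B
  expect_equal(qtilde_pmf(0:2, p_a = c(.5, .5),
                          p_b = rbind(c(.5, .5), c(.5, .5)), x = 2),
               c(0.25, 0.5, 0.25))
  # A degenerate at 1, B uniform on {0,1}, cap 1: dose is always 1
  expect_equal(qtilde_pmf(1, p_a = c(0, 1),
                          p_b = rbind(c(.5, .5), c(.5, .5)), x = 1), 1)
  expect_error(qtilde_pmf(0, p_a = c(.6, .6), p_b = c(.5, .5), x = 1),
               "sum to 1")
  expect_error(qtilde_pmf(5, p_a = c(.5, .5), p_b = c(.5, .5), x = 2),
               "0..x")
})

test_that("qtilde equals exhaustive enumeration and normalises", {
  set.seed(101)
  for (r in 1:100) {
    ka <- sample(2:10, 1)
    kb <- sample(2:10, 1)
    x <- sample(1:(ka + kb - 2), 1)
    p_a <- random_pmf(ka)
    p_b <- t(replicate(ka, random_pmf(kb)))
    got <- qtilde_pmf(0:x, p_a, p_b, x)
    want <- vapply(0:x, qtilde_brute, numeric(1), p_a = p_a, p_b = p_b,
                   x = x)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_lt(abs(sum(got) - 1), 1e-10)
  }
})

test_that("substitution weights follow the identification display", {
  # records with A != 0 get exactly zero without touching the models
  dgp <- known_pmf_dgp(400, seed = 5)
  obs <- observed_data(dgp$data, "A", "B", "C", "L", y = "Y")
  nuis <- known_nuisance_set(obs, dgp)
  w <- substitution_weights(obs, nuis, substitution(2))
  expect_true(all(w$W[obs$A != 0] == 0))
  expect_true(all(w$W >= 0))

  # hand computation: single record (A=0, B=1), uniform pmfs on {0,1},
  # cap 2 => W = qtilde(1) / (pA(0) pB(1|0)) = 0.5 / 0.25 = 2
  d <- data.frame(A = 0L, B = 1L, C = 0L, L = 0, Y = 1L)
  obs1 <- observed_data(d, "A", "B", "C", "L", y = "Y")
  nu <- list(pA = matrix(c(.5, .5), 1), support_A = 0:1, support_B = 0:1,
             pB_given_a = list(matrix(c(.5, .5), 1),
                               matrix(c(.5, .5), 1)),
             mhat_obs = 0.5, mhat_int = 0.5)
  class(nu) <- "nuisance_set"
  w1 <- substitution_weights(obs1, nu, substitution(2))
  expect_equal(w1$W, 2)

  # with the true pmfs, the weights average to one and reweight Y to the
  # counterfactual mean (law of total probability for qtilde)
  dgp <- known_pmf_dgp(40000, seed = 6)
  obs <- observed_data(dgp$data, "A", "B", "C", "L", y = "Y")
  nuis <- known_nuisance_set(obs, dgp)
  w <- substitution_weights(obs, nuis, substitution(2))
  se <- sd(w$W) / sqrt(obs$n)
  expect_lt(abs(mean(w$W) - 1), 3 * se)
  mu_true <- known_dgp_mu(dgp)
  se_wy <- sd(w$W * obs$Y) / sqrt(obs$n)
  expect_lt(abs(mean(w$W * obs$Y) - mu_true), 3 * se_wy)
})
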