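# Shared helpers: small constructed datasets, random pmfs, a brute-force
# oracle for the marginalised intervened-dose pmf, and a hand-built
# nuisance set with known (true) exposure pmfs.

model_frame_for_tests <- function(obs) {
  data.frame(A = obs$A, B = obs$B, obs$C, obs$L, Y = obs$Y,
             check.names = FALSE)
}

toy_frame <- function() {
  data.frame(A = c(2, 0, 1), B = c(1, 5, 6), C = c(0, 1, 2),
             L = c(0, 1, 0), Y = c(0, 1, 0))
}

toy_obs <- function() {
  observed_data(toy_frame(), a = "A", b = "B", c_cols = "C",
                l_cols = "L", y = "Y")
}

random_pmf <- function(k) {
  p <- stats::rexp(k)
  p / sum(p)
}

# exhaustive-enumeration oracle for the intervened-dose pmf: push every
# (a, b) pair through the dose map and accumulate probability
qtilde_brute <- function(b_dagger, p_a, p_b, x,
                         support_a = seq_along(p_a) - 1L,
                         support_b = seq_len(ncol(p_b)) - 1L) {
  tot <- 0
  for (ai in seq_along(support_a)) for (bi in seq_along(support_b)) {
    d <- min(support_a[ai] + support_b[bi], x)
    if (d == b_dagger) tot <- tot + p_a[ai] * p_b[ai, bi]
  }
  tot
}

# a single-stratum data-generating process with known exposure pmfs and a
# known outcome law: A ~ p_a on {0,1,2}, B | A = a ~ p_b[a+1, ] on
# {0,1,2}, Y ~ Ber(expit(-0.5 + 0.8 B - 0.6 A)); no covariates beyond a
# constant column.
known_pmf_dgp <- function(n, seed) {
  p_a <- c(0.5, 0.3, 0.2)
  p_b <- rbind(c(0.2, 0.5, 0.3),
               c(0.4, 0.4, 0.2),
               c(0.6, 0.3, 0.1))
  set.seed(seed)
  A <- sample(0:2, n, TRUE, p_a)
  B <- vapply(A, function(a) sample(0:2, 1, TRUE, p_b[a + 1, ]),
              integer(1))
  m <- function(a, b) plogis(-0.5 + 0.8 * b - 0.6 * a)
  Y <- rbinom(n, 1, m(A, B))
  d <- data.frame(A = A, B = B, C = 0L, L = 0, Y = Y)
  list(data = d, p_a = p_a, p_b = p_b, m = m)
}

# hand-built nuisance set carrying the TRUE exposure pmfs of
# known_pmf_dgp (and a supplied outcome evaluation), bypassing fitting
known_nuisance_set <- function(obs, dgp, x = 2,
                               mhat_obs = NULL, mhat_int = NULL) {
  n <- obs$n
  if (is.null(mhat_obs)) mhat_obs <- dgp$m(obs$A, obs$B)
  if (is.null(mhat_int))
    mhat_int <- dgp$m(0, substitute_dose(obs$A, obs$B, x))
  structure(list(
    mhat_obs = mhat_obs, mhat_int = mhat_int,
    pA = matrix(rep(dgp$p_a, each = n), n),
    pB_given_a = lapply(1:3, function(ai)
      matrix(rep(dgp$p_b[ai, ], each = n), n)),
    support_A = 0:2, support_B = 0:2,
    folds = 1L, fold_id = rep(1L, n), seed = NULL,
    models = list(), specs = list(
      outcome = list(backend = "known"),
      exposure_a = list(backend = "known"),
      exposure_b = list(backend = "known"))
  ), class = "nuisance_set")
}

# true counterfactual mean for known_pmf_dgp by enumeration
known_dgp_mu <- function(dgp, x = 2) {
  mu <- 0
  for (ai in 1:3) for (bi in 1:3) {
    a <- ai - 1; b <- bi - 1
    mu <- mu + dgp$p_a[ai] * dgp$p_b[ai, bi] * dgp$m(0, min(a + b, x))
  }
  mu
}
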