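#' Capped substitution strategy
#'
#' Defines the intervention: set the replaced exposure `A` to 0 and the
#' substitute exposure `B` to `d(A, B) = min(A + B, x)`, leaving other food
#' groups unchanged. The cap `x` is typically the maximum of the support of
#' `B`, but may be set a priori to a lower acceptable limit.
#'
#' @param x positive integer cap on the intervened substitute intake.
#' @return an object of class `substitution`.
#' @examples
#' substitution(7)
#' @export
substitution <- function(x) {
  if (!is.numeric(x) || length(x) != 1 || x < 1 || x != round(x))
    stop("cap x must be a single positive integer")
  structure(list(x = as.integer(x), target_A = 0L), class = "substitution")
}

#' @export
print.substitution <- function(x, ...) {
  cat(sprintf(
    "Substitution strategy: A -> 0, B -> min(A + B, %d), C unchanged\n",
    x$x))
  invisible(x)
}

#' Capped dose map d(a, b)
#'
#' The intervened substitute dose: `a + b` when `a + b <= x`, else the cap
#' `x`. Vectorised over `a` and `b`.
#'
#' @param a,b non-negative integer intakes of the replaced and substitute
#'   foods.
#' @param x positive integer cap.
#' @return integer vector of intervened doses, always `<= x`.
#' @examples
#' substitute_dose(2, 1, 7) # 3
#' substitute_dose(4, 6, 7) # capped at 7
#' @export
substitute_dose <- function(a, b, x) {
  if (any(a < 0) || any(b < 0)) stop("a and b must be non-negative")
  if (length(x) != 1 || x < 1) stop("x must be a single positive integer")
  pmin(a + b, x)
}

#' Apply the substitution strategy to a dataset
#'
#' @param obs an [observed_data] object.
#' @param spec a [substitution] strategy.
#' @return data.frame with columns `A_int` (all 0), `B_int` (`d(A,B)`),
#'   and the unchanged `C` columns.
#' @export
apply_intervention <- function(obs, spec) {
  stopifnot(inherits(obs, "observed_data"), inherits(spec, "substitution"))
  data.frame(A_int = 0L,
             B_int = substitute_dose(obs$A, obs$B, spec$x),
             obs$C, check.names = FALSE)
}

#' Degenerate intervened-exposure kernel q
#'
#' The conditional law of the intervened substitute dose given natural
#' intakes is a point mass: `q(b_dagger | a, b) = 1` iff
#' `b_dagger = d(a, b)`.
#'
#' @param b_dagger candidate intervened dose.
#' @param a,b natural intakes.
#' @param x positive integer cap.
#' @return 0/1, vectorised.
#' @export
q_pointmass <- function(b_dagger, a, b, x) {
  if (any(b_dagger < 0)) stop("b_dagger must be non-negative")
  as.integer(b_dagger == substitute_dose(a, b, x))
}

#' Marginalised intervened-dose pmf
#'
#' The pmf of the intervened substitute dose after marginalising the
#' degenerate kernel over the natural joint law of `(A, B)` at fixed
#' covariates:
#' \deqn{\tilde q(b^\dagger) = \sum_a \{ I(a \le b^\dagger \le x)
#'   p_B(b^\dagger - a \mid a) + I(b^\dagger = x)[1 - F_B(x - a \mid a)]\}
#'   p_A(a)}
#' with \eqn{F_B(t) = 0} for \eqn{t < 0}, so natural `A` values above the
#' cap contribute their whole mass to the capped dose.
#'
#' @param b_dagger intervened dose(s) at which to evaluate, each in
#'   `0..x`.
#' @param p_a numeric pmf of `A` over `support_a` (sums to 1).
#' @param p_b numeric matrix of conditional pmfs of `B` given `A = a`:
#'   rows indexed by `support_a`, columns by `support_b`; each row sums
#'   to 1. A single vector is recycled across `a`.
#' @param x positive integer cap.
#' @param support_a,support_b integer supports; default `0,1,...` matching
#'   the lengths of `p_a` and the columns of `p_b`.
#' @return numeric vector of probabilities, one per `b_dagger`.
#' @examples
#' # uniform A and B on {0,1}, cap 2: doses 0,1,2 w.p. 1/4, 1/2, 1/4
#' qtilde_pmf(0:2, p_a = c(.5, .5), p_b = rbind(c(.5, .5), c(.5, .5)),
#'            x = 2)
#' @export
qtilde_pmf <- function(b_dagger, p_a, p_b, x,
                       support_a = seq_along(p_a) - 1L,
                       support_b = NULL) {
  if (is.vector(p_b)) p_b <- matrix(p_b, nrow = length(p_a),
                                    ncol = length(p_b), byrow = TRUE)
  if (is.null(support_b)) support_b <- seq_len(ncol(p_b)) - 1L
  if (nrow(p_b) != length(p_a))
    stop("p_b must have one row per support_a value")
  if (abs(sum(p_a) - 1) > 1e-8) stop("p_a does not sum to 1")
  rs <- rowSums(p_b)
  if (any(abs(rs - 1) > 1e-8)) stop("rows of p_b do not sum to 1")
  if (any(b_dagger < 0 | b_dagger > x))
    stop("b_dagger must lie in 0..x")

  # F_B(t | a) = P(B <= t | a); 0 for t < 0
  cdf_b <- function(t, ai) {
    keep <- support_b <= t
    if (!any(keep)) return(0)
    sum(p_b[ai, keep])
  }
  pmf_b <- function(v, ai) {
    j <- match(v, support_b)
    if (is.na(j)) 0 else p_b[ai, j]
  }
  vapply(b_dagger, function(bd) {
    tot <- 0
    for (ai in seq_along(support_a)) {
      a <- support_a[ai]
      term <- 0
      if (a <= bd && bd <= x) term <- term + pmf_b(bd - a, ai)
      if (bd == x) term <- term + (1 - cdf_b(x - a, ai))
      tot <- tot + term * p_a[ai]
    }
    tot
  }, numeric(1))
}

#' Inverse-probability weights for the substitution strategy
#'
#' Computes the per-record weight
#' \deqn{W_i = I(A_i = 0)\, \tilde q(B_i \mid C_i, L_i) /
#'   \{\hat\lambda_A(0 \mid C_i, L_i)\,\hat\lambda_B(B_i \mid 0, C_i, L_i)\}}
#' used by the IPW estimator and as the TMLE fluctuation weight. Records
#' with `A != 0` receive exactly 0 without evaluating the denominator.
#' Estimated denominator densities below `floor` are raised to `floor`
#' and counted in the truncation report.
#'
#' @param obs an [observed_data] object.
#' @param nuis a [fit_nuisances] result (only the exposure models are
#'   used).
#' @param spec a [substitution] strategy.
#' @param floor lower truncation for each estimated denominator density.
#' @return list of class `substitution_weights` with components `W`,
#'   `qtilde` (the per-record intervened-dose density at the observed
#'   `B`), `denom_A`, `denom_B`, and `n_truncated`.
#' @export
substitution_weights <- function(obs, nuis, spec, floor = 1e-6) {
  stopifnot(inherits(obs, "observed_data"), inherits(spec, "substitution"))
  x <- spec$x
  sa <- nuis$support_A
  sb <- nuis$support_B
  n <- obs$n
  pA <- nuis$pA                   # n x |sa|, p(A = a | C, L)
  pB <- nuis$pB_given_a           # list over a: n x |sb|, p(B = b | a, C, L)

  # qtilde at the observed B for every record (vectorised over records)
  qt <- numeric(n)
  Bobs <- obs$B
  for (ai in seq_along(sa)) {
    a <- sa[ai]
    pBa <- pB[[ai]]
    # density term: I(a <= B <= x) pB(B - a | a)
    j <- match(Bobs - a, sb)
    dens <- ifelse(!is.na(j) & a <= Bobs & Bobs <= x,
                   pBa[cbind(seq_len(n), ifelse(is.na(j), 1L, j))], 0)
    # cap term: I(B = x) (1 - F_B(x - a | a)); F_B(t)=0 for t<0
    keep <- which(sb <= x - a)
    Fb <- if (length(keep)) rowSums(pBa[, keep, drop = FALSE]) else
      numeric(n)
    cap <- ifelse(Bobs == x, 1 - Fb, 0)
    qt <- qt + (dens + cap) * pA[, ai]
  }

  iz <- obs$A == 0
  a0 <- match(0L, sa)
  if (is.na(a0)) stop("A = 0 is not in the modelled support of A")
  dA <- pA[, a0]
  jB <- match(Bobs, sb)
  dB <- pB[[a0]][cbind(seq_len(n), jB)]

  n_trunc <- sum(iz & (dA < floor | dB < floor))
  dA <- pmax(dA, floor)
  dB <- pmax(dB, floor)

  W <- ifelse(iz, qt / (dA * dB), 0)
  structure(list(W = W, qtilde = qt, denom_A = dA, denom_B = dB,
                 n_truncated = n_trunc, floor = floor),
            class = "substitution_weights")
}
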