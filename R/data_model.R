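#' Validate an observed-data table for substitution analysis
#'
#' Builds the observed-data structure used throughout the package: baseline
#' covariates `L`, the exposure to be replaced `A`, the substitute exposure
#' `B`, other food-group exposures `C` (possibly several columns), and a
#' binary outcome `Y`. Exposures must be non-negative integer counts (e.g.
#' weekly servings); fractional servings must be rounded or binned by the
#' caller before validation -- silent coercion is refused.
#'
#' Under the determinism assumption, planned intake equals actual intake, so
#' the planned-intake variables are aliases of `A`, `B`, `C` and are not
#' stored separately.
#'
#' @param data a data.frame, one row per subject, no missing values.
#' @param a,b,y single column names for the replaced exposure, the
#'   substitute exposure, and the binary outcome.
#' @param c_cols character vector of column names for other food groups
#'   (at least one).
#' @param l_cols character vector of baseline covariate column names
#'   (binary or continuous; may be empty).
#' @return an object of class `observed_data`: a list with components
#'   `A`, `B` (integer vectors), `C` (integer matrix), `L` (data.frame),
#'   `Y` (0/1 integer vector), `support_A`, `support_B` (ordered integer
#'   supports), `n`, and `roles` (the column-name mapping).
#' @examples
#' d <- data.frame(A = c(2, 0, 1), B = c(1, 5, 6), C = c(0, 1, 2),
#'                 L = c(0, 1, 0), Y = c(0, 1, 0))
#' obs <- observed_data(d, a = "A", b = "B", c_cols = "C", l_cols = "L",
#'                      y = "Y")
#' obs$support_A
#' @export
observed_data <- function(data, a, b, c_cols, l_cols = character(), y) {
  stopifnot(is.data.frame(data))
  needed <- c(a, b, c_cols, l_cols, y)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  n <- nrow(data)
  if (n < 1L) stop("data must contain at least one record")

  check_count <- function(col) {
    v <- data[[col]]
    if (!is.numeric(v)) stop("exposure column '", col, "' is not numeric")
    bad <- which(is.na(v))
    if (length(bad))
      stop("missing value in column '", col, "' at row ", bad[1])
    frac <- which(v != round(v))
    if (length(frac))
      stop("non-integer exposure value ", v[frac[1]], " in column '", col,
           "' at row ", frac[1],
           " (round or bin fractional servings before validation)")
    neg <- which(v < 0)
    if (length(neg))
      stop("negative exposure value in column '", col, "' at row ", neg[1])
    as.integer(round(v))
  }

  A <- check_count(a)
  B <- check_count(b)
  C <- vapply(c_cols, check_count, integer(n))
  if (is.null(dim(C))) C <- matrix(C, nrow = n, dimnames = list(NULL, c_cols))

  Yv <- data[[y]]
  if (anyNA(Yv)) stop("missing value in outcome column '", y, "'")
  if (!all(Yv %in% c(0, 1)))
    stop("outcome column '", y, "' must be binary 0/1")
  Y <- as.integer(Yv)

  L <- data[, l_cols, drop = FALSE]
  for (col in l_cols) {
    if (anyNA(L[[col]])) stop("missing value in covariate column '", col, "'")
    if (!is.numeric(L[[col]]))
      stop("covariate column '", col, "' must be numeric")
  }

  structure(list(
    A = A, B = B, C = C, L = L, Y = Y,
    support_A = sort(unique(A)),
    support_B = sort(unique(B)),
    n = n,
    roles = list(a = a, b = b, c = c_cols, l = l_cols, y = y)
  ), class = "observed_data")
}

#' @export
print.observed_data <- function(x, ...) {
  cat("Observed substitution-analysis data\n")
  cat(sprintf("  n = %d records\n", x$n))
  cat(sprintf("  A ('%s'): support {%s}, P(A=0) = %.3f\n", x$roles$a,
              paste(x$support_A, collapse = ","), mean(x$A == 0)))
  cat(sprintf("  B ('%s'): support {%s}\n", x$roles$b,
              paste(x$support_B, collapse = ",")))
  cat(sprintf("  C: %d column(s); L: %d column(s)\n",
              ncol(x$C), ncol(x$L)))
  cat(sprintf("  Y ('%s'): mean %.3f\n", x$roles$y, mean(x$Y)))
  invisible(x)
}

#' @export
as.data.frame.observed_data <- function(x, ...) {
  d <- data.frame(A = x$A, B = x$B, x$C, x$L, Y = x$Y,
                  check.names = FALSE)
  names(d)[1:2] <- c(x$roles$a, x$roles$b)
  names(d)[ncol(d)] <- x$roles$y
  d
}

# internal: the modelling frame with canonical names A, B plus the original
# C and L column names; outcome column named Y
model_frame <- function(obs) {
  d <- data.frame(A = obs$A, B = obs$B, obs$C, obs$L, Y = obs$Y,
                  check.names = FALSE)
  d
}

#' Empirical positivity diagnostics for a capped substitution strategy
#'
#' The positivity condition requires that every intervened exposure level
#' `(A = 0, B = b)` that the strategy can produce within a covariate stratum
#' is also observed in the data within that stratum, and in particular that
#' some individuals have `A = 0` everywhere. This function checks the
#' condition empirically on coarsened `(C, L)` strata: for each stratum and
#' each intervened value `b = d(A, B)` arising in it, it reports whether any
#' record with `A = 0, B = b` exists in the stratum.
#'
#' @param obs an [observed_data] object.
#' @param x positive integer cap on the substitute exposure.
#' @param coarsen optional function mapping the `(C, L)` data.frame to a
#'   vector of stratum labels. The default uses exact levels of discrete
#'   columns and empirical quartiles of continuous columns (more than 10
#'   distinct values).
#' @return an object of class `positivity_report` with components
#'   `n_cells_checked`, `violating_cells` (data.frame of stratum and
#'   intervened B value with no empirical support), `fraction_A_zero`,
#'   and `n_empty_strata`.
#' @export
positivity_diagnostics <- function(obs, x, coarsen = NULL) {
  stopifnot(inherits(obs, "observed_data"), x >= 1)
  cl <- data.frame(obs$C, obs$L, check.names = FALSE)
  if (is.null(coarsen)) coarsen <- default_coarsening
  strata <- coarsen(cl)
  if (length(strata) != obs$n)
    stop("coarsening must return one stratum label per record")

  b_int <- substitute_dose(obs$A, obs$B, x)
  cells <- 0L
  viol <- list()
  empty <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (!length(idx)) { empty <- empty + 1L; next }
    levels_b <- unique(b_int[idx])
    have <- unique(obs$B[idx][obs$A[idx] == 0])
    for (bb in levels_b) {
      cells <- cells + 1L
      if (!(bb %in% have))
        viol[[length(viol) + 1L]] <- data.frame(stratum = s,
                                                b_intervened = bb)
    }
  }
  violating <- if (length(viol)) do.call(rbind, viol) else
    data.frame(stratum = character(), b_intervened = integer())
  structure(list(
    n_cells_checked = cells,
    violating_cells = violating,
    fraction_A_zero = mean(obs$A == 0),
    n_empty_strata = empty
  ), class = "positivity_report")
}

default_coarsening <- function(cl) {
  lab <- rep("", nrow(cl))
  for (j in seq_len(ncol(cl))) {
    v <- cl[[j]]
    if (length(unique(v)) > 10) {
      qs <- unique(stats::quantile(v, probs = c(0.25, 0.5, 0.75)))
      v <- findInterval(v, qs)
    }
    lab <- paste(lab, v, sep = "|")
  }
  lab
}

#' @export
print.positivity_report <- function(x, ...) {
  cat("Empirical positivity diagnostics\n")
  cat(sprintf("  P(A = 0) = %.3f\n", x$fraction_A_zero))
  cat(sprintf("  cells checked: %d; violations: %d\n",
              x$n_cells_checked, nrow(x$violating_cells)))
  if (nrow(x$violating_cells)) {
    cat("  cells with no empirical support (A=0, B=b within stratum):\n")
    print(utils::head(x$violating_cells, 10))
  }
  if (x$n_empty_strata)
    cat(sprintf("  strata skipped (no records): %d\n", x$n_empty_strata))
  invisible(x)
}
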