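#' Two-sided Mann-Whitney test with tie-corrected normal approximation
#'
#' Computes the rank-sum statistic U1 of the first group from midranks and
#' the tie-corrected standardised statistic
#' `z = (U1 - n1 n2 / 2) / sigma`, where `sigma` uses the usual tie
#' correction; no continuity correction is applied (a flag restores it).
#' The two-sided p-value comes from the standard normal tail. For small
#' samples (`n1 + n2 <= exact_max`, default 12) an exact permutation
#' p-value over all group assignments is also returned.
#'
#' The sign convention follows the group order: `z < 0` when the first
#' group tends to have smaller values.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param continuity Apply a 0.5 continuity correction to z (default FALSE).
#' @param exact_max Compute the exact permutation p when `n1 + n2` is at
#'   most this (default 12; set 0 to skip).
#' @return List of class `mann_whitney`: `u1`, `z`, `p_two_sided`, `n1`,
#'   `n2`, `p_exact` (NA when not computed), `tie_correction`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y, continuity = FALSE, exact_max = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                       # midranks
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    z <- 0
    p <- 1
  } else {
    d <- u1 - mu
    if (continuity && d != 0) d <- d - sign(d) * 0.5
    z <- d / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  p_exact <- NA_real_
  if (N <= exact_max && sigma2 > 0) {
    v <- c(x, y)
    rk <- rank(v)
    combos <- utils::combn(N, n1)
    u_all <- apply(combos, 2L, function(idx) sum(rk[idx])) - n1 * (n1 + 1) / 2
    p_exact <- mean(abs(u_all - mu) >= abs(u1 - mu) - 1e-12)
  }
  structure(list(u1 = u1, z = z, p_two_sided = min(1, p),
                 n1 = n1, n2 = n2, p_exact = p_exact,
                 tie_correction = tie_term > 0), class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney test (two-sided): U1 = %.1f, Z = %.3f, p = %.4g  (n1 = %d, n2 = %d)%s\n",
              x$u1, x$z, x$p_two_sided, x$n1, x$n2,
              if (!is.na(x$p_exact)) sprintf("; exact p = %.4g", x$p_exact) else ""))
  invisible(x)
}

#' Kruskal-Wallis test for more than two groups
#'
#' Thin wrapper over [stats::kruskal.test()] (tie-corrected H, chi-square
#' p with k - 1 df) with input validation.
#'
#' @param groups List of two or more nonempty numeric vectors.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("all groups must be nonempty")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Pearson correlation coefficient
#'
#' The product-moment correlation of two equal-length signal vectors, as
#' used for line-profile co-localisation.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return r in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in one of the inputs")
  stats::cor(x, y, method = "pearson")
}

#' Compare a feature between sphere- and network-forming RNAs
#'
#' Runs the two-sided Mann-Whitney test on one feature of a source-data
#' table with a fixed group orientation — sphere first, network second — so
#' that signed Z values are comparable across runs (negative Z: the sphere
#' group is smaller).
#'
#' @param records data.frame with columns `observed` and the feature.
#' @param feature One of `"length_nt"`, `"n_are"`, `"gc_frac"`, `"ned"`.
#' @param subset Optional logical vector (or expression result) selecting
#'   rows before the comparison.
#' @param ... Passed to [mann_whitney()].
#' @return A `mann_whitney` result.
#' @export
compare_groups <- function(records, feature = c("ned", "length_nt", "n_are", "gc_frac"),
                           subset = NULL, ...) {
  feature <- match.arg(feature)
  if (!is.null(subset)) records <- records[subset, , drop = FALSE]
  sph <- records[[feature]][records$observed == "sphere"]
  net <- records[[feature]][records$observed == "network"]
  if (length(sph) == 0L || length(net) == 0L) {
    stop("both morphology groups must be nonempty after subsetting")
  }
  mann_whitney(sph, net, ...)
}
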