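#' Exact McNemar test from discordant counts
#'
#' Two-sided exact McNemar: with discordant counts b and c, the p-value is
#' \code{min(1, 2 * P(X <= min(b, c)))} for X ~ Binomial(b + c, 1/2);
#' p = 1 when b + c = 0. Used to compare paired classifier decisions on the
#' same subjects.
#'
#' @param b,c non-negative discordant counts.
#' @return the exact two-sided p-value.
#' @examples
#' mcnemarExact(17, 6)   # 0.0347
#' @export
mcnemarExact <- function(b, c) {
  if (b < 0 || c < 0) stop("counts must be non-negative")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}

#' Chi-square survival function
#'
#' Upper-tail probability P(X > x) for X ~ chi-square(df).
#'
#' @param x non-negative statistic.
#' @param df degrees of freedom (>= 1).
#' @return upper-tail probability.
#' @export
chi2Sf <- function(x, df) {
  if (any(x < 0)) stop("x must be >= 0")
  if (any(df < 1)) stop("invalid df")
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Friedman rank test over a block design
#'
#' Within-block midranks; the statistic is
#' \code{12 n / (k (k + 1)) * sum_j (Rbar_j - (k + 1)/2)^2} over the k
#' condition mean ranks, referred to chi-square with k - 1 df. Ties are
#' midranked without a tie-correction denominator; the result flags whether
#' ties occurred. Identical values in every block give statistic 0, p 1.
#'
#' @param blockMatrix subjects x conditions numeric matrix.
#' @return list(statistic, df, p, ties).
#' @export
friedmanTest <- function(blockMatrix) {
  m <- as.matrix(blockMatrix)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 blocks and >= 2 conditions")
  ranks <- t(apply(m, 1, rank))
  ties <- any(apply(m, 1, anyDuplicated) > 0)
  rbar <- colMeans(ranks)
  stat <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  list(statistic = stat, df = k - 1, p = chi2Sf(stat, k - 1), ties = ties)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1
#' (delegates to \code{stats::p.adjust}).
#'
#' @param p p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test
#'
#' U from midranked rank sums (reported for the first sample). Exact
#' two-sided p when both groups have at most \code{exactMax} observations
#' and the pooled data has no ties; otherwise the normal approximation with
#' tie correction (no continuity correction). Rank-based, hence invariant
#' to monotone transformations of the pooled data.
#'
#' @param x,y non-empty numeric samples.
#' @param exactMax exact/approximate switch per-group size (default 8).
#' @return list(U, p, method).
#' @export
mannWhitneyU <- function(x, y, exactMax = 8) {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  hasTies <- anyDuplicated(pooled) > 0
  if (n1 <= exactMax && n2 <= exactMax && !hasTies) {
    pLe <- stats::pwilcox(U, n1, n2)
    pGe <- 1 - if (U >= 1) stats::pwilcox(U - 1, n1, n2) else 0
    p <- min(1, 2 * min(pLe, pGe))
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tieTab <- table(pooled)
    tieSum <- sum(tieTab^3 - tieTab)
    sig2 <- n1 * n2 / 12 * ((N + 1) - tieSum / (N * (N - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = U, p = p, method = method)
}
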