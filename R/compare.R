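#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired test of the null hypothesis that the median of the
#' differences `x - y` is zero. Zero differences are discarded, tied
#' absolute differences are mid-ranked. For n <= `exact_max` non-zero
#' pairs, the two-sided p-value comes from full enumeration of all 2^n
#' sign assignments of the (possibly tied) ranks; above that, the normal
#' approximation with continuity and tie correction is used.
#'
#' @param x,y Paired numeric series of equal length.
#' @param exact_max Largest n for which the exact enumeration is used.
#' @return List: `statistic` (W, the smaller of the positive- and
#'   negative-rank sums), `w_plus`, `w_minus`, `p_value` (two-sided),
#'   `n_pairs` (non-zero differences), `method` ("exact" or "normal").
#' @export
#' @examples
#' wilcoxon_signed_rank(2:6, rep(1, 5))$p_value  # 0.0625
wilcoxon_signed_rank <- function(x, y, exact_max = 15L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  mu <- n * (n + 1) / 4

  if (n <= exact_max) {
    # enumerate the null distribution of the positive-rank sum over all
    # sign assignments of these (mid-)ranks
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    p <- mean(abs(sums - mu) >= abs(w_plus - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (abs(w_plus - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(0, z)))
    method <- "normal"
  }
  list(statistic = w, w_plus = w_plus, w_minus = w_minus,
       p_value = p, n_pairs = n, method = method)
}

#' Root mean square error
#'
#' @param a,b Numeric series of equal, non-zero length.
#' @return sqrt(mean((a - b)^2)).
#' @export
rmse <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) == 0L) stop("empty series")
  sqrt(mean((a - b)^2))
}

#' Compare paired stride-length series
#'
#' Convenience wrapper bundling the paired Wilcoxon signed-rank test and
#' the RMSE of insole-estimated against radar-estimated stride lengths.
#'
#' @param insole,radar Paired stride lengths (m).
#' @param alpha Significance level (reported, never used to gate
#'   computation).
#' @return List: `wilcoxon`, `rmse_m`, `n_pairs`, `significant`.
#' @export
compare_stride_lengths <- function(insole, radar, alpha = 0.05) {
  wt <- wilcoxon_signed_rank(insole, radar)
  list(wilcoxon = wt, rmse_m = rmse(insole, radar),
       n_pairs = length(insole), significant = wt$p_value < alpha)
}
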