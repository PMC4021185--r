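#' Wilcoxon signed-rank test on paired scores
#'
#' Differences are ranked by absolute value (zero differences dropped, tied
#' magnitudes receiving average ranks), each rank takes the sign of its
#' difference, and the signed ranks are summed into the statistic W. The
#' two-sided p-value uses the normal approximation of W's null sampling
#' distribution with a tie correction; for small samples an exact 2^n
#' sign-flip enumeration is available.
#'
#' @param a,b paired score vectors (e.g. per-protein MCCs of two methods).
#' @param exact use exact enumeration (default when 12 or fewer non-zero
#'   differences).
#' @return one-row tibble: w, n (non-zero differences), p.
#' @export
wilcoxon_signed_rank <- function(a, b, exact = NULL) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("degenerate pairing: all differences are zero")
  r <- rank(abs(d))
  w <- sum(sign(d) * r)
  exact <- exact %||% (n <= 12)
  p <- if (exact) {
    # enumerate all 2^n sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    w_null <- as.vector(signs %*% r)
    mean(abs(w_null) >= abs(w) - 1e-12)
  } else {
    ties <- table(r)
    var_w <- n * (n + 1) * (2 * n + 1) / 6 - sum(ties^3 - ties) / 12
    z <- w / sqrt(var_w)
    2 * pnorm(-abs(z))
  }
  tibble::tibble(w = w, n = n, p = min(1, p))
}

#' Point-biserial correlation of a feature with a binary label
#'
#' Pearson product-moment correlation between a numeric feature column and
#' a 0/1 interface label, with a two-tailed t-test p-value.
#'
#' @param feature numeric vector.
#' @param label logical or 0/1 vector.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_feature_correlation <- function(feature, label) {
  label <- as.numeric(label)
  n <- length(feature)
  if (n < 3) abort("need at least 3 observations")
  if (sd(feature) == 0 || sd(label) == 0) {
    abort("zero variance: correlation undefined")
  }
  r <- cor(feature, label)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}
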