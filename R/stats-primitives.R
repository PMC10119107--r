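# Shared statistical primitives: Mann-Whitney U (exact by enumeration for
# small samples, normal approximation with tie and continuity corrections
# otherwise), Benjamini-Hochberg adjustment, pooled-variance t, and Spearman
# correlation with a t-approximation p value.

#' Two-tailed Mann-Whitney U test
#'
#' For combined sample sizes up to `exact_max` the null distribution of U is
#' enumerated over all assignments of the pooled (average) ranks, handling
#' ties exactly; the two-sided p is twice the smaller tail probability,
#' clipped at 1. Larger samples use the normal approximation with tie
#' correction and a 0.5 continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Enumerate exactly when `length(x) + length(y)` is at most
#'   this (default 12).
#' @return A list of class `ribodyn_mwu`: `statistic` (U of `x`), `p.value`,
#'   `method`, `n_x`, `n_y`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p.value # 0.1, by enumeration
mann_whitney <- function(x, y, exact_max = 12L) {
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (n <= exact_max) {
    idx <- combn(n, nx)
    rsums <- colSums(matrix(r[idx], nrow = nx))
    u_all <- rsums - nx * (nx + 1) / 2
    p_lo <- mean(u_all <= u + 1e-9)
    p_hi <- mean(u_all >= u - 1e-9)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  structure(list(statistic = u, p.value = p, method = method,
                 n_x = nx, n_y = ny),
            class = "ribodyn_mwu")
}

#' @export
print.ribodyn_mwu <- function(x, ...) {
  cat("Two-tailed Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat("U =", x$statistic, " n =", x$n_x, "vs", x$n_y,
      " p =", format.pval(x$p.value), "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values (a thin wrapper over
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return q values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Vectorised pooled-variance two-sided t-test over rows of two matrices
# (replicates in columns). Degenerate rows (zero pooled variance) get p = 1
# when the means agree and p = 0, flagged, when they differ.
row_pooled_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (mb - ma) / se
  p <- 2 * pt(-abs(t), df)
  degenerate <- se == 0
  p[degenerate & abs(mb - ma) < 1e-12] <- 1
  t[degenerate & abs(mb - ma) < 1e-12] <- 0
  p[degenerate & abs(mb - ma) >= 1e-12] <- 0
  tibble(mean_a = ma, mean_b = mb, t = t, df = df, p = p,
         degenerate = degenerate)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Average ranks for ties; the two-sided p value uses the t approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, with a
#' Bonferroni-adjusted p over a family of related comparisons.
#'
#' @param x,y Numeric vectors of equal length (at least 4 pairs).
#' @param family_size Bonferroni family size (e.g. 3 when testing the A-, P-
#'   and E-sites together).
#' @return A list of class `ribodyn_cor`: `r`, `n`, `p.value`,
#'   `p.adjusted`, `family_size`.
#' @export
spearman_cor <- function(x, y, family_size = 1L) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("Need at least 4 complete pairs")
  r <- cor(rank(x), rank(y))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  structure(list(r = r, n = n, p.value = p,
                 p.adjusted = min(1, p * family_size),
                 family_size = family_size),
            class = "ribodyn_cor")
}

#' @export
print.ribodyn_cor <- function(x, ...) {
  cat("Spearman correlation: r =", round(x$r, 4), " n =", x$n,
      " p =", format.pval(x$p.value),
      " adjusted p =", format.pval(x$p.adjusted), "\n")
  invisible(x)
}
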