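#' Two-tailed unpaired Mann-Whitney U test
#'
#' U is computed with midrank ties. The p-value is exact (network
#' algorithm) when the combined sample size is at most 20 and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @return One-row tibble: `n_a`, `n_b`, `u_a`, `u_b`, `statistic` (= `u_a`),
#'   `p_two_sided`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    param_error("both groups must be non-empty")
  n_a <- length(values_a); n_b <- length(values_b)
  if (length(unique(c(values_a, values_b))) == 1) {
    # fully tied pooled sample: no evidence of separation
    return(tibble(n_a = n_a, n_b = n_b, u_a = n_a * n_b / 2,
                  u_b = n_a * n_b / 2, statistic = n_a * n_b / 2,
                  p_two_sided = 1, method = "normal"))
  }
  tied <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (n_a + n_b) <= 20 && !tied
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  u_a <- unname(ht$statistic)
  tibble(n_a = n_a, n_b = n_b, u_a = u_a, u_b = n_a * n_b - u_a,
         statistic = u_a, p_two_sided = min(1, ht$p.value),
         method = if (exact) "exact" else "normal")
}

#' Spearman rank correlation with asymptotic t p-value
#'
#' rho is the Pearson correlation of midranks; the two-sided p-value comes
#' from `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 4, non-constant).
#' @return One-row tibble: `n`, `rho`, `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) param_error("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) param_error("spearman correlation requires n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    param_error("spearman correlation undefined for constant input")
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE,
                    continuity = FALSE))
  tibble(n = n, rho = unname(ht$estimate), p = ht$p.value)
}
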