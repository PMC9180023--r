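# Mann-Kendall trend test: S statistic, tie-corrected variance,
# continuity-corrected normal score, significance stars, exact small-n null.

#' Mann-Kendall trend test
#'
#' Rank-based test for monotone trend in an annual series. The statistic
#' `S = sum_{i<j} sgn(x_j - x_i)` counts concordant minus discordant pairs
#' (positive for a rising series); its null variance is tie-corrected,
#' `Var(S) = [n(n-1)(2n+5) - sum_t f_t (f_t - 1)(2 f_t + 5)] / 18`
#' with `f_t` the size of each tie group; and the normal score applies a
#' continuity correction: `Z = (S - 1)/sqrt(Var)` if `S > 0`, `0` if
#' `S = 0`, `(S + 1)/sqrt(Var)` if `S < 0`. Because S depends only on
#' ranks, any strictly increasing transform of the series leaves the whole
#' test unchanged.
#'
#' Significance stars follow the alpha ladder 0.01 / 0.05 / 0.1:
#' `"***"` for p < 0.01, `"**"` for p < 0.05, `"*"` for p < 0.1, else `""`.
#'
#' @param x Numeric series in time order, length >= 2.
#' @param alphas Significance ladder, ascending.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return `mk_test()`: a one-row tibble with `n`, `S`, `var_s`, `Z`, `p`,
#'   `direction` (`"increasing"`, `"decreasing"`, `"none"`), `stars`.
#'   `mk_s()`: integer S. `mk_variance()`: the tie-corrected variance.
#' @examples
#' mk_test(c(1, 2, 3, 4))      # Z ~ 1.698, one star
#' mk_test(1:18)$Z             # 152 / sqrt(697) ~ 5.757
#' @export
mk_test <- function(x, alphas = c(0.01, 0.05, 0.1),
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  S <- mk_s(x)
  v <- mk_variance(x)
  if (S != 0 && v <= 0) {
    stop_equipanel("degenerate_variance",
      "zero Mann-Kendall variance with non-zero S: corrupt series")
  }
  Z <- if (S > 0) (S - 1) / sqrt(v) else if (S < 0) (S + 1) / sqrt(v) else 0
  p <- switch(alternative,
    two.sided = 2 * pnorm(-abs(Z)),
    greater = pnorm(Z, lower.tail = FALSE),
    less = pnorm(Z))
  tibble::tibble(
    n = length(x), S = S, var_s = v, Z = Z, p = p,
    direction = if (S > 0) "increasing" else if (S < 0) "decreasing" else "none",
    stars = mk_stars(p, alphas))
}

#' @rdname mk_test
#' @export
mk_s <- function(x) {
  n <- length(x)
  if (n < 2) stop_equipanel("series", "Mann-Kendall needs at least 2 values")
  if (anyNA(x)) stop_equipanel("series", "series contains missing values")
  d <- outer(x, x, "-")  # d[j, i] = x_j - x_i; lower triangle has j > i
  as.integer(sum(sign(d[lower.tri(d)])))
}

#' @rdname mk_test
#' @export
mk_variance <- function(x) {
  n <- length(x)
  if (n < 2) stop_equipanel("series", "Mann-Kendall needs at least 2 values")
  f <- as.integer(table(x))
  (n * (n - 1) * (2 * n + 5) - sum(f * (f - 1) * (2 * f + 5))) / 18
}

#' @rdname mk_test
#' @param p P-value(s).
#' @export
mk_stars <- function(p, alphas = c(0.01, 0.05, 0.1)) {
  alphas <- sort(alphas)
  vapply(p, function(pp) strrep("*", sum(pp < alphas)), "")
}

#' Exact null distribution of the Mann-Kendall S statistic
#'
#' For a series of `n` distinct values under the null, every ordering is
#' equally likely and S is determined by the inversion count of the
#' permutation: `S = n(n-1)/2 - 2k` for `k` inversions. The number of
#' permutations with `k` inversions is the coefficient of `q^k` in
#' `prod_{i=1}^{n} (1 + q + ... + q^{i-1})`, computed here by polynomial
#' convolution -- exact, and independent of [mk_s()], so it serves as the
#' small-n oracle for the normal approximation. The distribution is
#' symmetric about 0 with variance `n(n-1)(2n+5)/18`.
#'
#' @param n Series length, between 2 and 10.
#' @return A tibble with columns `s` (possible values, ascending) and
#'   `prob` (probabilities summing to 1).
#' @examples
#' exact_null(3)
#' @export
exact_null <- function(n) {
  if (length(n) != 1 || n != round(n) || n < 2 || n > 10) {
    stop_equipanel("domain", "exact null supported for integer 2 <= n <= 10")
  }
  counts <- 1  # counts[k + 1] = number of permutations with k inversions
  for (i in 2:n) {
    out <- numeric(length(counts) + i - 1)
    for (j in 0:(i - 1)) {
      idx <- seq_along(counts) + j
      out[idx] <- out[idx] + counts
    }
    counts <- out
  }
  k <- seq_along(counts) - 1
  M <- n * (n - 1) / 2
  tibble::tibble(s = rev(M - 2 * k), prob = rev(counts) / factorial(n))
}

#' Trend table over a bundle of index series
#'
#' Applies [mk_test()] to each named series and formats the cell the way
#' equity studies tabulate it: `Z` to three decimals, significance stars,
#' and the trend sign -- `"(+)"` rising, `"(-)"` falling, `"(0)"` flat.
#'
#' @param series A named list of numeric vectors (each a year-ordered index
#'   series), or a data frame with columns `series`, `year`, `value`.
#' @param alphas Significance ladder passed to [mk_test()].
#' @return A tibble with one row per series: `series`, `n`, `S`, `var_s`,
#'   `Z`, `p`, `stars`, `sign`, `cell`.
#' @examples
#' trend_table(list(rising = 1:10, flat = rep(1, 10)))
#' @export
trend_table <- function(series, alphas = c(0.01, 0.05, 0.1)) {
  if (is.data.frame(series)) {
    stopifnot(all(c("series", "year", "value") %in% names(series)))
    series <- series[order(series$year), ]
    series <- split(series$value, series$series)
  }
  stopifnot(is.list(series), !is.null(names(series)))
  purrr::map_dfr(names(series), function(id) {
    r <- mk_test(series[[id]], alphas = alphas)
    sign_lab <- switch(r$direction, increasing = "(+)", decreasing = "(-)", "(0)")
    tibble::tibble(
      series = id, n = r$n, S = r$S, var_s = r$var_s, Z = r$Z, p = r$p,
      stars = r$stars, sign = sign_lab,
      cell = paste(c(sprintf("%.3f", r$Z),
                     if (nzchar(r$stars)) r$stars, sign_lab), collapse = " "))
  })
}
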