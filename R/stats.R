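# Exact and asymptotic statistics shared by all analysis stages.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` = group-A successes,
#'   `b` = group-A failures, `c` = group-B successes, `d` = group-B
#'   failures.
#' @return A named integer vector of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (anyNA(x) || any(x < 0) || any(x != floor(x))) stopf("two_by_two: cells must be non-negative integers")
  if (sum(x) < 1) stopf("two_by_two: table must contain at least one observation")
  structure(as.integer(x), names = names(x), class = "two_by_two")
}

as_two_by_two <- function(table) {
  if (inherits(table, "two_by_two")) return(table)
  if (is.matrix(table) && all(dim(table) == c(2, 2))) {
    return(two_by_two(table[1, 1], table[1, 2], table[2, 1], table[2, 2]))
  }
  if (is.numeric(table) && length(table) == 4) {
    return(two_by_two(table[1], table[2], table[3], table[4]))
  }
  stopf("expected a two_by_two, a 2x2 matrix, or a length-4 numeric vector")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value uses
#' the probability-ordering convention: the sum of probabilities of all
#' tables whose probability does not exceed that of the observed table, with
#' a relative tolerance of 1e-12 guarding floating-point ties. A table with
#' any zero margin is degenerate and returns p = 1.
#'
#' @param table A [two_by_two()], 2x2 matrix (rows = groups), or length-4
#'   vector `(a, b, c, d)`.
#' @param alternative `"two_sided"` (default), `"greater"` (group A enriched
#'   for successes) or `"less"`.
#' @return A list with `p_value` and `odds_ratio` (the sample odds ratio
#'   `a*d / (b*c)`; `Inf` when `b*c == 0` and `a*d > 0`, `NaN` when both
#'   products are zero).
#' @examples
#' fisher_exact(two_by_two(4, 0, 0, 6))$p_value  # 1/choose(10, 4)
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  t <- as_two_by_two(table)
  a <- t[["a"]]; b <- t[["b"]]; c <- t[["c"]]; d <- t[["d"]]
  or <- if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c)
  m <- a + b; n2 <- c + d; k <- a + c; n <- m + n2
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    return(list(p_value = 1, odds_ratio = or))
  }
  xs <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(xs, k, n - k, m)
  p_obs <- stats::dhyper(a, k, n - k, m)
  p <- switch(alternative,
              two_sided = sum(probs[probs <= p_obs * (1 + 1e-12)]),
              greater   = sum(probs[xs >= a]),
              less      = sum(probs[xs <= a]))
  list(p_value = min(1, max(0, p)), odds_ratio = unname(or))
}

check_pvalues <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stopf("p-values must be numeric in [0, 1]")
  }
  invisible(p)
}

#' Multiple-testing corrections
#'
#' Benjamini-Hochberg step-up FDR adjustment and Bonferroni adjustment, both
#' capped at 1 and returned in the input order.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @rdname multiple_testing
#' @export
benjamini_hochberg <- function(p_values) {
  check_pvalues(p_values)
  stats::p.adjust(p_values, method = "BH")
}

#' @rdname multiple_testing
#' @export
bonferroni <- function(p_values) {
  check_pvalues(p_values)
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Rank-sum comparison of two samples. The U statistic is computed from
#' midranks for the first sample `x`. The p-value is exact (full null
#' distribution of U) when there are no ties and the number of rank
#' arrangements `choose(n_x + n_y, n_x)` is at most 200,000; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' The default effect size is the rank-biserial correlation
#' `r = 2 * U / (n_x * n_y) - 1`, positive when `x` tends to exceed `y` and
#' bounded in `[-1, 1]` (equivalently `1 - 2*U'/(n_x*n_y)` for the second
#' sample's U). `r_method = "z_normal"` instead returns `z / sqrt(N)` from
#' the tie-corrected normal approximation without continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two_sided"`, `"greater"` (`x` shifted upward) or
#'   `"less"`.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) p-value;
#'   `NULL` (default) applies the rule above.
#' @param continuity Apply the continuity correction in the normal
#'   approximation.
#' @param r_method `"rank_biserial"` (default) or `"z_normal"`.
#' @return A list with `u_statistic`, `p_value`, `effect_size_r`, `method`
#'   (`"exact"` or `"normal_approx"`), `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two_sided", "greater", "less"),
                           exact = NULL, continuity = TRUE,
                           r_method = c("rank_biserial", "z_normal")) {
  alternative <- match.arg(alternative)
  r_method <- match.arg(r_method)
  if (length(x) == 0 || length(y) == 0) stopf("mann_whitney_u: both samples must be non-empty")
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    stopf("mann_whitney_u: samples must be numeric without NA")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  rk <- rank(pooled)
  u <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) exact <- !ties && choose(n, nx) <= 2e5
  alt <- switch(alternative, two_sided = "two.sided", greater = "greater", less = "less")
  tie_counts <- table(pooled)
  sigma2 <- (nx * ny / 12) * ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) {
    # all observations identical: no information
    p <- 1
    method <- "normal_approx"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
                                              exact = exact, correct = continuity))
    p <- wt$p.value
    method <- if (exact) "exact" else "normal_approx"
  }
  r <- if (r_method == "rank_biserial") {
    2 * u / (nx * ny) - 1
  } else {
    if (sigma2 <= 0) 0 else ((u - nx * ny / 2) / sqrt(sigma2)) / sqrt(n)
  }
  list(u_statistic = unname(u), p_value = unname(p), effect_size_r = unname(r),
       method = method, n_x = nx, n_y = ny)
}

#' Pearson chi-square test for a 2x2 table with phi coefficient
#'
#' Chi-square statistic `n * (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without
#' continuity correction by default (switchable), with p-value from the
#' chi-square distribution with 1 degree of freedom and signed effect size
#' `phi = sign(ad - bc) * sqrt(chi2 / n)`. A table with any zero margin is
#' degenerate: `chi2 = 0`, `phi = 0`, `p = 1`.
#'
#' @inheritParams fisher_exact
#' @param correct Apply the Yates continuity correction (affects `chi2`,
#'   `p_value` and, through the spec formula, `phi`).
#' @return A list with `chi2`, `p_value`, `phi`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  t <- as_two_by_two(table)
  a <- as.numeric(t[["a"]]); b <- as.numeric(t[["b"]])
  c <- as.numeric(t[["c"]]); d <- as.numeric(t[["d"]])
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(chi2 = 0, p_value = 1, phi = 0))
  }
  num <- a * d - b * c
  dev <- if (correct) max(0, abs(num) - n / 2) else abs(num)
  chi2 <- n * dev^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       phi = sign(num) * sqrt(chi2 / n))
}
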