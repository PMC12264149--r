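# Grouped statistical comparisons: two-sided Wilcoxon rank-sum and one-sided
# Fisher's exact test, with the five-percentile boxplot summary used for all
# group outputs.
#
# The kernels are written against the exact null distributions (Wilcoxon
# rank-sum counts via pwilcox, hypergeometric tail via phyper) rather than
# delegating to the omnibus test functions, so the test-suite can check them
# against independent brute-force enumeration.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact when both groups have at most 25 observations and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return List with `statistic` (Mann-Whitney U of `x`), `p_value`, and
#'   `exact` flag.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  .assert(length(x) >= 2 && length(y) >= 2, "both groups need >= 2 values")
  nx <- length(x); ny <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(rk)
  has_ties <- any(ties > 1)
  exact <- !has_ties && nx <= 25 && ny <= 25
  if (exact) {
    if (u > nx * ny / 2) {
      p <- 2 * stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(u, nx, ny)
    }
    p <- min(1, p)
  } else {
    n <- nx + ny
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (nx * ny / 12) * ((n + 1) - tie_term)
    mu <- nx * ny / 2
    z <- u - mu
    z <- z - sign(z) * 0.5            # continuity correction
    z <- if (sigma2 > 0) z / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = u, p_value = p, exact = exact)
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Tests whether the success proportion in the first row exceeds the second
#' (alternative "greater"), by the hypergeometric tail probability
#' `P(X >= a)` for the observed top-left count `a`.
#'
#' @param tab 2x2 matrix of non-negative counts; rows are groups, column 1
#'   is the "success" outcome.
#' @return List with `statistic` (observed top-left count) and `p_value`.
#' @export
fisher_one_sided <- function(tab) {
  tab <- as.matrix(tab)
  .assert(all(dim(tab) == c(2, 2)) && all(tab >= 0) &&
            all(tab == round(tab)), "need a 2x2 table of counts")
  a <- tab[1, 1]
  p <- stats::phyper(a - 1, m = sum(tab[1, ]), n = sum(tab[2, ]),
                     k = sum(tab[, 1]), lower.tail = FALSE)
  list(statistic = a, p_value = min(1, p))
}

#' Compare two groups
#'
#' Front door for all grouped comparisons: two-sided Wilcoxon rank-sum on
#' two value vectors, or one-sided Fisher's exact test on a 2x2 count
#' table.  Every result carries the five-percentile summary (5th, 25th,
#' 50th, 75th, 95th; linear interpolation) plus the mean for each group.
#'
#' @param a,b Numeric value vectors (Wilcoxon), or `NULL` when `table` is
#'   given.
#' @param test `"wilcoxon_two_sided"` or `"fisher_one_sided"`.
#' @param table 2x2 count matrix for the Fisher test.
#' @param labels Group labels of length 2.
#' @return An object of class `GroupComparisonResult`.
#' @export
compare_groups <- function(a = NULL, b = NULL,
                           test = c("wilcoxon_two_sided", "fisher_one_sided"),
                           table = NULL, labels = c("group1", "group2")) {
  test <- match.arg(test)
  if (test == "wilcoxon_two_sided") {
    .assert(length(a) >= 1 && length(b) >= 1, "empty group")
    res <- wilcoxon_rank_sum(a, b)
    summ <- rbind(.five_num(a), .five_num(b))
    summary_df <- data.frame(group = labels, n = c(length(a), length(b)),
                             summ, row.names = NULL)
  } else {
    .assert(!is.null(table), "fisher_one_sided requires `table`")
    res <- fisher_one_sided(table)
    tot <- rowSums(table)
    summary_df <- data.frame(group = labels, n = tot,
                             successes = table[, 1],
                             proportion = ifelse(tot > 0, table[, 1] / tot,
                                                 NA_real_),
                             row.names = NULL)
  }
  structure(list(test = test, statistic = res$statistic,
                 p_value = res$p_value, summary = summary_df),
            class = "GroupComparisonResult")
}

#' @export
print.GroupComparisonResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Entropy-based expression specificity
#'
#' KL divergence (base 2) of the normalized cross-sample expression profile
#' from the uniform distribution: `sum(p_i * log2(N * p_i))` with
#' `0 * log(0) = 0`.  Zero for a perfectly constant gene, `log2(N)` for
#' expression confined to one sample.  A gene is called constantly
#' expressed when the score is below 0.5 and its abundance is at least 10
#' in every sample.
#'
#' @param x Non-negative abundance values across `N >= 2` samples; not all
#'   zero.
#' @return The specificity score in `[0, log2(N)]`.
#' @export
entropy_specificity <- function(x) {
  .assert(length(x) >= 2 && all(x >= 0), "need >= 2 non-negative values")
  s <- sum(x)
  .assert(s > 0, "all-zero expression vector")
  p <- x / s
  nz <- p > 0
  sum(p[nz] * log2(length(x) * p[nz]))
}
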