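new_test_result <- function(statistic, p_value, method, n1, n2) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n1 = n1, n2 = n2),
            class = "tandem_test")
}

#' @export
print.tandem_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is the Mann-Whitney count `W = sum over pairs 1[x_i > y_j]`
#' (+ 1/2 per tie). The p-value is exact (full enumeration over assignments)
#' when `n1 + n2 <= 20` and there are no ties, and a normal approximation
#' with continuity correction otherwise. Exact mode refuses tied data unless
#' `tie_permutation = TRUE`, in which case the exact null distribution of the
#' midrank statistic is enumerated. Two-sided p-values double the smaller
#' tail, capped at 1.
#'
#' @param x,y Numeric samples.
#' @param exact `TRUE`, `FALSE`, or `NULL` (auto: exact when `n1 + n2 <= 20`).
#' @param tie_permutation Allow exact enumeration in the presence of ties.
#' @return A `tandem_test` result.
#' @export
rank_sum <- function(x, y, exact = NULL, tie_permutation = FALSE) {
  if (length(x) == 0 || length(y) == 0) abort("samples must be nonempty.")
  n1 <- length(x); n2 <- length(y)
  if (is.null(exact)) exact <- (n1 + n2) <= 20
  # Mann-Whitney count via midranks: equals sum over pairs of 1[x_i > y_j]
  # plus 1/2 per tie, but in O(n log n) rather than O(n1 n2)
  W <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0

  if (exact && !has_ties) {
    res <- suppressWarnings(wilcox.test(x, y, exact = TRUE, correct = TRUE))
    p <- res$p.value
    method <- "Exact Wilcoxon rank sum test"
  } else if (exact && has_ties) {
    if (!tie_permutation) {
      abort(paste0("ties present: the exact distribution is not available; ",
                   "set tie_permutation = TRUE for exact enumeration with ",
                   "midranks, or exact = FALSE for the normal approximation."))
    }
    n <- n1 + n2
    if (choose(n, n1) > 2e5) {
      abort("tie_permutation enumeration infeasible: too many assignments.")
    }
    pooled <- c(x, y)
    idx <- combn(n, n1)
    # midrank Mann-Whitney statistic for every assignment of n1 labels
    ws <- apply(idx, 2, function(ii) {
      xx <- pooled[ii]; yy <- pooled[-ii]
      sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    })
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= W + eps), mean(ws >= W - eps)))
    method <- "Exact Wilcoxon rank sum test (midrank enumeration)"
  } else {
    res <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- res$p.value
    method <- "Wilcoxon rank sum test (normal approximation)"
  }
  new_test_result(W, p, method, n1, n2)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic p-value, as used to
#' compare heading-difference distributions between real and randomised
#' pairings.
#'
#' @param x,y Numeric samples.
#' @return A `tandem_test` result.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("samples must be nonempty.")
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  new_test_result(res$statistic, res$p.value,
                  "Two-sample Kolmogorov-Smirnov test (asymptotic)",
                  length(x), length(y))
}

#' Paired t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = a - b`, with
#' `n - 1` degrees of freedom, two-sided. Zero-variance differences (for
#' example `b = a + c`) are a hard error rather than an infinite statistic.
#'
#' @param a,b Paired numeric samples of equal length (>= 2).
#' @return A `tandem_test` result.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("paired samples must have equal length.")
  if (length(a) < 2) abort("need at least 2 pairs.")
  d <- a - b
  if (sd(d) == 0) abort("zero-variance differences: paired t is undefined.")
  res <- t.test(a, b, paired = TRUE)
  new_test_result(res$statistic, res$p.value, "Paired t test",
                  length(a), length(b))
}
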