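# Shared statistical primitives: rank tests, multiplicity corrections,
# correlation, trend and hypergeometric tails. Thin, validated wrappers over
# the standard base-R engines where those exist; the Jonckheere-Terpstra
# trend test is implemented here because no installed package provides it.

test_result <- function(statistic, p_value, method, n) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n),
            class = "seedshift_test")
}

#' @export
print.seedshift_test <- function(x, ...) {
  cat("<", x$method, ">  statistic = ", format(x$statistic),
      ",  p = ", format.pval(x$p_value), ",  n = ",
      paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the smaller group has at most `exact_threshold`
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_threshold Largest min-group size for the exact path
#'   (default 10).
#' @return A `seedshift_test` with the rank-sum `W` statistic.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value # exact 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact_threshold = 10L) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && min(length(a), length(b)) <= exact_threshold
  wt <- suppressWarnings(wilcox.test(a, b, exact = use_exact, correct = TRUE))
  test_result(unname(wt$statistic), wt$p.value,
              if (use_exact) "wilcoxon rank-sum (exact)"
              else "wilcoxon rank-sum (normal approximation)",
              c(length(a), length(b)))
}

check_pvals <- function(p) {
  if (length(p) && (any(is.na(p)) || any(p < 0) || any(p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Multiple-testing adjustments
#'
#' `bh_adjust()` is the Benjamini-Hochberg step-up false discovery rate;
#' `bonferroni_adjust()` is `min(1, p * m)`. Both validate that inputs lie in
#' `[0, 1]` and preserve the order of the input vector.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.05)) # 0.04 0.04 0.05 0.05
#' @export
bh_adjust <- function(p) {
  check_pvals(p)
  p.adjust(p, method = "BH")
}

#' @rdname bh_adjust
#' @export
bonferroni_adjust <- function(p) {
  check_pvals(p)
  p.adjust(p, method = "bonferroni")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rho is the Pearson correlation of midranks; the two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom. If either vector is constant, rho is undefined: the result
#' carries `statistic = NA` and `undefined = TRUE` rather than an error, so
#' screens over many pairs can record and move on.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `seedshift_test` with `statistic = rho` and an extra logical
#'   field `undefined`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length", call. = FALSE)
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  res <- test_result(NA_real_, NA_real_, "spearman rank correlation", n)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    res$undefined <- TRUE
    return(res)
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  res$statistic <- rho
  res$p_value <- p
  res$undefined <- FALSE
  res
}

check_hyper_args <- function(k, N, K, n) {
  if (any(c(k, N, K, n) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric arguments: need 0 <= k <= min(K, n) ",
         "and K, n <= N", call. = FALSE)
}

#' Hypergeometric upper tail P(X >= k)
#'
#' For `X ~ Hypergeometric(N, K, n)` (population `N`, `K` successes, draw
#' `n`), the probability of observing `k` or more successes — the enrichment
#' p-value of over-representation analysis. Evaluated through the stable
#' log-space tail of [stats::phyper()].
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)`.
#' @param N Population (universe) size.
#' @param K Number of successes in the population.
#' @param n Draw (query) size.
#' @return `P(X >= k)` in `[0, 1]`.
#' @examples
#' hypergeometric_upper_tail(3, 20, 5, 5) # 1126/15504
#' @export
hypergeometric_upper_tail <- function(k, N, K, n) {
  check_hyper_args(k, N, K, n)
  if (k == 0L) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' The JT statistic sums, over every ordered group pair `i < j`, the number
#' of cross-pairs `(u in group i, v in group j)` with `v > u`, ties counting
#' one half. Large values indicate an increasing trend in the group order.
#' The p-value is two-sided, by seeded permutation of group membership
#' (default; valid under ties) or by the large-sample normal approximation
#' (no tie correction).
#'
#' @param groups List of >= 3 non-empty numeric vectors in their hypothesised
#'   order.
#' @param method `"permutation"` (default) or `"normal"`.
#' @param n_perm Number of permutations for the permutation p-value.
#' @param seed Optional integer seed for the permutation draw; the caller's
#'   RNG state is untouched.
#' @return A `seedshift_test` with the JT statistic.
#' @examples
#' jonckheere_terpstra_trend(list(c(1, 2), c(3, 4), c(5, 6)),
#'                           method = "normal")
#' @export
jonckheere_terpstra_trend <- function(groups,
                                      method = c("permutation", "normal"),
                                      n_perm = 2000L, seed = NULL) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 3L)
    stop("need at least 3 ordered groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("all groups must be non-empty", call. = FALSE)
  jt_stat <- function(values, sizes) {
    idx <- rep(seq_along(sizes), sizes)
    s <- 0
    for (i in seq_len(length(sizes) - 1L)) {
      u <- values[idx == i]
      v <- values[idx > i]
      s <- s + sum(outer(u, v, "<")) + 0.5 * sum(outer(u, v, "=="))
    }
    s
  }
  sizes <- vapply(groups, length, integer(1))
  values <- unlist(groups, use.names = FALSE)
  obs <- jt_stat(values, sizes)
  n <- sum(sizes)
  mu <- (n^2 - sum(sizes^2)) / 4
  if (method == "normal") {
    v <- (n^2 * (2 * n + 3) - sum(sizes^2 * (2 * sizes + 3))) / 72
    z <- (obs - mu) / sqrt(v)
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  } else {
    draw <- function() {
      perm <- sample(values)
      abs(jt_stat(perm, sizes) - mu)
    }
    perm_dev <- if (is.null(seed)) replicate(n_perm, draw())
      else withr::with_seed(seed, replicate(n_perm, draw()))
    p <- (1 + sum(perm_dev >= abs(obs - mu))) / (n_perm + 1)
  }
  test_result(obs, min(p, 1),
              paste0("Jonckheere-Terpstra trend (", method, ")"), sizes)
}
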