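# Normalisation, expression filters and the lightweight differential
# expression stage: median-of-ratios size factors, group log2 fold change
# with a 0.5 pseudocount, per-feature Wilcoxon rank-sum p-values on
# normalised counts, BH adjustment, and the |log2FC| > 1.5 & adj p < 0.05
# significance rule.

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors: for each sample, the median over
#' features (restricted to features with strictly positive counts in every
#' sample) of the ratio count / geometric-mean-across-samples. Scale
#' equivariant: doubling a sample's counts doubles its factor.
#'
#' @param cm A [count_matrix()] or a plain counts matrix.
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  all_pos <- rowSums(counts == 0) == 0L
  if (!any(all_pos))
    stop("no feature has positive counts in every sample; ",
         "size factors are undefined", call. = FALSE)
  logc <- log(counts[all_pos, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2L, function(col) exp(median(col - loggeo)))
}

#' Reads-per-million normalisation
#'
#' Each count scaled by 1e6 over its sample's total; every RPM column sums
#' to 1e6.
#'
#' @param cm A [count_matrix()] or counts matrix.
#' @return Numeric matrix of RPM values.
#' @export
rpm_normalize <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Detection filter
#'
#' Drops features detected (raw count > 0) in fewer than
#' `ceiling(min_fraction * n_samples)` samples, the "eliminated if detected
#' in under half of all samples" rule at its default.
#'
#' @param cm A [count_matrix()].
#' @param min_fraction Minimum detected fraction (default 0.5).
#' @return The filtered [count_matrix()].
#' @export
detection_filter <- function(cm, min_fraction = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  need <- ceiling(min_fraction * ncol(cm$counts))
  keep <- rowSums(cm$counts > 0) >= need
  count_matrix(cm$counts[keep, , drop = FALSE], cm$groups, cm$pairs)
}

#' Abundance filters on RPM and baseMean
#'
#' Keeps features whose maximum RPM over samples is at least `min_rpm` and
#' whose baseMean (mean of size-factor-normalised counts over all samples)
#' is at least `min_baseMean` — both "not less than" comparisons, so the
#' boundary value is kept. Presets in common use: `min_rpm = 50` with
#' `min_baseMean = 500` for the deregulation analysis, and `min_rpm = 500`
#' (any one sample) for repertoire summaries.
#'
#' @param results Data frame with `feature_id` and `baseMean` columns (as
#'   from [differential_expression()]).
#' @param rpm Matrix from [rpm_normalize()], rows matching `feature_id`.
#' @param min_rpm,min_baseMean Thresholds.
#' @return The filtered results data frame.
#' @export
expression_filters <- function(results, rpm, min_rpm = 50, min_baseMean = 500) {
  max_rpm <- apply(rpm[results$feature_id, , drop = FALSE], 1L, max)
  keep <- max_rpm >= min_rpm & results$baseMean >= min_baseMean
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential expression between tumor and normal groups
#'
#' A deliberately lightweight stage: counts are normalised by
#' median-of-ratios [size_factors()]; the fold change is
#' `log2((mean_tumor + 0.5) / (mean_normal + 0.5))` of group means of
#' normalised counts (pseudocount 0.5 guards zero means); the p-value is a
#' two-sided Wilcoxon rank-sum test on normalised counts; adjustment is
#' Benjamini-Hochberg. A feature is significant iff `|log2FC| >
#' lfc_threshold` and `adjusted_p < alpha` (defaults 1.5 and 0.05).
#'
#' @param cm A [count_matrix()] whose `groups` take exactly two values.
#' @param group_tumor,group_normal Group labels (defaults `"tumor"`,
#'   `"normal"`).
#' @param lfc_threshold,alpha Significance thresholds.
#' @return Data frame with `feature_id`, `baseMean`, `log2FC`, `p_value`,
#'   `adjusted_p`, `direction` (`up`/`down`/`ns`), `significant`.
#' @export
differential_expression <- function(cm, group_tumor = "tumor",
                                    group_normal = "normal",
                                    lfc_threshold = 1.5, alpha = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  is_t <- cm$groups == group_tumor
  is_n <- cm$groups == group_normal
  if (!any(is_t) || !any(is_n))
    stop("both groups must be non-empty (labels '", group_tumor, "', '",
         group_normal, "')", call. = FALSE)
  sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  mean_t <- rowMeans(norm[, is_t, drop = FALSE])
  mean_n <- rowMeans(norm[, is_n, drop = FALSE])
  lfc <- log2((mean_t + 0.5) / (mean_n + 0.5))
  p <- vapply(seq_len(nrow(norm)), function(i)
    wilcoxon_rank_sum(norm[i, is_t], norm[i, is_n])$p_value, numeric(1))
  adj <- bh_adjust(p)
  significant <- abs(lfc) > lfc_threshold & adj < alpha
  direction <- ifelse(!significant, "ns", ifelse(lfc > 0, "up", "down"))
  data.frame(feature_id = rownames(cm$counts), baseMean = base_mean,
             log2FC = lfc, p_value = p, adjusted_p = adj,
             direction = direction, significant = significant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname differential_expression
#' @param results A results data frame.
#' @param path Output TSV path.
#' @export
write_de_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
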