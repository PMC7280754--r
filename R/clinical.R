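# Median-split survival analysis (log-rank via the survival package) and
# drug-response group comparison per isomiR.

#' Split samples at the median of an expression vector
#'
#' Samples strictly above the median go to `"high"`, samples at or below it
#' to `"low"` (so with ties at the median the low group absorbs them).
#' Fewer than two distinct values make the split degenerate and raise an
#' error.
#'
#' @param expression Named numeric vector (sample -> expression).
#' @return Named character vector of `"high"`/`"low"` labels.
#' @examples
#' median_split(setNames(c(1, 2, 2, 3), paste0("s", 1:4)))
#' # s4 is "high"; s1-s3 are "low"
#' @export
median_split <- function(expression) {
  if (length(unique(expression)) < 2L)
    stop("cannot median-split: fewer than 2 distinct expression values",
         call. = FALSE)
  m <- median(expression)
  setNames(ifelse(expression > m, "high", "low"), names(expression))
}

#' Two-group log-rank test
#'
#' The standard log-rank chi-square over distinct event times,
#' `(sum(O1 - E1))^2 / sum(V)`, computed by [survival::survdiff()], with the
#' p-value from a chi-square on 1 degree of freedom. If either group has no
#' observed events the result is flagged `unreliable` but still computed.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param group Two-level group labels.
#' @param isomir_id Optional id recorded on the result.
#' @return A list of class `survival_result`: `isomir_id`, `n_high`/`n_low`
#'   style per-group counts, `chi_square`, `p_value`, `unreliable`.
#' @export
logrank_survival <- function(time, event, group, isomir_id = NA_character_) {
  group <- as.character(group)
  levels <- sort(unique(group))
  if (length(levels) != 2L)
    stop("log-rank test requires exactly 2 groups, got ", length(levels),
         call. = FALSE)
  event <- as.integer(event)
  events_per_group <- tapply(event, group, sum)
  unreliable <- any(events_per_group == 0)
  if (sum(event) == 0L) {
    # no events at all: no information, chi-square 0 by convention
    chisq <- 0
  } else {
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    chisq <- unname(sd$chisq)
  }
  structure(list(isomir_id = isomir_id,
                 n = table(group),
                 n_events = events_per_group,
                 chi_square = chisq,
                 p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
                 unreliable = unreliable),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("<survival_result> log-rank chi-square = ", format(x$chi_square),
      ", p = ", format.pval(x$p_value),
      if (x$unreliable) " [unreliable: a group has no events]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Median-split survival analysis for one isomiR
#'
#' Splits samples at the median of the isomiR's expression and runs the
#' log-rank test between the high and low groups.
#'
#' @param expression Named numeric vector (sample -> expression).
#' @param clinical Data frame with `sample_id`, `time`, `event`.
#' @param isomir_id Optional id recorded on the result.
#' @return A `survival_result`.
#' @export
median_split_survival <- function(expression, clinical,
                                  isomir_id = NA_character_) {
  shared <- intersect(names(expression), clinical$sample_id)
  if (length(shared) < 4L)
    stop("fewer than 4 samples shared between expression and clinical data",
         call. = FALSE)
  groups <- median_split(expression[shared])
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  logrank_survival(cl$time, cl$event, groups[shared], isomir_id = isomir_id)
}

#' Drug-response comparison between two isomiR-defined groups
#'
#' `DR` is the difference of group mean sensitivities (shifted minus
#' comparison, both pre-scaled to `[0, 1]`); the p-value is a two-sided
#' Wilcoxon rank-sum test. The call is `"resistant"` for `DR > dr_threshold`
#' with `p < alpha`, `"sensitive"` for `DR < -dr_threshold` with `p <
#' alpha`, and `"ns"` otherwise (the conjunction `|DR| > 0.1 & p < 0.05` at
#' the defaults).
#'
#' @param sensitivity Named numeric vector (cell line -> sensitivity in
#'   `[0, 1]`).
#' @param groups Named character vector (cell line -> `"shifted"` /
#'   `"comparison"`).
#' @param drug,isomir_id Optional identifiers recorded on the result.
#' @param dr_threshold,alpha Call thresholds (defaults 0.1 and 0.05).
#' @return A list of class `drug_response_record`: `isomir_id`, `drug`,
#'   `DR`, `p_value`, `call`, group sizes.
#' @export
drug_response_test <- function(sensitivity, groups, drug = NA_character_,
                               isomir_id = NA_character_, dr_threshold = 0.1,
                               alpha = 0.05) {
  if (any(sensitivity < 0 | sensitivity > 1))
    stop("sensitivity values must be pre-scaled to [0, 1]", call. = FALSE)
  shifted <- sensitivity[names(groups)[groups == "shifted"]]
  comparison <- sensitivity[names(groups)[groups == "comparison"]]
  if (length(shifted) == 0L || length(comparison) == 0L)
    stop("both the shifted and the comparison group must be non-empty",
         call. = FALSE)
  dr <- mean(shifted) - mean(comparison)
  p <- wilcoxon_rank_sum(shifted, comparison)$p_value
  call <- if (abs(dr) > dr_threshold && p < alpha) {
    if (dr > 0) "resistant" else "sensitive"
  } else "ns"
  structure(list(isomir_id = isomir_id, drug = drug, DR = dr, p_value = p,
                 call = call,
                 n = c(shifted = length(shifted),
                       comparison = length(comparison))),
            class = "drug_response_record")
}

#' @export
print.drug_response_record <- function(x, ...) {
  cat("<drug_response_record> DR = ", format(x$DR), ", p = ",
      format.pval(x$p_value), ", call = ", x$call, "\n", sep = "")
  invisible(x)
}
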