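#' Split samples into tertiles of platinum SBS signature activity
#'
#' Samples with zero activity are excluded first (only tumors whose clonal
#' expansion fixed treatment mutations carry the signature); the remaining
#' activities are split at their empirical 0.33 and 0.66 quantiles into
#' `lower` (activity <= q33), `middle` (q33 < activity <= q66) and `upper`
#' (activity > q66) groups. A value tied with a threshold goes to the lower
#' of the two groups, deterministically.
#'
#' @param activities Named numeric vector of non-negative platinum SBS
#'   mutation counts keyed by sample.
#' @return Named factor with levels `lower`, `middle`, `upper` over the
#'   positive-activity samples.
#' @export
tertile_split <- function(activities) {
  if (any(activities < 0)) stop("activities must be non-negative",
                                call. = FALSE)
  pos <- activities[activities > 0]
  if (length(pos) < 3L) {
    stop("need at least 3 samples with positive activity", call. = FALSE)
  }
  qs <- stats::quantile(pos, c(0.33, 0.66), names = FALSE)
  if (qs[1] == qs[2]) {
    stop("degenerate tertile thresholds (too many tied activities)",
         call. = FALSE)
  }
  lab <- ifelse(pos <= qs[1], "lower", ifelse(pos <= qs[2], "middle",
                                              "upper"))
  factor(stats::setNames(lab, names(pos)),
         levels = c("lower", "middle", "upper"))
}

#' Compare footprint intensity between SBS-activity tertiles
#'
#' Two-sided Wilcoxon-Mann-Whitney comparison of per-sample platinum CN
#' footprint intensities between the lower and the upper tertile of
#' platinum SBS signature activity (the middle tertile is excluded). A
#' rising footprint with rising signature activity links the CN footprint
#' to the intensity of the exposure.
#'
#' @param intensities Named numeric vector of per-sample footprint
#'   intensities ([footprint_intensity()]).
#' @param groups Tertile labels from [tertile_split()] (named factor).
#' @param exact_max_n Exact-null size limit for the rank test.
#' @return List with `p_value`, `median_lower`, `median_upper`,
#'   `n_lower`, `n_upper`.
#' @export
compare_tertiles <- function(intensities, groups, exact_max_n = 25) {
  lower <- names(groups)[groups == "lower"]
  upper <- names(groups)[groups == "upper"]
  lower <- intersect(lower, names(intensities))
  upper <- intersect(upper, names(intensities))
  if (length(lower) == 0L || length(upper) == 0L) {
    stop("both lower and upper tertiles must be non-empty", call. = FALSE)
  }
  x_up <- intensities[upper]
  x_lo <- intensities[lower]
  list(p_value = rank_sum_p(x_up, x_lo, exact_max_n),
       median_lower = stats::median(x_lo),
       median_upper = stats::median(x_up),
       n_lower = length(x_lo), n_upper = length(x_up))
}
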