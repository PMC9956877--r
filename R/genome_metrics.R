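#' Length-weighted average genome ploidy
#'
#' The ploidy of a genome is the mean of the total copy number of its called
#' CN segments weighted by their genomic length:
#' sum(total_cn * length) / sum(length).
#'
#' @param segments A `cn_segments` table for a single sample (or any subset
#'   of rows belonging to one genome).
#' @return Ploidy (copies), a single number.
#' @export
average_ploidy <- function(segments) {
  if (nrow(segments) == 0L) {
    stop("ploidy is undefined for an empty segment table", call. = FALSE)
  }
  len <- segments$end - segments$start
  sum(segments$total_cn * len) / sum(len)
}

#' Fraction of the callable genome under loss of heterozygosity
#'
#' The LoH fraction is the summed length of segments satisfying the
#' dialect's LoH rule (minor copy number exactly 0 for integer calls;
#' strictly below 0.5 for continuous calls) divided by the callable genome,
#' i.e. the summed length of all called segments.
#'
#' @param segments A `cn_segments` table for a single sample.
#' @param dialect Optional dialect override; default: the table's dialect.
#' @return Fraction in \[0, 1\].
#' @export
loh_fraction <- function(segments, dialect = NULL) {
  if (nrow(segments) == 0L) {
    stop("LoH fraction is undefined for an empty segment table",
         call. = FALSE)
  }
  if (is.null(dialect)) dialect <- segment_dialect(segments)
  len <- segments$end - segments$start
  sum(len[is_loh(segments$minor_cn, dialect)]) / sum(len)
}

#' Whole-genome doubling classification rule
#'
#' The WGD rule is the linear decision boundary in the (LoH fraction,
#' ploidy) plane that separates the diploid-like and genome-doubled clusters
#' of tumor cohorts: a sample is WGD when
#' `intercept - slope * loh <= ploidy`. Defaults: intercept 2.9 ploidy
#' units, slope 1.7 ploidy units per unit LoH fraction.
#'
#' @param intercept Ploidy intercept at LoH 0 (> 0).
#' @param slope Decrease of the ploidy threshold per unit LoH (>= 0).
#' @return A list with elements `intercept` and `slope`.
#' @export
wgd_rule <- function(intercept = 2.9, slope = 1.7) {
  stopifnot(intercept > 0, slope >= 0)
  list(intercept = intercept, slope = slope)
}

#' Classify whole-genome doubling from ploidy and LoH fraction
#'
#' A sample is classified WGD when `intercept - slope * loh <= ploidy`;
#' the boundary itself is classified WGD. The comparison is exact on the
#' supplied values: the rule is a definition, not an estimate, so no
#' tolerance is applied.
#'
#' @param ploidy Numeric vector of length-weighted ploidies.
#' @param loh Numeric vector of LoH fractions in \[0, 1\] (recycled).
#' @param rule A [wgd_rule()].
#' @return Logical vector: `TRUE` for WGD.
#' @export
classify_wgd <- function(ploidy, loh, rule = wgd_rule()) {
  if (any(is.na(loh)) || any(loh < 0 | loh > 1)) {
    stop("LoH fraction must lie in [0, 1]", call. = FALSE)
  }
  rule$intercept - rule$slope * loh <= ploidy
}

#' Per-sample genome profiles: ploidy, LoH fraction, WGD status
#'
#' Computes the length-weighted ploidy, callable LoH fraction and WGD
#' classification for every sample in a segment table.
#'
#' @param segments A `cn_segments` table (one or more samples).
#' @param rule A [wgd_rule()].
#' @return A `data.frame` with columns `sample`, `ploidy`, `loh_fraction`,
#'   `wgd`, one row per sample.
#' @export
sample_profiles <- function(segments, rule = wgd_rule()) {
  dialect <- segment_dialect(segments)
  pieces <- split(seq_len(nrow(segments)), segments$sample)
  out <- do.call(rbind, lapply(names(pieces), function(s) {
    sub <- segments[pieces[[s]], , drop = FALSE]
    data.frame(sample = s,
               ploidy = average_ploidy(sub),
               loh_fraction = loh_fraction(sub, dialect),
               stringsAsFactors = FALSE)
  }))
  out$wgd <- classify_wgd(out$ploidy, out$loh_fraction, rule)
  rownames(out) <- NULL
  out
}
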