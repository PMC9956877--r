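#' hg19 autosome lengths
#'
#' Chromosome lengths (bp) of the GRCh37/hg19 reference autosomes, the
#' coordinate frame of the bundled genome model.
#'
#' @return Named numeric vector, names `"1".."22"`.
#' @export
hg19_autosomes <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566)
}

#' Footprint configuration
#'
#' Filters defining the platinum CN footprint: heterozygous or LoH segments
#' with rounded total copy number between `cn_min` and `cn_max` (inclusive;
#' homozygous deletions are excluded) and length strictly below
#' `max_length`. `region_bin` is the width of the genomic bins of the
#' regional analysis, and `genome` the autosome length table.
#'
#' @param cn_min,cn_max Inclusive rounded-CN bounds (defaults 1 and 4).
#' @param max_length Strict upper length bound in bp (default 10 Mb).
#' @param region_bin Regional bin width in bp (default 1 Mb).
#' @param genome Named vector of autosome lengths (default
#'   [hg19_autosomes()]).
#' @return A list of class `footprint_config`.
#' @export
footprint_config <- function(cn_min = 1, cn_max = 4, max_length = 1e7,
                             region_bin = 1e6, genome = hg19_autosomes()) {
  stopifnot(cn_min <= cn_max, max_length > 0, region_bin > 0)
  structure(list(cn_min = cn_min, cn_max = cn_max, max_length = max_length,
                 region_bin = region_bin, genome = genome),
            class = "footprint_config")
}

qualifies_footprint <- function(segments, config) {
  rounded <- round_cn(segments$total_cn)
  len <- segments$end - segments$start
  rounded >= config$cn_min & rounded <= config$cn_max &
    rounded >= 1 &            # homdel never qualifies
    len < config$max_length
}

#' Per-sample platinum CN footprint intensity
#'
#' Counts, for every sample, the heterozygous or LoH segments with rounded
#' total copy number between `cn_min` and `cn_max` (default 1-4) and length
#' strictly below `max_length` (default 10 Mb) — the direct per-tumor
#' measure of the platinum CN footprint.
#'
#' @param segments A `cn_segments` table (one or more samples).
#' @param config A [footprint_config()].
#' @param samples Optional sample ids to report (zero counts for samples
#'   with no qualifying segment).
#' @return Named integer vector of counts keyed by sample.
#' @export
footprint_intensity <- function(segments, config = footprint_config(),
                                samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(segments$sample))
  q <- qualifies_footprint(segments, config)
  counts <- table(factor(segments$sample[q], levels = samples))
  stats::setNames(as.integer(counts), samples)
}

#' Cumulative CN-profile difference between exposed and unexposed tumors
#'
#' Sums the 48-category counts over all exposed samples and over all
#' unexposed samples and subtracts the unexposed vector from the exposed
#' one. Positive components mark CN categories with higher prevalence
#' across exposed tumors; they constitute the CN footprint of the exposure.
#'
#' @param feature_matrix Samples x 48 count matrix.
#' @param exposed Logical vector along the matrix rows, or character vector
#'   of exposed sample ids.
#' @param normalize If `TRUE`, per-group mean profiles are subtracted
#'   instead of sums (non-default variant for unbalanced groups).
#' @return Named numeric 48-vector of signed count differences.
#' @export
profile_difference <- function(feature_matrix, exposed, normalize = FALSE) {
  if (is.character(exposed)) {
    exposed <- rownames(feature_matrix) %in% exposed
  }
  if (!any(exposed) || all(exposed)) {
    stop("both exposure groups must be non-empty", call. = FALSE)
  }
  agg <- if (normalize) colMeans else colSums
  agg(feature_matrix[exposed, , drop = FALSE]) -
    agg(feature_matrix[!exposed, , drop = FALSE])
}

#' Regional distribution of the footprint difference along the genome
#'
#' Divides every autosome into `region_bin`-wide bins, assigns each
#' footprint-qualifying segment of each tumor to the bin containing its
#' midpoint, and reports per bin the mean per-tumor count across exposed
#' tumors minus the mean across unexposed tumors. Under a uniform
#' genome-wide fragmentation process no bin should stand out.
#'
#' @param segments A `cn_segments` table for the cohort.
#' @param exposed Character vector of exposed sample ids (all other samples
#'   in the table are the unexposed group).
#' @param config A [footprint_config()] carrying the genome build.
#' @return A `data.frame` with columns `chrom`, `bin_start`, `difference`
#'   (one row per bin of every autosome in the genome table).
#' @export
regional_difference <- function(segments, exposed,
                                config = footprint_config()) {
  samples <- sort(unique(segments$sample))
  exposed <- intersect(exposed, samples)
  unexposed <- setdiff(samples, exposed)
  if (length(exposed) == 0L || length(unexposed) == 0L) {
    stop("both exposure groups must be non-empty", call. = FALSE)
  }
  counts <- regional_counts(segments, config, samples)
  bins <- attr(counts, "bins")
  mean_e <- colMeans(counts[exposed, , drop = FALSE])
  mean_u <- colMeans(counts[unexposed, , drop = FALSE])
  data.frame(chrom = bins$chrom, bin_start = bins$bin_start,
             difference = as.numeric(mean_e - mean_u),
             stringsAsFactors = FALSE)
}

#' Per-sample, per-bin counts of footprint-qualifying fragments
#'
#' Midpoint binning of footprint-qualifying segments into fixed-width
#' genomic bins; the row sums equal each sample's [footprint_intensity()].
#'
#' @param segments A `cn_segments` table.
#' @param config A [footprint_config()].
#' @param samples Optional sample ids (rows).
#' @return Samples x bins numeric matrix with attribute `bins` (data.frame
#'   `chrom`, `bin_start`).
#' @export
regional_counts <- function(segments, config = footprint_config(),
                            samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(segments$sample))
  genome <- config$genome
  chroms <- segments$chrom
  unknown <- setdiff(unique(chroms), names(genome))
  if (length(unknown) > 0L) {
    stop("no genome length for chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(segments$end > genome[chroms])) {
    stop("segment extends beyond chromosome length", call. = FALSE)
  }
  nbin_per_chrom <- ceiling(genome / config$region_bin)
  bins <- data.frame(
    chrom = rep(names(genome), nbin_per_chrom),
    bin_start = unlist(lapply(nbin_per_chrom, function(k) {
      (seq_len(k) - 1) * config$region_bin
    }), use.names = FALSE),
    stringsAsFactors = FALSE)
  bin_id <- paste(bins$chrom, bins$bin_start, sep = ":")
  q <- qualifies_footprint(segments, config)
  mid <- floor((segments$start + segments$end) / 2)
  seg_bin <- paste(chroms, (mid %/% config$region_bin) * config$region_bin,
                   sep = ":")
  tab <- table(factor(segments$sample[q], levels = samples),
               factor(seg_bin[q], levels = bin_id))
  mat <- matrix(as.numeric(tab), nrow = length(samples),
                dimnames = list(samples, bin_id))
  attr(mat, "bins") <- bins
  mat
}

#' Fold change of footprint intensity between exposed and unexposed tumors
#'
#' Ratio of the median per-sample footprint intensity across exposed tumors
#' to the median across unexposed tumors, with the zero-median convention
#' of [compare_groups()] (both 0 gives 1; unexposed 0 alone gives `Inf`).
#'
#' @param exposed,unexposed Non-empty numeric vectors of per-sample
#'   intensities.
#' @return A single number (possibly `Inf`).
#' @export
intensity_fold_change <- function(exposed, unexposed) {
  if (length(exposed) == 0L || length(unexposed) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  median_fold_change(stats::median(exposed), stats::median(unexposed))
}
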