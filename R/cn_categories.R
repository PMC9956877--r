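#' The canonical 48-category copy-number feature space
#'
#' Somatic CN segments are classified by total copy-number level
#' (0, 1, 2, 3-4, 5-8, 9+), zygosity (homozygous deletion, LoH,
#' heterozygous) and segment length. Heterozygous and LoH segments use five
#' length bins (0-100Kb, 100Kb-1Mb, 1Mb-10Mb, 10Mb-40Mb, 40Mb+); homozygous
#' deletions use a reduced set of three (0-100Kb, 100Kb-1Mb, 1Mb+). Valid
#' combinations are: homdel (CN 0) x 3 lengths, LoH x CN {1,2,3-4,5-8,9+}
#' x 5 lengths, and het x CN {2,3-4,5-8,9+} x 5 lengths — 3 + 25 + 20 = 48
#' mutually exclusive, exhaustive categories. A single retained copy cannot
#' be heterozygous, so CN level 1 only occurs with LoH.
#'
#' @return A `data.frame` with 48 rows and columns `label`, `cn_level`,
#'   `zygosity`, `length_bin`, in the canonical order (homdel block, then LoH
#'   by CN level then length, then het by CN level then length). The order is
#'   deterministic and is the column order of all feature matrices.
#' @export
cn_category_space <- function() {
  len5 <- c("0-100Kb", "100Kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", "40Mb+")
  len3 <- c("0-100Kb", "100Kb-1Mb", "1Mb+")
  rows <- list(data.frame(cn_level = "0", zygosity = "homdel",
                          length_bin = len3, stringsAsFactors = FALSE))
  for (lv in c("1", "2", "3-4", "5-8", "9+")) {
    rows[[length(rows) + 1L]] <- data.frame(cn_level = lv, zygosity = "LoH",
                                            length_bin = len5,
                                            stringsAsFactors = FALSE)
  }
  for (lv in c("2", "3-4", "5-8", "9+")) {
    rows[[length(rows) + 1L]] <- data.frame(cn_level = lv, zygosity = "het",
                                            length_bin = len5,
                                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- cbind(label = paste(out$cn_level, out$zygosity, out$length_bin,
                             sep = ":"),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Round a continuous copy number to its integer level
#'
#' Half-up rounding: 2.5 copies rounds to 3. Used to map continuous
#' (PURPLE-style) calls onto the discrete CN levels.
#'
#' @param cn Numeric vector of copy numbers.
#' @return Integer-valued numeric vector.
#' @export
round_cn <- function(cn) floor(cn + 0.5)

cn_level_of <- function(rounded) {
  lv <- character(length(rounded))
  lv[rounded == 0] <- "0"
  lv[rounded == 1] <- "1"
  lv[rounded == 2] <- "2"
  lv[rounded >= 3 & rounded <= 4] <- "3-4"
  lv[rounded >= 5 & rounded <= 8] <- "5-8"
  lv[rounded >= 9] <- "9+"
  lv
}

length_bin_of <- function(len, homdel) {
  # half-open [low, high): a 100,000-bp segment is in 100Kb-1Mb
  bin <- character(length(len))
  bin[len < 1e5] <- "0-100Kb"
  bin[len >= 1e5 & len < 1e6] <- "100Kb-1Mb"
  long <- len >= 1e6
  bin[long & homdel] <- "1Mb+"
  bin[long & !homdel & len < 1e7] <- "1Mb-10Mb"
  bin[long & !homdel & len >= 1e7 & len < 4e7] <- "10Mb-40Mb"
  bin[long & !homdel & len >= 4e7] <- "40Mb+"
  bin
}

is_loh <- function(minor_cn, dialect) {
  if (dialect == "integer") minor_cn == 0 else minor_cn < 0.5
}

#' Assign CN segments to their category
#'
#' Vectorized classification of segments into the 48-category space: the
#' total copy number is rounded half-up to its CN level; zygosity is homdel
#' when the rounded total is 0, LoH when the rounded total is 1 or the
#' dialect's LoH rule holds on the minor copy number (exactly 0 for the
#' integer dialect, strictly below 0.5 for the continuous dialect), and het
#' otherwise; the length bin uses half-open boundaries.
#'
#' @param total_cn Numeric vector of total copy numbers.
#' @param minor_cn Numeric vector of minor-allele copy numbers.
#' @param length_bp Numeric vector of segment lengths in bp.
#' @param dialect `"integer"` or `"continuous"`.
#' @return Character vector of canonical category labels.
#' @export
assign_category <- function(total_cn, minor_cn, length_bp,
                            dialect = c("integer", "continuous")) {
  dialect <- match.arg(dialect)
  rounded <- round_cn(total_cn)
  zyg <- ifelse(rounded == 0, "homdel",
                ifelse(rounded == 1 | is_loh(minor_cn, dialect),
                       "LoH", "het"))
  lv <- cn_level_of(rounded)
  bin <- length_bin_of(length_bp, zyg == "homdel")
  paste(lv, zyg, bin, sep = ":")
}

#' Build the per-sample CN category feature matrix
#'
#' Counts each sample's segments in each of the 48 CN categories. Every
#' segment falls in exactly one category, so row sums equal per-sample
#' segment counts.
#'
#' @param segments A `cn_segments` table (one or more samples).
#' @param samples Optional character vector of sample ids to include (rows
#'   for samples with no segments are all-zero). Default: samples present in
#'   the table.
#' @return Integer matrix, rows named by sample, 48 canonical columns.
#' @export
build_feature_matrix <- function(segments, samples = NULL) {
  dialect <- segment_dialect(segments)
  canon <- cn_category_space()$label
  if (is.null(samples)) samples <- sort(unique(segments$sample))
  cat <- assign_category(segments$total_cn, segments$minor_cn,
                         segments$end - segments$start, dialect)
  bad <- setdiff(unique(cat), canon)
  if (length(bad) > 0L) {
    stop("segment mapped outside the category space: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(segments$sample, levels = samples),
               factor(cat, levels = canon))
  mat <- matrix(as.integer(tab), nrow = length(samples),
                dimnames = list(samples, canon))
  mat
}
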