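#' Read an allele-specific copy-number segment table
#'
#' Reads a BED-like TSV of somatic copy-number segments for one or more
#' samples and returns a validated segment table. Two dialects of
#' allele-specific calls are supported: `"integer"` (absolute integer copy
#' numbers, PCAWG-style callers) and `"continuous"` (continuous copy numbers,
#' PURPLE-style callers). The dialect determines the loss-of-heterozygosity
#' rule used downstream (minor copy number exactly 0 vs. strictly below 0.5)
#' and is stored on the returned table.
#'
#' The input must have header columns `sample`, `chrom`, `start`, `end`,
#' `total_cn`, `minor_cn` (extra columns are ignored). Coordinates are
#' 0-based half-open internally; files recorded 1-based inclusive can be
#' converted on read with `one_based = TRUE`. Only autosomes `"1".."22"`
#' (with or without a `"chr"` prefix) are analyzed; other rows are dropped
#' with a message reporting the count. Gzipped files are read transparently.
#'
#' @param path Path to a TSV (optionally gzipped) segment file.
#' @param dialect `"integer"` or `"continuous"`; the copy-number call dialect.
#' @param one_based If `TRUE`, input coordinates are 1-based inclusive and are
#'   converted to 0-based half-open on read. Default `FALSE`.
#' @return A `data.frame` with columns `sample`, `chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`, sorted by sample, chromosome and start, with
#'   attribute `dialect`. Class `c("cn_segments", "data.frame")`.
#' @seealso [validate_segments()], [write_segments()]
#' @export
read_segments <- function(path, dialect = c("integer", "continuous"),
                          one_based = FALSE) {
  dialect <- match.arg(dialect)
  df <- read_tsv_checked(path, c("sample", "chrom", "start", "end",
                                 "total_cn", "minor_cn"))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad) > 0L) {
      stop(sprintf("malformed %s at line %d of %s: %s", col,
                   bad[1L] + 1L, path, df[[col]][bad[1L]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  for (col in c("total_cn", "minor_cn")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("malformed %s at line %d of %s: %s", col,
                   bad[1L] + 1L, path, df[[col]][bad[1L]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  if (one_based) df$start <- df$start - 1
  df$chrom <- sub("^chr", "", as.character(df$chrom))
  keep <- df$chrom %in% autosome_names()
  if (any(!keep)) {
    message(sprintf("read_segments: dropped %d non-autosomal row(s)",
                    sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  df <- df[, c("sample", "chrom", "start", "end", "total_cn", "minor_cn")]
  df$sample <- as.character(df$sample)
  as_segments(df, dialect)
}

#' Construct and validate a segment table from a data.frame
#'
#' @param df Data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `total_cn`, `minor_cn`.
#' @param dialect `"integer"` or `"continuous"`.
#' @return The sorted, validated table with class `cn_segments`.
#' @export
as_segments <- function(df, dialect = c("integer", "continuous")) {
  dialect <- match.arg(dialect)
  need <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, need]
  df$sample <- as.character(df$sample)
  df$chrom <- as.character(df$chrom)
  ord <- order(df$sample, suppressWarnings(as.integer(df$chrom)), df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  validate_segments(df)
  attr(df, "dialect") <- dialect
  class(df) <- c("cn_segments", "data.frame")
  df
}

#' Validate segment-table invariants
#'
#' Checks that every segment has positive length, non-negative copy numbers,
#' a minor allele no larger than the major allele (tolerance 1e-9), a
#' non-missing minor copy number, and that segments of one sample do not
#' overlap within a chromosome.
#'
#' @param df A segment data.frame sorted by sample, chromosome, start.
#' @return Invisibly `TRUE`; stops with a validation error otherwise.
#' @export
validate_segments <- function(df) {
  if (nrow(df) == 0L) return(invisible(TRUE))
  if (anyNA(df$minor_cn)) {
    stop("missing minor_cn is not allowed (zygosity is undefined)",
         call. = FALSE)
  }
  if (anyNA(df$total_cn) || anyNA(df$start) || anyNA(df$end)) {
    stop("missing coordinates or total_cn", call. = FALSE)
  }
  bad <- which(df$end <= df$start)
  if (length(bad) > 0L) {
    stop(sprintf("segment with end <= start (sample %s, %s:%g-%g)",
                 df$sample[bad[1L]], df$chrom[bad[1L]],
                 df$start[bad[1L]], df$end[bad[1L]]), call. = FALSE)
  }
  bad <- which(df$total_cn < 0 | df$minor_cn < 0)
  if (length(bad) > 0L) {
    stop(sprintf("negative copy number (sample %s, %s:%g-%g)",
                 df$sample[bad[1L]], df$chrom[bad[1L]],
                 df$start[bad[1L]], df$end[bad[1L]]), call. = FALSE)
  }
  bad <- which(df$minor_cn > df$total_cn - df$minor_cn + 1e-9)
  if (length(bad) > 0L) {
    stop(sprintf("minor_cn exceeds major allele (sample %s, %s:%g-%g)",
                 df$sample[bad[1L]], df$chrom[bad[1L]],
                 df$start[bad[1L]], df$end[bad[1L]]), call. = FALSE)
  }
  same <- df$sample[-1L] == df$sample[-nrow(df)] &
    df$chrom[-1L] == df$chrom[-nrow(df)]
  ovl <- which(same & df$start[-1L] < df$end[-nrow(df)])
  if (length(ovl) > 0L) {
    i <- ovl[1L]
    stop(sprintf("overlapping segments (sample %s, %s: %g-%g and %g-%g)",
                 df$sample[i], df$chrom[i], df$start[i], df$end[i],
                 df$start[i + 1L], df$end[i + 1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a segment table to TSV
#'
#' @param segments A `cn_segments` table.
#' @param path Output path; `.gz` suffix writes gzipped.
#' @export
write_segments <- function(segments, path) {
  write_tsv(as.data.frame(segments), path)
}

#' Dialect of a segment table
#' @param segments A `cn_segments` table.
#' @return `"integer"` or `"continuous"`.
#' @export
segment_dialect <- function(segments) {
  d <- attr(segments, "dialect")
  if (is.null(d)) stop("segment table has no dialect attribute", call. = FALSE)
  d
}

#' Sum of segment lengths per sample
#' @param segments A `cn_segments` table.
#' @return Named numeric vector (bp) keyed by sample.
#' @export
callable_length <- function(segments) {
  len <- segments$end - segments$start
  vapply(split(len, segments$sample), sum, numeric(1))
}

#' Read a clinical table
#'
#' Reads a TSV with columns `sample`, `tumor_type` and `treatments`
#' (semicolon-separated treatment-family labels; an empty field means
#' unexposed to all recorded treatments). Optional columns `sex`,
#' `biopsy_date`, `treatment_end_date` and `death_date` are kept if present;
#' any other column is dropped with a warning. Treatment labels are trimmed
#' and lower-cased.
#'
#' @param path Path to the clinical TSV.
#' @return A `data.frame` with one row per sample and a list-column
#'   `treatments` of character vectors.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path, c("sample", "tumor_type", "treatments"))
  optional <- c("sex", "biopsy_date", "treatment_end_date", "death_date")
  extra <- setdiff(names(df), c("sample", "tumor_type", "treatments", optional))
  if (length(extra) > 0L) {
    warning("ignoring unknown clinical column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  df <- df[, intersect(c("sample", "tumor_type", "treatments", optional),
                       names(df)), drop = FALSE]
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id(s) in clinical table: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "),
         call. = FALSE)
  }
  df$treatments <- parse_treatments(df$treatments)
  for (col in intersect(c("biopsy_date", "treatment_end_date", "death_date"),
                        names(df))) {
    df[[col]] <- as.Date(df[[col]])
  }
  rownames(df) <- NULL
  df
}

parse_treatments <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- tolower(trimws(v))
    sort(unique(v[nzchar(v)]))
  })
}

#' Write a per-sample CN category feature matrix to TSV
#'
#' The matrix must have exactly the 48 canonical category columns in any
#' order; it is written in the canonical [cn_category_space()] column order
#' with sample ids in the first column, so a read-back with
#' [read_feature_matrix()] reproduces it exactly.
#'
#' @param mat Numeric matrix, rows named by sample, columns named by the 48
#'   canonical category labels.
#' @param path Output TSV path.
#' @export
write_feature_matrix <- function(mat, path) {
  canon <- cn_category_space()$label
  if (!setequal(colnames(mat), canon) || ncol(mat) != length(canon)) {
    stop("feature matrix columns must be exactly the 48 canonical categories",
         call. = FALSE)
  }
  mat <- mat[, canon, drop = FALSE]
  out <- data.frame(sample = rownames(mat), check.names = FALSE)
  out[canon] <- as.data.frame(mat, check.names = FALSE)
  write_tsv(out, path)
}

#' Read a per-sample CN category feature matrix from TSV
#'
#' @param path TSV written by [write_feature_matrix()].
#' @return Numeric matrix, rows named by sample, 48 canonical columns.
#' @export
read_feature_matrix <- function(path) {
  df <- read_tsv_checked(path, "sample")
  canon <- cn_category_space()$label
  if (!setequal(setdiff(names(df), "sample"), canon)) {
    stop("feature matrix columns must be exactly the 48 canonical categories",
         call. = FALSE)
  }
  mat <- as.matrix(df[, canon, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- as.character(df$sample)
  mat
}

#' Read per-sample platinum SBS signature activities
#'
#' TSV with columns `sample` and `sbs_count` (non-negative mutation counts
#' attributed to the platinum SBS signature by an external extraction).
#'
#' @param path Path to the activities TSV.
#' @return Named numeric vector of counts keyed by sample.
#' @export
read_sbs_activities <- function(path) {
  df <- read_tsv_checked(path, c("sample", "sbs_count"))
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id(s) in SBS activity table", call. = FALSE)
  }
  counts <- as.numeric(df$sbs_count)
  if (anyNA(counts) || any(counts < 0)) {
    stop("sbs_count must be non-negative numbers", call. = FALSE)
  }
  stats::setNames(counts, as.character(df$sample))
}

autosome_names <- function() as.character(1:22)

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "", fill = FALSE,
                          colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
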