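# Shared fixtures and independent oracles for the test suite.

# Build a validated segment table from parallel vectors.
make_segments <- function(sample, chrom, start, end, total_cn, minor_cn,
                          dialect = "integer") {
  as_segments(data.frame(sample = sample, chrom = as.character(chrom),
                         start = start, end = end, total_cn = total_cn,
                         minor_cn = minor_cn, stringsAsFactors = FALSE),
              dialect = dialect)
}

# A minimal clinical table with a treatments list-column.
make_clinical <- function(sample, tumor_type, treatments, sex = NULL) {
  df <- data.frame(sample = sample, tumor_type = tumor_type,
                   stringsAsFactors = FALSE)
  df$treatments <- lapply(treatments, function(v) sort(tolower(v)))
  if (!is.null(sex)) df$sex <- sex
  df
}

# Independent oracle for the two-sided Mann-Whitney p-value: enumerate every
# assignment of group labels to the combined observations and compare midrank
# sums. Doubles the smaller tail, capped at 1 (the same two-sided convention
# the package documents). Feasible for combined n <= 12.
enum_rank_p <- function(x, y) {
  n1 <- length(x)
  v <- c(x, y)
  n <- length(v)
  r <- rank(v)
  w <- sum(r[seq_len(n1)])
  ws <- utils::combn(n, n1, FUN = function(i) sum(r[i]))
  p_lo <- mean(ws <= w + 1e-9)
  p_hi <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Exposed sample ids of one treatment in a clinical table.
exposed_ids <- function(clinical, treatment) {
  clinical$sample[vapply(clinical$treatments,
                         function(v) treatment %in% v, logical(1))]
}

# Small fast cohort parameter set used across simulation tests.
quick_params <- function(n_samples, seed, ...) {
  cohort_params(n_samples = n_samples, seed = seed, wgd_fraction = 1, ...)
}
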