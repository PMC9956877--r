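#' Parameters of a synthetic tumor cohort
#'
#' Defines the generative model of a cohort of allele-specific CN segment
#' tables with known ground truth. Genomes start as diploid autosomes
#' fragmented by a Poisson number of uniformly placed breakpoints per
#' chromosome; whole-genome-doubled (WGD) genomes are doubled and then lose
#' single copies of randomly chosen segments (biased towards producing LoH)
#' until the length-weighted ploidy reaches `target_ploidy_wgd` within
#' `ploidy_tolerance`. Treatment exposure injects additional short CN 1-4
#' het/LoH fragments (Poisson-many per exposed genome, log-uniform lengths,
#' uniform genome-wide placement), and platinum SBS signature activity is
#' coupled linearly to the injected fragment count with Gaussian noise.
#'
#' @param n_samples Number of samples.
#' @param seed Mandatory integer seed; the full cohort is a deterministic
#'   function of the parameters and this seed.
#' @param tumor_type Tumor-type label for the clinical table.
#' @param wgd_fraction Fraction of WGD genomes (default 0.8).
#' @param target_ploidy_wgd Target length-weighted ploidy of WGD genomes
#'   (default 3.2 copies, the typical post-doubling average after segment
#'   losses).
#' @param target_ploidy_diploid Baseline diploid ploidy (2.0 copies).
#' @param ploidy_tolerance Acceptance half-width around the WGD ploidy
#'   target (default 0.15 copies).
#' @param background_breaks_per_chrom Poisson mean of breakpoints per
#'   autosome (default 3).
#' @param diploid_losses Poisson mean of single-copy segment losses in
#'   non-WGD genomes (default 2).
#' @param loh_bias Probability that a segment loss removes a minor-allele
#'   copy when one is present, driving LoH (default 0.6).
#' @param exposure_rate Poisson mean of injected footprint fragments per
#'   exposed genome (default 30); per-treatment rates override it.
#' @param fragment_length_min,fragment_length_max Log-uniform bounds (bp) of
#'   injected fragment lengths (defaults 10 kb and 10 Mb; the upper bound is
#'   exclusive so injected fragments always satisfy the footprint length
#'   filter).
#' @param treatments List of treatment definitions, each a list with
#'   `name`, `prob` (exposure probability), optional `rate` (overrides
#'   `exposure_rate`; 0 makes the treatment a passenger), and optional
#'   `overlap_with`/`overlap` (target fraction of this treatment's exposed
#'   samples that are also exposed to the named earlier treatment).
#' @param sbs_coupling List with `slope` (SBS mutations per injected
#'   fragment) and `noise_sd` (Gaussian noise sd); defaults 10 and 20.
#' @param dialect Copy-number dialect of the generated tables
#'   (`"integer"`).
#' @param genome Named autosome length vector (default [hg19_autosomes()]).
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_samples, seed, tumor_type = "colorectal",
                          wgd_fraction = 0.8, target_ploidy_wgd = 3.2,
                          target_ploidy_diploid = 2.0,
                          ploidy_tolerance = 0.15,
                          background_breaks_per_chrom = 3,
                          diploid_losses = 2, loh_bias = 0.6,
                          exposure_rate = 30,
                          fragment_length_min = 1e4,
                          fragment_length_max = 1e7,
                          treatments = list(list(name = "platinum",
                                                 prob = 0.5)),
                          sbs_coupling = list(slope = 10, noise_sd = 20),
                          dialect = "integer",
                          genome = hg19_autosomes()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory",
                                           call. = FALSE)
  stopifnot(n_samples >= 1, wgd_fraction >= 0, wgd_fraction <= 1,
            background_breaks_per_chrom >= 0, diploid_losses >= 0,
            loh_bias >= 0, loh_bias <= 1, exposure_rate >= 0,
            fragment_length_min >= 1,
            fragment_length_max > fragment_length_min,
            ploidy_tolerance > 0)
  treatments <- lapply(treatments, function(t) {
    stopifnot(is.character(t$name), t$prob >= 0, t$prob <= 1)
    if (!is.null(t$rate)) stopifnot(t$rate >= 0)
    if (!is.null(t$overlap)) stopifnot(t$overlap >= 0, t$overlap <= 1)
    t$name <- tolower(trimws(t$name))
    if (!is.null(t$overlap_with)) {
      t$overlap_with <- tolower(trimws(t$overlap_with))
    }
    t
  })
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 tumor_type = tumor_type, wgd_fraction = wgd_fraction,
                 target_ploidy_wgd = target_ploidy_wgd,
                 target_ploidy_diploid = target_ploidy_diploid,
                 ploidy_tolerance = ploidy_tolerance,
                 background_breaks_per_chrom = background_breaks_per_chrom,
                 diploid_losses = diploid_losses, loh_bias = loh_bias,
                 exposure_rate = exposure_rate,
                 fragment_length_min = fragment_length_min,
                 fragment_length_max = fragment_length_max,
                 treatments = treatments, sbs_coupling = sbs_coupling,
                 dialect = dialect, genome = genome),
            class = "cohort_params")
}

# One segment-loss event: remove one copy of one allele of a random segment
# (sampled proportionally to length among segments with total >= 2), with
# probability loh_bias from the minor allele when one is present.
apply_loss <- function(total, minor, idx, loh_bias) {
  if (minor[idx] > 0 && stats::runif(1) < loh_bias) {
    minor[idx] <- minor[idx] - 1
  }
  total[idx] <- total[idx] - 1
  if (minor[idx] > total[idx] - minor[idx]) {
    minor[idx] <- total[idx] - minor[idx]  # relabel: minor is the smaller
  }
  list(total = total, minor = minor)
}

#' Simulate one genome's segment table
#'
#' Partitions each autosome at a Poisson number of uniformly placed
#' breakpoints into baseline CN 2 (minor 1) segments. WGD genomes are
#' doubled to CN 4 (minor 2) and then lose single segment copies until the
#' length-weighted ploidy is within `ploidy_tolerance` of
#' `target_ploidy_wgd`; diploid genomes receive a small Poisson number of
#' losses. Losses preferentially remove minor-allele copies (`loh_bias`),
#' producing the elevated LoH typical of genome-doubled tumors. Uses the
#' current RNG state; seed the session (or call via [simulate_cohort()])
#' for reproducibility.
#'
#' @param params A [cohort_params()].
#' @param wgd Logical: generate a whole-genome-doubled genome.
#' @param sample_id Sample id for the table.
#' @param max_iter Cap on loss iterations while approaching the ploidy
#'   target (default 10000).
#' @return A validated `cn_segments` table for one sample.
#' @export
simulate_genome <- function(params, wgd = TRUE, sample_id = "S1",
                            max_iter = 10000) {
  genome <- params$genome
  chrom <- character(0); start <- numeric(0); end <- numeric(0)
  for (ch in names(genome)) {
    L <- genome[[ch]]
    k <- stats::rpois(1, params$background_breaks_per_chrom)
    bp <- if (k > 0) sort(sample.int(L - 1L, min(k, L - 1L))) else numeric(0)
    bounds <- c(0, bp, L)
    chrom <- c(chrom, rep(ch, length(bounds) - 1L))
    start <- c(start, bounds[-length(bounds)])
    end <- c(end, bounds[-1L])
  }
  len <- end - start
  G <- sum(len)
  if (wgd) {
    total <- rep(4, length(len)); minor <- rep(2, length(len))
    target <- params$target_ploidy_wgd
    tol <- params$ploidy_tolerance
    # per-genome stopping point inside the band, so cohort ploidies center
    # on the target rather than piling up at its upper edge
    stop_at <- stats::runif(1, target - tol, target + tol)
    pl <- sum(total * len) / G
    iter <- 0L
    while (pl > stop_at) {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop(sprintf("ploidy target %.2f unreachable within %d iterations",
                     target, max_iter), call. = FALSE)
      }
      # only segments whose single-copy loss keeps ploidy inside the band
      cand <- which(total >= 2 & len / G <= pl - (target - tol))
      if (length(cand) == 0L) {
        if (pl <= target + tol) break  # already inside the band
        stop(sprintf("ploidy target %.2f unreachable: no segment left to lose",
                     target), call. = FALSE)
      }
      i <- cand[sample.int(length(cand), 1L, prob = len[cand])]
      upd <- apply_loss(total, minor, i, params$loh_bias)
      total <- upd$total; minor <- upd$minor
      pl <- pl - len[i] / G
    }
  } else {
    total <- rep(2, length(len)); minor <- rep(1, length(len))
    nl <- stats::rpois(1, params$diploid_losses)
    for (j in seq_len(nl)) {
      cand <- which(total >= 2)
      if (length(cand) == 0L) break
      i <- cand[sample.int(length(cand), 1L, prob = len[cand])]
      upd <- apply_loss(total, minor, i, params$loh_bias)
      total <- upd$total; minor <- upd$minor
    }
  }
  as_segments(data.frame(sample = sample_id, chrom = chrom, start = start,
                         end = end, total_cn = total, minor_cn = minor,
                         stringsAsFactors = FALSE),
              dialect = params$dialect)
}

#' Inject exposure-associated footprint fragments into a genome
#'
#' Draws a Poisson(`rate`) number of new fragments with log-uniform lengths
#' in `[fragment_length_min, fragment_length_max)` and rounded copy number
#' uniform in 1-4 (CN 1 always LoH; higher CN het or LoH with equal
#' probability), and splices them into the table. Host segments are sampled
#' proportionally to their length (so the aggregate placement across
#' genomes is close to uniform genome-wide), and each new fragment is
#' carved at a randomly chosen edge of its host, shortening the host by the
#' fragment length. Hosts are restricted to those that remain in their own
#' length bin after shortening, so the exposure effect is purely additive
#' on the 48 category counts: each injection adds exactly one fragment to
#' one footprint-qualifying category and changes no other category. The
#' increase of [footprint_intensity()] therefore equals the Poisson draw
#' exactly.
#'
#' @param table A validated `cn_segments` table for one sample.
#' @param rate Poisson mean of injected fragments.
#' @param params A [cohort_params()] (length bounds, dialect).
#' @return The spliced table with attribute `n_injected` (number of
#'   fragments actually placed).
#' @export
inject_platinum_effect <- function(table, rate, params) {
  k <- if (rate > 0) stats::rpois(1, rate) else 0L
  df <- as.data.frame(table)
  # each host edge hosts at most one injected fragment per round, so
  # fragments spread over distinct (uniformly located) segment boundaries
  # instead of stacking inside one genomic bin; chromosome-terminal edges
  # are excluded because they sit at the same coordinates in every genome
  # and would accumulate cross-sample hotspots at chromosome ends
  edge_used <- cbind(df$start == 0,
                     df$end == params$genome[df$chrom])
  placed <- 0L
  for (j in seq_len(k)) {
    len <- floor(exp(stats::runif(1, log(params$fragment_length_min),
                                  log(params$fragment_length_max))))
    cn <- sample.int(4L, 1L)
    minor <- if (cn == 1L || stats::runif(1) < 0.5) {
      0
    } else {
      sample.int(cn %/% 2L, 1L)
    }
    host_len <- df$end - df$start
    remnant <- host_len - len
    free_edge <- !edge_used[, 1] | !edge_used[, 2]
    ok <- which(free_edge & remnant >= 1 &
                  length_bin_of(remnant, FALSE) ==
                    length_bin_of(host_len, FALSE))
    if (length(ok) == 0L) ok <- which(free_edge & remnant >= 1)  # fallback
    if (length(ok) == 0L) next  # genome too fragmented to host this length
    h <- ok[sample.int(length(ok), 1L, prob = host_len[ok])]
    free <- which(!edge_used[h, ])
    side <- free[sample.int(length(free), 1L)]
    edge_used[h, side] <- TRUE
    piece <- df[h, , drop = FALSE]
    piece$total_cn <- cn
    piece$minor_cn <- minor
    if (side == 1L) {             # carve at the host's start edge
      piece$end <- piece$start + len
      df$start[h] <- df$start[h] + len
    } else {                      # carve at the host's end edge
      piece$start <- piece$end - len
      df$end[h] <- df$end[h] - len
    }
    df <- rbind(df, piece)
    edge_used <- rbind(edge_used, c(TRUE, TRUE))  # new fragments not re-hosts
    placed <- placed + 1L
  }
  out <- as_segments(df, dialect = segment_dialect(table))
  attr(out, "n_injected") <- placed
  out
}

assign_exposures <- function(params, ids) {
  n <- length(ids)
  exposure <- list()
  for (t in params$treatments) {
    n_t <- round(t$prob * n)
    if (is.null(t$overlap_with)) {
      exposure[[t$name]] <- sample(ids, n_t)
    } else {
      base <- exposure[[t$overlap_with]]
      if (is.null(base)) {
        stop("overlap_with references unknown treatment: ", t$overlap_with,
             call. = FALSE)
      }
      n_in <- round(t$overlap * n_t)
      n_out <- n_t - n_in
      outside <- setdiff(ids, base)
      if (n_in > length(base) || n_out > length(outside)) {
        stop(sprintf("infeasible overlap configuration for treatment %s",
                     t$name), call. = FALSE)
      }
      exposure[[t$name]] <- c(sample(base, n_in),
                              if (n_out > 0) sample(outside, n_out))
    }
  }
  exposure
}

#' Simulate a full cohort with ground truth
#'
#' Generates segment tables, clinical records and platinum SBS signature
#' activities for `params$n_samples` genomes: WGD status per
#' `wgd_fraction`, treatment exposure per the configured probabilities and
#' pairwise overlap targets, Poisson fragment injection for exposed genomes
#' (summing the rates of all exposing treatments), and SBS counts coupled
#' linearly to the injected fragment count with truncated Gaussian noise
#' (unexposed samples have activity 0). The whole cohort is a
#' deterministic function of the parameters and `params$seed`.
#'
#' @param params A [cohort_params()].
#' @return List with `segments` (combined `cn_segments` table), `clinical`
#'   (data.frame: sample, tumor_type, treatments list-column), `sbs` (named
#'   vector of SBS counts), `truth` (data.frame: sample, wgd, n_injected,
#'   rate) and `params`.
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  wgd <- seq_len(n) <= round(n * params$wgd_fraction)
  exposure <- assign_exposures(params, ids)
  rate <- stats::setNames(numeric(n), ids)
  for (t in params$treatments) {
    r <- if (is.null(t$rate)) params$exposure_rate else t$rate
    rate[exposure[[t$name]]] <- rate[exposure[[t$name]]] + r
  }
  tables <- vector("list", n)
  n_injected <- integer(n)
  for (i in seq_len(n)) {
    tab <- simulate_genome(params, wgd = wgd[i], sample_id = ids[i])
    if (rate[i] > 0) {
      tab <- inject_platinum_effect(tab, rate[i], params)
      n_injected[i] <- attr(tab, "n_injected")
    }
    tables[[i]] <- as.data.frame(tab)
  }
  segments <- as_segments(do.call(rbind, tables), dialect = params$dialect)
  exposed_any <- ids %in% unique(unlist(exposure))
  sbs <- stats::setNames(numeric(n), ids)
  cp <- params$sbs_coupling
  for (i in which(exposed_any)) {
    sbs[i] <- max(0, round(cp$slope * n_injected[i] +
                             stats::rnorm(1, 0, cp$noise_sd)))
  }
  treatments_col <- lapply(ids, function(id) {
    sort(vapply(params$treatments, function(t) t$name,
                character(1))[vapply(params$treatments, function(t) {
                  id %in% exposure[[t$name]]
                }, logical(1))])
  })
  clinical <- data.frame(sample = ids, tumor_type = params$tumor_type,
                         stringsAsFactors = FALSE)
  clinical$treatments <- treatments_col
  truth <- data.frame(sample = ids, wgd = wgd, n_injected = n_injected,
                      rate = as.numeric(rate), stringsAsFactors = FALSE)
  list(segments = segments, clinical = clinical, sbs = sbs, truth = truth,
       params = params)
}
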