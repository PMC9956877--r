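#' Screen configuration
#'
#' Parameters of the exposure association screen: the minimum number of
#' samples required in both the exposed and unexposed arm of a tumor-type /
#' treatment combination, the sample-overlap fraction above which two
#' treatments are collapsed to a single representative before multiple-test
#' correction (strictly greater than), the FDR level, and whether the screen
#' is restricted to whole-genome-doubled samples.
#'
#' @param min_group_size Minimum samples per arm (default 20).
#' @param overlap_threshold Collapse treatments whose exposed or unexposed
#'   sample sets overlap by more than this fraction in either direction
#'   (default 0.9, strict).
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param wgd_only Restrict to WGD samples (default `TRUE`).
#' @param priority Optional character vector of treatment labels; when a set
#'   of overlapping treatments is collapsed, the first label present in this
#'   vector is kept as representative (mirrors manual curation). Default:
#'   the treatment with the larger exposed arm.
#' @param exact_max_n Largest combined group size for which the rank test
#'   uses the exact null (default 25).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(min_group_size = 20, overlap_threshold = 0.9,
                          fdr_alpha = 0.05, wgd_only = TRUE,
                          priority = NULL, exact_max_n = 25) {
  stopifnot(min_group_size >= 2, overlap_threshold > 0,
            overlap_threshold < 1, fdr_alpha > 0, fdr_alpha < 1)
  structure(list(min_group_size = min_group_size,
                 overlap_threshold = overlap_threshold,
                 fdr_alpha = fdr_alpha, wgd_only = wgd_only,
                 priority = priority, exact_max_n = exact_max_n),
            class = "screen_config")
}

#' Two-sided rank comparison of exposed vs unexposed category counts
#'
#' Unpaired two-sided Wilcoxon-Mann-Whitney comparison of per-sample counts
#' between an exposed and an unexposed group. For combined sample sizes up
#' to `exact_max_n` the p-value is computed from the exact permutation null
#' of the midrank sum (ties handled exactly, by dynamic programming over the
#' count polynomial); for larger samples the tie-corrected normal
#' approximation with continuity correction is used. The two-sided p-value
#' is twice the smaller tail, capped at 1.
#'
#' The fold change is the ratio of group medians with the zero-median
#' convention: both medians 0 gives 1, an exposed median over an unexposed
#' median of 0 gives `Inf`, and no pseudocounts are added. Direction is
#' `"up"` when the exposed group is larger (by median, with the rank sum
#' breaking exact median ties).
#'
#' @param exposed,unexposed Non-empty numeric vectors of per-sample counts.
#' @param exact_max_n Exact-null size limit (default 25).
#' @return List with `p_value`, `fold_change`, `direction`,
#'   `median_exposed`, `median_unexposed`.
#' @export
compare_groups <- function(exposed, unexposed, exact_max_n = 25) {
  if (length(exposed) == 0L || length(unexposed) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  p <- rank_sum_p(exposed, unexposed, exact_max_n)
  med_e <- stats::median(exposed)
  med_u <- stats::median(unexposed)
  fc <- median_fold_change(med_e, med_u)
  direction <- if (med_e > med_u) {
    "up"
  } else if (med_e < med_u) {
    "down"
  } else {
    # equal medians: break by mean rank
    r <- rank(c(exposed, unexposed))
    if (mean(r[seq_along(exposed)]) >= mean(r[-seq_along(exposed)]))
      "up" else "down"
  }
  list(p_value = p, fold_change = fc, direction = direction,
       median_exposed = med_e, median_unexposed = med_u)
}

median_fold_change <- function(med_e, med_u) {
  if (med_e == 0 && med_u == 0) return(1)
  if (med_u == 0) return(Inf)
  med_e / med_u
}

rank_sum_p <- function(x, y, exact_max_n = 25) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  if (n <= exact_max_n) {
    exact_rank_sum_p(round(2 * r), n1)
  } else {
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- u - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
  }
}

# Exact two-sided tail of the midrank-sum null: scores are doubled midranks
# (integers); dp[k+1, s+1] counts size-k subsets with score sum s.
exact_rank_sum_p <- function(scores, n1) {
  n <- length(scores)
  total <- sum(scores)
  dp <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  dp[1L, 1L] <- 1
  for (sc in scores) {
    kmax <- n1
    for (k in kmax:1L) {
      shifted <- c(rep(0, sc), dp[k, seq_len(total + 1L - sc)])
      dp[k + 1L, ] <- dp[k + 1L, ] + shifted
    }
  }
  dist <- dp[n1 + 1L, ]
  nways <- sum(dist)
  w <- sum(scores[seq_len(n1)])
  p_low <- sum(dist[seq_len(w + 1L)]) / nways
  p_high <- sum(dist[(w + 1L):(total + 1L)]) / nways
  min(1, 2 * min(p_low, p_high))
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Standard step-up BH with monotonicity enforcement; the input order is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values in the input order.
#' @export
fdr_correct <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

has_treatment <- function(treatment_lists, treatment) {
  treatment <- tolower(trimws(treatment))
  vapply(treatment_lists, function(v) treatment %in% v, logical(1))
}

#' Collapse treatments with heavily overlapping exposure
#'
#' For every pair of treatments, the sample overlap is measured in both the
#' exposed and the unexposed direction: with exposed sets `Ae`, `Be` and
#' unexposed sets `Au`, `Bu` within the cohort, the four fractions
#' `|Ae∩Be|/|Ae|`, `|Ae∩Be|/|Be|`, `|Au∩Bu|/|Au|`, `|Au∩Bu|/|Bu|` are
#' computed. Pairs whose maximal fraction strictly exceeds the threshold are
#' collapsed (transitively) to one representative treatment, which is the
#' first member found in `priority`, or otherwise the treatment with the
#' largest exposed arm (ties broken alphabetically). Only the
#' representatives enter the multiple-test correction.
#'
#' @param exposed_sets Named list of character vectors: exposed sample ids
#'   per treatment.
#' @param all_samples Character vector of all cohort sample ids (defines the
#'   unexposed complements).
#' @param overlap_threshold Collapse above this fraction, strictly
#'   (default 0.9).
#' @param priority Optional character vector of preferred representatives.
#' @return List with `kept` (representative treatment labels), `collapsed`
#'   (named character: dropped treatment -> representative) and `report`
#'   (data.frame of pairwise overlap fractions).
#' @export
dedup_overlapping_treatments <- function(exposed_sets, all_samples,
                                         overlap_threshold = 0.9,
                                         priority = NULL) {
  trts <- names(exposed_sets)
  if (length(trts) == 0L) stop("no treatments supplied", call. = FALSE)
  report <- NULL
  linked <- matrix(FALSE, length(trts), length(trts),
                   dimnames = list(trts, trts))
  if (length(trts) > 1L) {
    pairs <- utils::combn(trts, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1L, i]; b <- pairs[2L, i]
      ae <- exposed_sets[[a]]; be <- exposed_sets[[b]]
      au <- setdiff(all_samples, ae); bu <- setdiff(all_samples, be)
      ie <- length(intersect(ae, be)); iu <- length(intersect(au, bu))
      fr <- c(exposed_a = ie / length(ae), exposed_b = ie / length(be),
              unexposed_a = if (length(au)) iu / length(au) else 1,
              unexposed_b = if (length(bu)) iu / length(bu) else 1)
      data.frame(treatment_a = a, treatment_b = b,
                 overlap_exposed_a = fr[["exposed_a"]],
                 overlap_exposed_b = fr[["exposed_b"]],
                 overlap_unexposed_a = fr[["unexposed_a"]],
                 overlap_unexposed_b = fr[["unexposed_b"]],
                 collapsed = max(fr) > overlap_threshold,
                 stringsAsFactors = FALSE)
    })
    report <- do.call(rbind, rows)
    for (i in seq_len(nrow(report))) {
      if (report$collapsed[i]) {
        linked[report$treatment_a[i], report$treatment_b[i]] <- TRUE
        linked[report$treatment_b[i], report$treatment_a[i]] <- TRUE
      }
    }
  }
  # transitive closure into components
  comp <- seq_along(trts)
  repeat {
    changed <- FALSE
    for (i in seq_along(trts)) {
      for (j in seq_along(trts)) {
        if (linked[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[max(i, j)]] <- comp[min(i, j)]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  kept <- character(0)
  collapsed <- character(0)
  for (cc in unique(comp)) {
    members <- trts[comp == cc]
    rep_t <- pick_representative(members, exposed_sets, priority)
    kept <- c(kept, rep_t)
    for (m in setdiff(members, rep_t)) collapsed[m] <- rep_t
  }
  list(kept = sort(kept), collapsed = collapsed, report = report)
}

pick_representative <- function(members, exposed_sets, priority) {
  if (!is.null(priority)) {
    hit <- priority[priority %in% members]
    if (length(hit) > 0L) return(hit[1L])
  }
  sizes <- vapply(exposed_sets[members], length, integer(1))
  members[order(-sizes, members)][1L]
}

#' Exposure association screen over tumor types, treatments and CN categories
#'
#' For every tumor type and treatment, compares the per-sample counts of
#' each of the 48 CN categories between exposed and unexposed samples with a
#' two-sided rank test ([compare_groups()]). Samples are restricted to WGD
#' genomes when `config$wgd_only`; combinations with fewer than
#' `config$min_group_size` samples in either arm are skipped; treatments
#' whose exposure overlaps another treatment's by more than
#' `config$overlap_threshold` are collapsed to one representative per
#' overlap group ([dedup_overlapping_treatments()]); and q-values are
#' obtained by Benjamini-Hochberg correction across all retained tests
#' jointly.
#'
#' @param feature_matrix Samples x 48 count matrix
#'   ([build_feature_matrix()]).
#' @param profiles Per-sample profiles ([sample_profiles()]) with a `wgd`
#'   column.
#' @param clinical Clinical table ([read_clinical()]).
#' @param config A [screen_config()].
#' @return A `data.frame` of screen results (one row per tumor type x
#'   treatment x category) with columns `tumor_type`, `treatment`,
#'   `category`, `n_exposed`, `n_unexposed`, `median_exposed`,
#'   `median_unexposed`, `fold_change`, `direction`, `p_value`, `q_value`,
#'   plus attributes `skipped` (data.frame of skipped combinations with
#'   reasons) and `dedup` (pairwise overlap report).
#' @export
run_screen <- function(feature_matrix, profiles, clinical,
                       config = screen_config()) {
  samples <- rownames(feature_matrix)
  if (!all(samples %in% profiles$sample) ||
      !all(samples %in% clinical$sample)) {
    stop("profiles and clinical tables must cover all matrix samples",
         call. = FALSE)
  }
  profiles <- profiles[match(samples, profiles$sample), , drop = FALSE]
  clinical <- clinical[match(samples, clinical$sample), , drop = FALSE]
  if (config$wgd_only) {
    keep <- profiles$wgd
    feature_matrix <- feature_matrix[keep, , drop = FALSE]
    clinical <- clinical[keep, , drop = FALSE]
    samples <- samples[keep]
  }
  canon <- cn_category_space()$label
  skipped <- list()
  dedup_reports <- list()
  rows <- list()
  for (tt in sort(unique(clinical$tumor_type))) {
    in_tt <- clinical$tumor_type == tt
    cl_tt <- clinical[in_tt, , drop = FALSE]
    trts <- sort(unique(unlist(cl_tt$treatments)))
    if (length(trts) == 0L) next
    exposed_sets <- list()
    for (tr in trts) {
      ex <- cl_tt$sample[has_treatment(cl_tt$treatments, tr)]
      n_ex <- length(ex)
      n_un <- nrow(cl_tt) - n_ex
      if (n_ex < config$min_group_size || n_un < config$min_group_size) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          tumor_type = tt, treatment = tr,
          n_exposed = n_ex, n_unexposed = n_un,
          reason = "arm below min_group_size", stringsAsFactors = FALSE)
      } else {
        exposed_sets[[tr]] <- ex
      }
    }
    if (length(exposed_sets) == 0L) next
    dd <- dedup_overlapping_treatments(exposed_sets, cl_tt$sample,
                                       config$overlap_threshold,
                                       config$priority)
    if (!is.null(dd$report)) {
      dd$report <- cbind(tumor_type = tt, dd$report,
                         stringsAsFactors = FALSE)
      dedup_reports[[length(dedup_reports) + 1L]] <- dd$report
    }
    for (dropped in names(dd$collapsed)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        tumor_type = tt, treatment = dropped,
        n_exposed = length(exposed_sets[[dropped]]),
        n_unexposed = nrow(cl_tt) - length(exposed_sets[[dropped]]),
        reason = paste0("collapsed into ", dd$collapsed[[dropped]]),
        stringsAsFactors = FALSE)
    }
    for (tr in dd$kept) {
      ex_idx <- match(exposed_sets[[tr]], samples)
      un_idx <- match(setdiff(cl_tt$sample, exposed_sets[[tr]]), samples)
      for (cat in canon) {
        cmp <- compare_groups(feature_matrix[ex_idx, cat],
                              feature_matrix[un_idx, cat],
                              config$exact_max_n)
        rows[[length(rows) + 1L]] <- data.frame(
          tumor_type = tt, treatment = tr, category = cat,
          n_exposed = length(ex_idx), n_unexposed = length(un_idx),
          median_exposed = cmp$median_exposed,
          median_unexposed = cmp$median_unexposed,
          fold_change = cmp$fold_change, direction = cmp$direction,
          p_value = cmp$p_value, stringsAsFactors = FALSE)
      }
    }
  }
  skipped_df <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(tumor_type = character(0), treatment = character(0),
               n_exposed = integer(0), n_unexposed = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("no tumor type / treatment combination retained", call. = FALSE)
    out <- data.frame()
  } else {
    out <- do.call(rbind, rows)
    out$q_value <- fdr_correct(out$p_value)
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped_df
  attr(out, "dedup") <- if (length(dedup_reports)) {
    do.call(rbind, dedup_reports)
  } else {
    NULL
  }
  out
}

#' Re-test an association on exclusively exposed samples
#'
#' Guards an association of treatment A against confounding by a
#' co-administered treatment B: the category counts of samples exposed to A
#' but not B are compared against samples exposed to neither A nor B. Group
#' sizes are reported so under-powered re-tests can be flagged.
#'
#' @param feature_matrix Samples x 48 count matrix.
#' @param clinical Clinical table covering the matrix samples.
#' @param treatment_a,treatment_b Treatment labels.
#' @param category Canonical category label to test.
#' @param profiles Optional [sample_profiles()]; with `wgd_only = TRUE`
#'   restricts to WGD samples.
#' @param wgd_only Restrict to WGD samples when profiles are given.
#' @param exact_max_n Exact-null size limit for the rank test.
#' @return List with `p_exclusive`, `n_exclusive_exposed`,
#'   `n_clean_unexposed`, `fold_change`, `direction`.
#' @export
exclusive_exposure_retest <- function(feature_matrix, clinical, treatment_a,
                                      treatment_b, category,
                                      profiles = NULL, wgd_only = TRUE,
                                      exact_max_n = 25) {
  samples <- rownames(feature_matrix)
  clinical <- clinical[match(samples, clinical$sample), , drop = FALSE]
  keep <- rep(TRUE, length(samples))
  if (!is.null(profiles) && wgd_only) {
    keep <- profiles$wgd[match(samples, profiles$sample)]
  }
  has_a <- has_treatment(clinical$treatments, treatment_a)
  has_b <- has_treatment(clinical$treatments, treatment_b)
  excl <- keep & has_a & !has_b
  clean <- keep & !has_a & !has_b
  if (!any(excl)) {
    stop(sprintf("no sample exposed to %s but not %s",
                 treatment_a, treatment_b), call. = FALSE)
  }
  if (!any(clean)) {
    stop(sprintf("no sample unexposed to both %s and %s",
                 treatment_a, treatment_b), call. = FALSE)
  }
  cmp <- compare_groups(feature_matrix[excl, category],
                        feature_matrix[clean, category], exact_max_n)
  list(p_exclusive = cmp$p_value,
       n_exclusive_exposed = sum(excl),
       n_clean_unexposed = sum(clean),
       fold_change = cmp$fold_change,
       direction = cmp$direction)
}

#' Stratified covariate re-test of an association
#'
#' Guards an association against a categorical clinical covariate (e.g.
#' sex): the exposed/unexposed comparison is repeated within each covariate
#' stratum, and the association is considered replicated when every stratum
#' with both arms non-empty shows the same direction.
#'
#' @param feature_matrix Samples x 48 count matrix.
#' @param clinical Clinical table with the covariate column.
#' @param treatment Treatment label.
#' @param category Canonical category label.
#' @param covariate Name of a categorical column of `clinical`.
#' @param profiles Optional [sample_profiles()] for WGD restriction.
#' @param wgd_only Restrict to WGD samples when profiles are given.
#' @param exact_max_n Exact-null size limit for the rank test.
#' @return List with `strata` (data.frame: stratum, n_exposed, n_unexposed,
#'   p_value, direction) and `replicated` (logical).
#' @export
stratified_retest <- function(feature_matrix, clinical, treatment, category,
                              covariate, profiles = NULL, wgd_only = TRUE,
                              exact_max_n = 25) {
  if (!covariate %in% names(clinical)) {
    stop("covariate column not found: ", covariate, call. = FALSE)
  }
  samples <- rownames(feature_matrix)
  clinical <- clinical[match(samples, clinical$sample), , drop = FALSE]
  keep <- rep(TRUE, length(samples))
  if (!is.null(profiles) && wgd_only) {
    keep <- profiles$wgd[match(samples, profiles$sample)]
  }
  has_t <- has_treatment(clinical$treatments, treatment)
  strata <- sort(unique(clinical[[covariate]][keep]))
  rows <- lapply(strata, function(s) {
    in_s <- keep & clinical[[covariate]] == s
    ex <- in_s & has_t
    un <- in_s & !has_t
    if (!any(ex) || !any(un)) {
      return(data.frame(stratum = s, n_exposed = sum(ex),
                        n_unexposed = sum(un), p_value = NA_real_,
                        direction = NA_character_, stringsAsFactors = FALSE))
    }
    cmp <- compare_groups(feature_matrix[ex, category],
                          feature_matrix[un, category], exact_max_n)
    data.frame(stratum = s, n_exposed = sum(ex), n_unexposed = sum(un),
               p_value = cmp$p_value, direction = cmp$direction,
               stringsAsFactors = FALSE)
  })
  strata_df <- do.call(rbind, rows)
  dirs <- strata_df$direction[!is.na(strata_df$direction)]
  list(strata = strata_df,
       replicated = length(dirs) > 0L && length(unique(dirs)) == 1L)
}
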