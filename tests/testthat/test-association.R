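test_that("compare_groups reproduces hand-enumerated and degenerate cases", {
  # full enumeration of C(6,3)=20 assignments: 1/20 one-sided, doubled
  cmp <- compare_groups(c(5, 6, 7), c(1, 2, 3))
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$direction, "up")

  same <- compare_groups(c(2, 3, 3, 5), c(3, 5, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$fold_change, 1)

  zero <- compare_groups(c(4, 4, 4, 4), c(0, 0, 0, 0))
  expect_equal(zero$fold_change, Inf)
  expect_equal(zero$direction, "up")

  both0 <- compare_groups(c(0, 0, 0), c(0, 0, 0))
  expect_equal(both0$fold_change, 1)
  expect_equal(both0$p_value, 1)

  down <- compare_groups(c(1, 1, 2), c(5, 6, 7))
  expect_equal(down$direction, "down")
  expect_equal(down$fold_change, 1 / 6)

  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("the exact null matches full enumeration for all sizes up to 12", {
  set.seed(101)
  for (n1 in 1:6) {
    for (n2 in n1:(12 - n1)) {
      for (rep in 1:3) {
        x <- rpois(n1, 3)  # heavy ties on purpose
        y <- rpois(n2, 4)
        expect_equal(compare_groups(x, y)$p_value, enum_rank_p(x, y),
                     info = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
      }
    }
  }
})

test_that("the exact path agrees with wilcox.test on tie-free data", {
  set.seed(7)
  for (rep in 1:20) {
    x <- sample(1:100, 8)
    y <- setdiff(sample(1:100, 20), x)[1:7]
    expect_equal(compare_groups(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("the large-sample path matches the tie-corrected approximation", {
  set.seed(8)
  x <- rpois(30, 5)
  y <- rpois(35, 6)
  expect_equal(compare_groups(x, y)$p_value,
               suppressWarnings(wilcox.test(x, y, correct = TRUE))$p.value)
})

test_that("BH correction matches the hand check and is monotone", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(0.03), 0.03)
  expect_error(fdr_correct(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fdr_correct(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(13)
  for (rep in 1:1000) {
    p <- runif(sample(2:30, 1))
    q <- fdr_correct(p)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= p - 1e-12))
  }
})

test_that("heavily overlapping treatments collapse to one representative", {
  samples <- sprintf("S%03d", 1:200)
  b <- samples[1:100]
  a <- c(samples[1:97], samples[101:103])  # |A∩B|/|A| = 0.97
  dd <- dedup_overlapping_treatments(list(a = a, b = b), samples)
  expect_equal(dd$kept, "a")  # equal sizes, alphabetical tie-break
  expect_equal(unname(dd$collapsed["b"]), "a")
  expect_true(dd$report$collapsed)

  # priority list overrides the size rule (mirrors manual curation)
  dd2 <- dedup_overlapping_treatments(list(a = a, b = b), samples,
                                      priority = "b")
  expect_equal(dd2$kept, "b")

  # disjoint exposures are both retained
  dd3 <- dedup_overlapping_treatments(
    list(a = samples[1:50], b = samples[51:100]), samples)
  expect_equal(dd3$kept, c("a", "b"))

  # the rule is strictly "more than": exactly 90% overlap keeps both
  a4 <- samples[1:100]
  b4 <- c(samples[1:90], samples[101:110])
  ov <- dedup_overlapping_treatments(list(a = a4, b = b4), samples[1:200])
  expect_equal(max(ov$report$overlap_exposed_a,
                   ov$report$overlap_exposed_b), 0.9)
  # unexposed direction: |Au∩Bu|/|Au| = 90/100 = 0.9 as well
  expect_equal(ov$kept, c("a", "b"))
})

test_that("run_screen filters small arms and is order-invariant", {
  set.seed(23)
  n <- 50
  ids <- sprintf("S%02d", 1:n)
  canon <- cn_category_space()$label
  mat <- matrix(rpois(n * 48, 3), nrow = n, dimnames = list(ids, canon))
  profiles <- data.frame(sample = ids, ploidy = 3.2, loh_fraction = 0.2,
                         wgd = TRUE)
  # "rare" has 19 exposed: below the 20-sample arm minimum
  clinical <- make_clinical(ids, "colorectal",
                            c(lapply(1:19, function(i) c("platinum", "rare")),
                              lapply(20:25, function(i) "platinum"),
                              lapply(26:n, function(i) character(0))))
  res <- run_screen(mat, profiles, clinical, screen_config())
  skipped <- attr(res, "skipped")
  expect_true("rare" %in% skipped$treatment)
  expect_match(skipped$reason[skipped$treatment == "rare"], "min_group_size")
  expect_equal(unique(res$treatment), "platinum")
  expect_equal(nrow(res), 48L)
  expect_equal(res$n_exposed[1], 25L)
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  # permuting sample order changes nothing
  perm <- sample(n)
  res2 <- run_screen(mat[perm, ], profiles[perm, ], clinical[perm, ],
                     screen_config())
  expect_equal(res2, res, ignore_attr = TRUE)
})

test_that("run_screen restricts to WGD samples when configured", {
  set.seed(29)
  n <- 60
  ids <- sprintf("S%02d", 1:n)
  canon <- cn_category_space()$label
  mat <- matrix(rpois(n * 48, 3), nrow = n, dimnames = list(ids, canon))
  wgd <- rep(c(TRUE, FALSE), each = 30)
  profiles <- data.frame(sample = ids, ploidy = ifelse(wgd, 3.2, 2),
                         loh_fraction = 0.1, wgd = wgd)
  clinical <- make_clinical(ids, "lung",
                            lapply(seq_len(n), function(i) {
                              if (i %% 2 == 0) "platinum" else character(0)
                            }))
  # only 15 exposed / 15 unexposed WGD samples: all skipped at default 20
  expect_warning(
    res <- run_screen(mat, profiles, clinical, screen_config()),
    "no tumor type")
  expect_equal(nrow(res), 0L)
  # with wgd_only off the arms are 30/30 and the screen runs
  res2 <- run_screen(mat, profiles, clinical,
                     screen_config(wgd_only = FALSE))
  expect_equal(nrow(res2), 48L)
  expect_equal(res2$n_exposed[1], 30L)
})

test_that("exclusive exposure re-test isolates a treatment's own signal", {
  set.seed(41)
  n <- 40
  ids <- sprintf("S%02d", 1:n)
  canon <- cn_category_space()$label
  mat <- matrix(rpois(n * 48, 3), nrow = n, dimnames = list(ids, canon))
  # nobody exposed to b: the exclusive re-test equals the plain comparison
  clinical <- make_clinical(ids, "colorectal",
                            lapply(seq_len(n), function(i) {
                              if (i <= 15) "a" else character(0)
                            }))
  r <- exclusive_exposure_retest(mat, clinical, "a", "b", canon[20])
  plain <- compare_groups(mat[1:15, canon[20]], mat[16:n, canon[20]])
  expect_equal(r$p_exclusive, plain$p_value)
  expect_equal(r$n_exclusive_exposed, 15)
  expect_equal(r$n_clean_unexposed, 25)

  # every a-exposed sample also b-exposed: empty exclusive set is an error
  cl2 <- make_clinical(ids, "colorectal",
                       lapply(seq_len(n), function(i) {
                         if (i <= 15) c("a", "b") else character(0)
                       }))
  expect_error(exclusive_exposure_retest(mat, cl2, "a", "b", canon[20]),
               "no sample exposed to a but not b")
})

test_that("stratified re-test reports per-stratum direction agreement", {
  set.seed(43)
  n <- 60
  ids <- sprintf("S%02d", 1:n)
  canon <- cn_category_space()$label
  mat <- matrix(rpois(n * 48, 3), nrow = n, dimnames = list(ids, canon))
  exposed <- seq_len(n) <= 30
  mat[exposed, canon[10]] <- mat[exposed, canon[10]] + 5L
  clinical <- make_clinical(ids, "lung",
                            lapply(exposed, function(e) {
                              if (e) "platinum" else character(0)
                            }),
                            sex = rep(c("F", "M"), n / 2))
  r <- stratified_retest(mat, clinical, "platinum", canon[10], "sex")
  expect_equal(nrow(r$strata), 2L)
  expect_true(r$replicated)
  expect_true(all(r$strata$direction == "up"))
  expect_error(stratified_retest(mat, clinical, "platinum", canon[10],
                                 "age"), "covariate")
})
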