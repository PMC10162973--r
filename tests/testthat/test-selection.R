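test_that("the signed-rank test matches closed-form and degenerate cases", {
  x <- c(1.2, 0.8, 1.5, 0.3, 2.2)
  expect_equal(wilcoxon_signed_rank(x, x)$p.value, 1)
  # five equal positive differences: two-sided exact p = 2/32
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(w$p.value, 0.0625)
  expect_true(w$exact)
  # no-ties exact branch agrees with the classic distribution
  set.seed(31)
  d15 <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(d15)$p.value,
               suppressWarnings(stats::wilcox.test(d15, exact = TRUE))$p.value)
  # n = 23 unique differences use the exact branch
  set.seed(1)
  w23 <- wilcoxon_signed_rank(rnorm(23), rnorm(23))
  expect_identical(w23$n_used, 23L)
  expect_true(w23$exact)
  # tied absolute differences keep the exact (enumeration) distribution
  wt <- wilcoxon_signed_rank(c(1, 1, 2, 2, 3, 3) + 10, rep(10, 6))
  expect_true(wt$exact)
  expect_equal(wt$p.value,
               enumerate_signed_rank(c(1, 1, 2, 2, 3, 3)), tolerance = 1e-12)
  # beyond 25 pairs the normal approximation takes over
  set.seed(2)
  expect_false(wilcoxon_signed_rank(rnorm(30))$exact)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("exact p-values agree with exhaustive sign enumeration", {
  set.seed(7)
  for (case in 1:150) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n), 3)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    alt <- sample(c("two.sided", "greater"), 1)
    expect_equal(wilcoxon_signed_rank(d, rep(0, length(d)),
                                      alternative = alt)$p.value,
                 enumerate_signed_rank(d, alt), tolerance = 1e-12,
                 info = paste("case", case))
  }
})

test_that("the Pratt variant handles zeros and approximates the classic test", {
  set.seed(3)
  d <- rnorm(30)
  p_w <- wilcoxon_signed_rank(d, zero_method = "wilcox")$p.value
  p_p <- wilcoxon_signed_rank(d, zero_method = "pratt")$p.value
  expect_lt(abs(p_w - p_p), 0.05)
  dz <- c(d[1:20], rep(0, 10))
  wz <- wilcoxon_signed_rank(dz, zero_method = "pratt")
  expect_identical(wz$n_used, 20L)
  expect_true(wz$p.value >= 0 && wz$p.value <= 1)
})

make_null_rs <- function(seed, folds = 23, rois = 68) {
  set.seed(seed)
  RS <- matrix(rnorm(folds * rois), folds, rois)
  colnames(RS) <- paste0("roi", seq_len(rois))
  RS
}

test_that("criterion 1 selects ROIs above the fold average", {
  RS <- matrix(5, 23, 68, dimnames = list(NULL, paste0("roi", 1:68)))
  same <- criterion_above_average(RS)
  expect_length(same$selected, 0L)
  expect_identical(same$n_tests, 68L)
  RS2 <- make_null_rs(1) * 0.01
  RS2[, 7] <- rowMeans(RS2) + 10
  sel <- criterion_above_average(RS2)
  expect_identical(sel$selected, "roi7")
  expect_error(criterion_above_average(RS2[1:4, ]), "folds")
})

test_that("criterion 1 selection is monotone in the ROI scores", {
  for (seed in 1:5) {
    RS <- make_null_rs(seed)
    RS[, 3] <- RS[, 3] + 8
    before <- criterion_above_average(RS)$selected
    RS[, 3] <- RS[, 3] + 5
    after <- criterion_above_average(RS)$selected
    expect_true(!("roi3" %in% before) || "roi3" %in% after)
    expect_true("roi3" %in% after)
  }
})

test_that("criterion 2 keeps the maximum ROI and its statistical peers", {
  RS <- matrix(rep(c(1, 2), 23 * 34), 23, 68, byrow = TRUE,
               dimnames = list(NULL, paste0("roi", 1:68)))
  RS[] <- 1                                       # all identical
  all_sel <- criterion_comparable_to_max(RS)
  expect_length(all_sel$selected, 68L)
  expect_identical(all_sel$n_tests, 67L)
  RS2 <- make_null_rs(2) * 0.01
  RS2[, 12] <- RS2[, 12] + 10
  dom <- criterion_comparable_to_max(RS2)
  expect_identical(dom$max_roi, "roi12")
  expect_identical(dom$selected, "roi12")
})

test_that("criterion 3 flags ROIs that differ from the control stimulus", {
  RS <- make_null_rs(4)
  same <- criterion_social_vs_control(RS, RS)
  expect_length(same$selected, 0L)
  expect_identical(same$n_tests, 68L)
  RSs <- RS
  RSs[, 30] <- RSs[, 30] + 10
  shifted <- criterion_social_vs_control(RSs, RS)
  expect_identical(shifted$selected, "roi30")
  expect_error(criterion_social_vs_control(RS, RS[, 1:10]), "shape")
})

test_that("the three-criterion intersection recovers a designed ROI set", {
  # control table: background noise; social table: six ROIs carry a large,
  # consistent relevance increase and tie with each other
  set.seed(11)
  RS_c <- make_null_rs(12) * 0.05
  RS_s <- RS_c
  six <- c(5, 12, 23, 40, 41, 60)
  RS_s[, six] <- RS_s[, six] + 10 +
    matrix(rnorm(23 * 6, sd = 0.05), 23, 6)
  res <- select_relevant_rois(RS_s, RS_c)
  expect_setequal(res$selected, paste0("roi", six))
  expect_true(all(res$summary$selected == res$summary$roi %in% res$selected))
  # null tables select nothing
  null_res <- select_relevant_rois(make_null_rs(13), make_null_rs(14))
  expect_length(null_res$selected, 0L)
})

test_that("selection recovers injected effect ROIs on 12-subject cohorts", {
  # 12 folds are the smallest count at which the exact signed-rank p-value
  # (2^-12) can clear the Bonferroni-corrected threshold 0.05 / 68
  effect_rois <- c("lateraloccipital_rh", "superiorparietal_rh")
  recovered <- logical(0)
  for (cid in 1:2) {
    red <- reduce_cohort(generate_cohort(
      12, 16, effects = default_effect_specs()[c("face", "house")],
      seed = 7100 + cid))
    rs <- list()
    for (stim in c("face", "house")) {
      ds <- lapply(red[[stim]], `[[`, "decoder")
      pr <- run_loso_protocol(ds, n_seeds = 2)
      maps <- lapply(seq_along(pr$models), function(s) {
        std_test <- list(
          X = apply_scaler(pr$test_sets[[s]]$X, pr$scalers[[s]]),
          y = pr$test_sets[[s]]$y)
        fold_relevance_map(pr$models[[s]], std_test)
      })
      rs[[stim]] <- relevance_scores(maps)
    }
    sel <- select_relevant_rois(rs$face, rs$house)
    recovered <- c(recovered, all(effect_rois %in% sel$selected))
  }
  expect_true(all(recovered))
})
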