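#' Paired Wilcoxon signed-rank test
#'
#' Classic signed-rank handling: zero differences are discarded and tied
#' absolute differences receive averaged ranks. With at most 25 non-zero
#' differences the exact null distribution of the rank sum is used (computed
#' by convolution over the -- possibly tied -- ranks, so it equals
#' exhaustive sign enumeration even in the presence of ties); larger samples
#' use the normal approximation with continuity correction. The Pratt
#' variant (zeros kept in the ranking, then dropped from the statistic;
#' always normal approximation) is available via `zero_method`.
#'
#' @param x,y Paired numeric vectors of equal length (>= 5 recommended).
#' @param alternative `"two.sided"` or `"greater"` (x tends larger than y).
#' @param zero_method `"wilcox"` (discard zeros) or `"pratt"`.
#' @return List with `statistic` (V, sum of positive ranks), `p.value`,
#'   `n_used` (non-zero pairs), `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater"),
                                 zero_method = c("wilcox", "pratt")) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  if (is.null(y)) y <- rep(0, length(x))
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  d <- x - y
  if (zero_method == "pratt") return(wilcoxon_pratt(d, alternative))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p.value = 1, n_used = 0L, exact = TRUE))
  if (n <= 25L) {
    r <- rank(abs(d))
    V <- sum(r[d > 0])
    p <- exact_signed_rank_p(r, V, alternative)
    return(list(statistic = V, p.value = p, n_used = n, exact = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = alternative, exact = FALSE, correct = TRUE
  ))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_used = n, exact = FALSE)
}

# Exact null distribution of the signed-rank sum for arbitrary (tied,
# averaged) ranks: convolution of the generating function over the 2^n
# equiprobable sign assignments. Ranks are doubled so half-ranks become
# integers; counts stay exact in doubles for n <= 25.
exact_signed_rank_p <- function(r, V, alternative) {
  w <- as.integer(round(2 * r))
  counts <- 1
  for (wi in w) counts <- c(counts, numeric(wi)) + c(numeric(wi), counts)
  total <- 2^length(w)
  v2 <- as.integer(round(2 * V))
  sums <- seq_along(counts) - 1L
  p_ge <- sum(counts[sums >= v2]) / total
  if (alternative == "greater") return(min(1, p_ge))
  p_le <- sum(counts[sums <= v2]) / total
  min(1, 2 * min(p_le, p_ge))
}

# Pratt zero handling: rank |d| with zeros included, drop the zero ranks
# from the statistic, normal approximation with tie and zero corrections.
wilcoxon_pratt <- function(d, alternative) {
  n <- length(d)
  r <- rank(abs(d))
  nz <- d != 0
  if (!any(nz)) return(list(statistic = 0, p.value = 1, n_used = 0L,
                            exact = FALSE))
  V <- sum(r[nz & d > 0])
  n0 <- sum(!nz)
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  tie_tab <- table(r[nz])
  tie_corr <- sum(tie_tab^3 - tie_tab) / 48
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    n0 * (n0 + 1) * (2 * n0 + 1) / 24 - tie_corr
  z <- (V - mu) / sqrt(sigma2)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE))
  list(statistic = V, p.value = min(1, p), n_used = sum(nz), exact = FALSE)
}

check_rs_table <- function(RS, min_folds = 5L) {
  if (!is.matrix(RS) || ncol(RS) < 2L)
    stop("relevance-score table must be a folds x ROIs matrix", call. = FALSE)
  if (nrow(RS) < min_folds)
    stop("fewer than ", min_folds, " folds: insufficient data", call. = FALSE)
  invisible(RS)
}

#' Criterion 1: relevance above the across-ROI average
#'
#' For every fold the average relevance score across all ROIs (including
#' the ROI under test) is computed; each ROI's per-fold scores are then
#' compared to these per-fold averages with a one-sided (greater) paired
#' signed-rank test, Bonferroni-corrected by the number of ROIs.
#'
#' @param RS Folds x ROIs relevance-score matrix (named columns).
#' @param alpha Family-wise significance level.
#' @return List with `selected` (ROI names), `p` (raw), `p_adj`, `n_tests`.
#' @export
criterion_above_average <- function(RS, alpha = 0.05) {
  check_rs_table(RS)
  fold_avg <- rowMeans(RS)
  p <- apply(RS, 2L, function(col)
    wilcoxon_signed_rank(col, fold_avg, alternative = "greater")$p.value)
  p_adj <- pmin(1, p * ncol(RS))
  list(selected = colnames(RS)[p_adj < alpha], p = p, p_adj = p_adj,
       n_tests = ncol(RS))
}

#' Criterion 2: relevance comparable to the maximally relevant ROI
#'
#' The ROI with the largest fold-mean relevance is identified; every other
#' ROI is compared to it with a two-sided paired signed-rank test,
#' Bonferroni-corrected by the number of comparisons (ROIs - 1). The
#' criterion keeps the maximum ROI together with all ROIs *not*
#' significantly different from it.
#'
#' @inheritParams criterion_above_average
#' @return List with `selected`, `max_roi`, `p`, `p_adj`, `n_tests`.
#' @export
criterion_comparable_to_max <- function(RS, alpha = 0.05) {
  check_rs_table(RS)
  j_max <- which.max(colMeans(RS))
  others <- setdiff(seq_len(ncol(RS)), j_max)
  p <- vapply(others, function(j)
    wilcoxon_signed_rank(RS[, j], RS[, j_max],
                         alternative = "two.sided")$p.value, numeric(1))
  p_adj <- pmin(1, p * length(others))
  keep <- others[p_adj >= alpha]
  sel <- colnames(RS)[sort(c(j_max, keep))]
  p_full <- rep(NA_real_, ncol(RS)); p_full[others] <- p
  p_adj_full <- rep(NA_real_, ncol(RS)); p_adj_full[others] <- p_adj
  names(p_full) <- names(p_adj_full) <- colnames(RS)
  list(selected = sel, max_roi = colnames(RS)[j_max], p = p_full,
       p_adj = p_adj_full, n_tests = length(others))
}

#' Criterion 3: social relevance different from the control stimulus
#'
#' Per ROI, a two-sided paired signed-rank test compares the relevance
#' scores under the social stimulus with those under the non-social control
#' (houses), Bonferroni-corrected by the number of ROIs.
#'
#' @param RS_social,RS_control Folds x ROIs matrices with matching
#'   dimensions and column order.
#' @param alpha Family-wise significance level.
#' @return List with `selected`, `p`, `p_adj`, `n_tests`.
#' @export
criterion_social_vs_control <- function(RS_social, RS_control, alpha = 0.05) {
  check_rs_table(RS_social)
  if (!identical(dim(RS_social), dim(RS_control)))
    stop("social and control tables must have matching shape", call. = FALSE)
  p <- vapply(seq_len(ncol(RS_social)), function(j)
    wilcoxon_signed_rank(RS_social[, j], RS_control[, j],
                         alternative = "two.sided")$p.value, numeric(1))
  names(p) <- colnames(RS_social)
  p_adj <- pmin(1, p * ncol(RS_social))
  list(selected = colnames(RS_social)[p_adj < alpha], p = p, p_adj = p_adj,
       n_tests = ncol(RS_social))
}

#' Select the ROIs most discriminant of stimulus inversion
#'
#' Intersects the three selection criteria: relevance above the across-ROI
#' average, relevance comparable to the maximally relevant ROI, and
#' relevance different from the control stimulus.
#'
#' @inheritParams criterion_social_vs_control
#' @return A `selection_result`: list with the per-criterion results, the
#'   final `selected` set (intersection), and a summary data frame (one row
#'   per ROI: fold-mean score, corrected p per criterion, flags).
#' @export
select_relevant_rois <- function(RS_social, RS_control, alpha = 0.05) {
  c1 <- criterion_above_average(RS_social, alpha)
  c2 <- criterion_comparable_to_max(RS_social, alpha)
  c3 <- criterion_social_vs_control(RS_social, RS_control, alpha)
  selected <- Reduce(intersect, list(c1$selected, c2$selected, c3$selected))
  rois <- colnames(RS_social)
  summary <- data.frame(
    roi = rois,
    mean_score = colMeans(RS_social),
    p_adj_above_average = c1$p_adj,
    p_adj_vs_max = c2$p_adj,
    p_adj_vs_control = c3$p_adj,
    criterion1 = rois %in% c1$selected,
    criterion2 = rois %in% c2$selected,
    criterion3 = rois %in% c3$selected,
    selected = rois %in% selected,
    row.names = NULL
  )
  structure(list(criterion1 = c1, criterion2 = c2, criterion3 = c3,
                 selected = selected, summary = summary),
            class = "selection_result")
}
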