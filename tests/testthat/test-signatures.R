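test_that("ERPs are trial means and linear in the trials", {
  set.seed(1)
  X <- array(rnorm(4 * 3 * 50), c(4, 3, 50))
  y <- c("upright", "upright", "inverted", "inverted")
  # identical trials: ERP equals the trial
  Xi <- X
  Xi[2, , ] <- Xi[1, , ]
  Xi[4, , ] <- Xi[3, , ]
  erp <- compute_erp(Xi, y)
  expect_equal(erp$upright, Xi[1, , ])
  # a trial and its negation cancel
  Xn <- X
  Xn[2, , ] <- -Xn[1, , ]
  expect_true(all(abs(compute_erp(Xn, y)$upright) < 1e-12))
  # linearity
  expect_equal(compute_erp(3 * X, y)$inverted, 3 * compute_erp(X, y)$inverted)
  expect_error(compute_erp(X, rep("upright", 4)), "no trials")
})

test_that("ERD/S baselines are zeroed and scale with power ratios", {
  fs <- 200
  t <- seq(-0.5, 0.5 - 1 / fs, by = 1 / fs)
  set.seed(2)
  x <- rnorm(length(t))
  m <- erds_map(x, fs, t0 = -0.5)
  bidx <- which(m$times < 0)
  expect_true(all(abs(rowMeans(m$power[, bidx])) < 1e-9))
  # amplitude doubling at f0 after onset: ERD/S -> (4B - B) / B = 3
  f0 <- 10
  amp <- ifelse(t < 0, 1, 2)
  xs <- amp * sin(2 * pi * f0 * t) + 0.01 * rnorm(length(t))
  ms <- erds_map(xs, fs, t0 = -0.5, freqs = 4:20)
  val <- ms$power[ms$freqs == f0, which.min(abs(ms$times - 0.3))]
  expect_lt(abs(val - 3), 0.5)
})

test_that("stationary noise produces near-zero average ERD/S", {
  fs <- 200
  set.seed(3)
  trials <- matrix(rnorm(500 * 200), 500, 200)
  m <- erds_average(trials, fs, t0 = -0.5)
  valid <- invcnn:::coi_mask(m$freqs, m$times, fs)
  post <- matrix(rep(m$times >= 0, each = length(m$freqs)),
                 length(m$freqs)) & valid
  # no systematic deviation from stationarity, and every point within the
  # Monte-Carlo fluctuation of 500 averaged power estimates
  expect_lt(abs(mean(m$power[post])), 0.05)
  expect_lt(max(abs(m$power[valid])), 0.2)
})

test_that("the generator's theta power gain appears in the ERD/S contrast", {
  spec <- effect_spec("lateraloccipital_rh")
  mean_band <- function(cond) {
    acc <- 0
    for (s in 1:30) {
      x <- generate_roi_trial(cond, spec, seed = 400 + s)
      ep <- x$X["lateraloccipital_rh", 101:300]   # [-0.5, 0.5)
      m <- erds_map(ep, 200, t0 = -0.5, freqs = 4:12)
      sel <- m$freqs %in% 4:6
      tsel <- m$times >= 0.1 & m$times <= 0.4
      acc <- acc + mean(m$power[sel, tsel])
    }
    acc / 30
  }
  expect_gt(mean_band("inverted"), mean_band("upright"))
})

test_that("time-domain cluster tests find injected effects and not null ones", {
  set.seed(5)
  n <- 12; T <- 100
  a <- matrix(rnorm(n * T, sd = 0.3), n, T)
  b <- matrix(rnorm(n * T, sd = 0.3), n, T)
  null_res <- cluster_test_time(a, a, n_perm = 500, seed = 1)
  expect_false(any(null_res$sig))
  b2 <- b
  b2[, 31:50] <- b2[, 31:50] + 1
  res <- cluster_test_time(b2, b, n_perm = 2000, seed = 2)
  expect_true(any(res$sig))
  covered <- unlist(res$clusters[res$sig])
  expect_gte(length(intersect(covered, 31:50)) / 20, 0.8)
  expect_length(res$null, 2000L)
  expect_error(cluster_test_time(a[1:4, ], b[1:4, ]), "subjects")
})

test_that("relabelling conditions flips the t map but not cluster p-values", {
  set.seed(6)
  a <- matrix(rnorm(8 * 60), 8, 60) + 0.8
  b <- matrix(rnorm(8 * 60), 8, 60)
  r1 <- cluster_test_time(a, b, n_perm = 500, seed = 9)
  r2 <- cluster_test_time(b, a, n_perm = 500, seed = 9)
  expect_equal(r1$t, -r2$t)
  expect_equal(sort(r1$p), sort(r2$p))
})

test_that("4-neighbour labelling matches a brute-force flood fill", {
  flood <- function(mask) {
    lab <- matrix(0L, nrow(mask), ncol(mask))
    cur <- 0L
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || lab[i, j] > 0L) next
      cur <- cur + 1L
      queue <- list(c(i, j))
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask))
          next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] > 0L) next
        lab[p[1], p[2]] <- cur
        queue <- c(queue, list(p + c(1, 0), p - c(1, 0),
                               p + c(0, 1), p - c(0, 1)))
      }
    }
    lab
  }
  set.seed(7)
  for (rep in 1:20) {
    mask <- matrix(runif(15 * 12) < 0.4, 15, 12)
    got <- invcnn:::label_components_4(mask)
    want <- flood(mask)
    # same partition up to label permutation
    expect_identical(got > 0L, want > 0L)
    key <- paste(got[mask], want[mask])
    expect_identical(length(unique(key)), length(unique(got[mask])))
    expect_identical(max(got), max(want))
  }
})

test_that("time-frequency cluster tests localize a theta synchronization", {
  set.seed(8)
  n <- 10; nf <- 20; nt <- 50
  a <- array(rnorm(n * nf * nt, sd = 0.5), c(n, nf, nt))
  same <- cluster_test_timefreq(a, a, n_perm = 300, seed = 3)
  expect_false(any(same$sig))
  expect_length(same$null, 300L)
  b <- array(rnorm(n * nf * nt, sd = 0.5), c(n, nf, nt))
  b2 <- b
  b2[, 2:4, 10:30] <- b2[, 2:4, 10:30] + 1.2      # rows 2:4 ~ theta band
  res <- cluster_test_timefreq(b2, b, n_perm = 1000, seed = 4)
  expect_true(any(res$sig))
  hit <- Reduce(`|`, res$clusters[res$sig])
  expect_gt(sum(hit[2:4, 10:30]), 0)
  expect_gt(sum(res$t_map[2:4, 10:30] > 0), 0.8 * 3 * 21)
})
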