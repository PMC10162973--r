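test_that("resampling and cropping produce the canonical epoch shapes", {
  x <- matrix(rnorm(3 * 2000), 3, 2000)          # [-1, 1) at 1000 Hz
  out <- resample_and_crop(x, 1000, 200, window = c(-0.5, 0.5), t0 = -1)
  expect_equal(ncol(out), 200L)
  expect_equal(attr(out, "t0"), -0.5)
  post <- resample_and_crop(x, 1000, 200, window = c(0, 0.5), t0 = -1)
  expect_equal(ncol(post), 100L)
  expect_equal(attr(post, "t0"), 0)
  # identity: already at target rate, full-span crop
  y <- matrix(rnorm(2 * 400), 2, 400)
  out2 <- resample_and_crop(y, 200, 200, window = c(-1, 1), t0 = -1)
  expect_equal(unname(out2), y, ignore_attr = TRUE)
  expect_error(resample_and_crop(y, 200, 200, window = c(-2, 1), t0 = -1),
               "span")
})

test_that("resampling preserves in-band sinusoids", {
  t1k <- seq(0, by = 1e-3, length.out = 2000)
  x <- sin(2 * pi * 10 * t1k + 0.3)
  out <- resample_and_crop(x, 1000, 200, window = c(0, 2), t0 = 0)
  t200 <- seq(0, by = 1 / 200, length.out = 400)
  expect_gt(cor(as.vector(out), sin(2 * pi * 10 * t200 + 0.3)), 0.999)
})

test_that("the first-component waveform matches the rank-1 generator", {
  v <- sin(2 * pi * 3 * seq(0, 1, length.out = 100)) + 0.4
  bundle <- rbind(v, v, v)
  pc <- roi_first_component(bundle)
  vc <- v - mean(v)
  expect_gt(abs(cor(pc, v)), 1 - 1e-12)
  # polarity rule: extremum sign matches the dominant original row
  expect_equal(sign(pc[which.max(abs(pc))]), sign(v[which.max(abs(v))]))
  expect_error(roi_first_component(matrix(1, 4, 50)), "degenerate")
})

test_that("a global sign flip of the bundle leaves the component unchanged", {
  for (i in 1:100) {
    b <- generate_vertex_bundle(rnorm(60), n_vertices = 3, mixing_seed = i,
                                noise_sd = 0.2)
    expect_equal(roi_first_component(b$signals),
                 roi_first_component(-b$signals), tolerance = 1e-9)
  }
})

test_that("the extracted component recovers the ground-truth ROI signal", {
  sig <- sin(2 * pi * 5 * seq(0, 1, length.out = 200)) +
    0.5 * sin(2 * pi * 11 * seq(0, 1, length.out = 200))
  ok <- 0
  for (i in 1:20) {
    b <- generate_vertex_bundle(sig, n_vertices = 6, mixing_seed = i,
                                noise_sd = 0.1)
    if (abs(cor(roi_first_component(b), sig)) > 0.95) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("the first component beats random projection directions", {
  set.seed(4)
  b <- generate_vertex_bundle(rnorm(150), n_vertices = 4, mixing_seed = 3,
                              noise_sd = 0.5)
  Xc <- b$signals - rowMeans(b$signals)
  v_pc <- stats::var(roi_first_component(b))
  dirs <- matrix(rnorm(1000 * nrow(Xc)), 1000)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  v_rand <- apply(dirs, 1, function(u) stats::var(as.vector(u %*% Xc)))
  expect_true(all(v_pc >= v_rand - 1e-9))
})

test_that("dataset assembly validates shapes and labels", {
  trials <- replicate(32, matrix(rnorm(68 * 100), 68, 100), simplify = FALSE)
  labels <- rep(c("upright", "inverted"), each = 16)
  ds <- assemble_stimulus_dataset(trials, labels, subject = 1,
                                  stimulus = "face")
  expect_s3_class(ds, "stimulus_dataset")
  expect_equal(ds$M, 32L)
  expect_error(assemble_stimulus_dataset(list(), character(0), 1, "face"),
               "empty")
  bad <- trials
  bad[[3]] <- matrix(0, 67, 100)
  expect_error(assemble_stimulus_dataset(bad, labels, 1, "face"),
               "inconsistent")
  expect_error(assemble_stimulus_dataset(trials, rep("up", 32), 1, "face"),
               "labels")
})

test_that("standardization uses training statistics only", {
  set.seed(2)
  tr <- array(rnorm(10 * 4 * 6, mean = 5, sd = 2), c(10, 4, 6))
  te <- array(9, c(2, 4, 6))
  std <- standardize_split(tr, val = tr, test = te)
  expect_lt(abs(mean(std$train)), 1e-9)
  expect_lt(abs(stats::sd(as.vector(std$train)) - 1), 1e-9)
  # closed form on the test set: (9 - mu) / sigma
  expect_equal(unique(as.vector(std$test)),
               (9 - mean(tr)) / stats::sd(as.vector(tr)))
  # fresh data standardized by train statistics is not re-centered
  te2 <- array(rnorm(40 * 4 * 6, mean = 8), c(40, 4, 6))
  std2 <- standardize_split(tr, test = te2)
  expect_gt(abs(mean(std2$test)), 0.1)
  expect_error(standardize_split(array(1, c(3, 2, 2))), "degenerate")
})

test_that("cohort reduction yields 68 x 100 decoder inputs", {
  effs <- list(face = effect_spec("lateraloccipital_rh"))
  red <- reduce_cohort(generate_cohort(2, 2, effects = effs, seed = 5))
  dec <- red$face[[1]]$decoder
  expect_equal(dim(dec$X)[2:3], c(68L, 100L))
  expect_equal(dim(red$face[[1]]$epoch$X)[3], 200L)
  expect_equal(dec$t0, 0)
  # 1000 Hz generation path goes through true resampling
  red2 <- reduce_cohort(generate_cohort(2, 2, effects = effs, seed = 5,
                                        fs = 1000))
  expect_equal(dim(red2$face[[1]]$decoder$X)[2:3], c(68L, 100L))
})
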