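test_that("the reference architecture counts exactly 1502 parameters", {
  m <- build_decoder(decoder_config(), seed = 0)
  expect_identical(count_trainable_parameters(m), 1502L)
  # the count is seed-invariant
  expect_identical(count_trainable_parameters(build_decoder(seed = 99)),
                   1502L)
})

test_that("parameter counts follow the layer arithmetic", {
  m <- build_decoder(decoder_config(temporal_kernel_len = 1,
                                    pool_factor = 100,
                                    spatial_depth_multiplier = 1), 0)
  expect_identical(count_trainable_parameters(m),
                   4L + 8L + 4L * 68L + 8L + (4L * 1L * 2L + 2L))
  dense_only <- structure(list(params = list(Wd = matrix(0, 2, 2),
                                             bd = rep(0, 2))),
                          class = "decoder_model")
  expect_identical(count_trainable_parameters(dense_only), 6L)
  m2 <- build_decoder(decoder_config(spatial_depth_multiplier = 4), 0)
  expect_identical(count_trainable_parameters(m2),
                   4L * 33L + 8L + 16L * 68L + 32L + (16L * 50L * 2L + 2L))
  expect_error(decoder_config(pool_factor = 3), "divide")
})

test_that("decoder outputs are normalized probabilities", {
  m <- build_decoder(decoder_config(), 1)
  X <- array(rnorm(5 * 68 * 100), c(5, 68, 100))
  pr <- predict_decoder(m, X)
  expect_equal(rowSums(pr$probs), rep(1, 5), tolerance = 1e-6)
  expect_true(all(pr$probs >= 0))
  expect_error(predict_decoder(m, array(0, c(2, 10, 10))), "shape")
})

test_that("compiled kernels match the reference implementation", {
  set.seed(8)
  cfg <- decoder_config(n_temporal_kernels = 3L, temporal_kernel_len = 7L,
                        spatial_depth_multiplier = 2L, pool_factor = 2L,
                        dropout_p = 0, n_rois = 9L, n_samples = 16L)
  m <- build_decoder(cfg, 2)
  B <- 11
  Xarr <- array(rnorm(9 * 16 * B), c(9, 16, B))
  y01 <- sample(0:1, B, replace = TRUE)
  batch <- invcnn:::prepare_batch(Xarr, y01, cfg)
  fwdR <- invcnn:::decoder_fwd(m$params, m$running, cfg, batch,
                               training = TRUE)
  grR <- invcnn:::decoder_bwd(m$params, cfg, batch, fwdR)
  st <- invcnn:::cnn_train_step(m$params, unclass(cfg), batch$x_num,
                                batch$mB, batch$CB, batch$Y, batch$y01,
                                NULL)
  expect_equal(st$loss, invcnn:::ce_loss(fwdR$probs, y01), tolerance = 1e-12)
  for (nm in names(grR))
    expect_equal(st$grads[[nm]], grR[[nm]], tolerance = 1e-10,
                 ignore_attr = TRUE)
  ev <- invcnn:::cnn_eval_forward(m$params, unclass(cfg), as.numeric(Xarr),
                                  m$running)
  fr <- invcnn:::decoder_fwd(m$params, m$running, cfg,
                             list(Xr = matrix(Xarr, 9), B = B),
                             training = FALSE)
  expect_equal(ev$O, fr$O, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  cfg <- decoder_config(n_temporal_kernels = 2L, temporal_kernel_len = 5L,
                        spatial_depth_multiplier = 2L, pool_factor = 2L,
                        dropout_p = 0, n_rois = 6L, n_samples = 12L)
  m <- build_decoder(cfg, 3)
  B <- 7
  Xarr <- array(rnorm(6 * 12 * B), c(6, 12, B))
  y01 <- sample(0:1, B, replace = TRUE)
  batch <- invcnn:::prepare_batch(Xarr, y01, cfg)
  fwd <- invcnn:::decoder_fwd(m$params, m$running, cfg, batch,
                              training = TRUE)
  gr <- invcnn:::decoder_bwd(m$params, cfg, batch, fwd)
  loss_of <- function(params) {
    f <- invcnn:::decoder_fwd(params, m$running, cfg, batch, training = TRUE)
    invcnn:::ce_loss(f$probs, y01)
  }
  eps <- 1e-6
  for (nm in c("Wt", "Ws", "g2", "Wd", "bd")) {
    p <- m$params[[nm]]
    for (i in sample(seq_along(p), min(6, length(p)))) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic and fits separable data", {
  prob <- separable_problem()
  std <- standardize_split(prob$X)
  data <- list(X = std$train, y = prob$y)
  hy <- decoder_hyper(max_epochs = 40, patience = 40)
  m1 <- train_decoder(build_decoder(decoder_config(), 0), data, data,
                      seed = 0, hyper = hy)
  m2 <- train_decoder(build_decoder(decoder_config(), 0), data, data,
                      seed = 0, hyper = hy)
  expect_identical(m1$params, m2$params)
  ev <- evaluate_decoder(m1, data)
  expect_equal(ev$accuracy, 1)
  expect_equal(sum(ev$confusion), length(prob$y))
  expect_equal(sum(diag(ev$confusion)), length(prob$y))
})

test_that("an untrained decoder scores at chance on balanced trials", {
  set.seed(3)
  m <- build_decoder(decoder_config(), 5)
  X <- array(rnorm(1000 * 68 * 100), c(1000, 68, 100))
  y <- rep(c("upright", "inverted"), 500)
  ev <- evaluate_decoder(m, list(X = X, y = y))
  expect_gte(ev$accuracy, 0.45)
  expect_lte(ev$accuracy, 0.55)
})

test_that("training on shuffled labels stays within the chance band", {
  set.seed(6)
  n <- 120
  X <- array(rnorm(n * 68 * 100), c(n, 68, 100))
  y <- sample(rep(c("upright", "inverted"), n / 2))
  std <- standardize_split(X[1:100, , ], test = X[101:n, , ])
  m <- train_decoder(build_decoder(decoder_config(), 0),
                     list(X = std$train[1:80, , ], y = y[1:80]),
                     list(X = std$train[81:100, , ], y = y[81:100]),
                     seed = 0, hyper = decoder_hyper(max_epochs = 30))
  ev <- evaluate_decoder(m, list(X = std$test, y = y[101:n]))
  # binomial 95% band around 0.5 for 20 trials is [0.28, 0.72]
  expect_gte(ev$accuracy, 0.28)
  expect_lte(ev$accuracy, 0.72)
})

test_that("the cross-validation protocol enumerates and decodes correctly", {
  runs <- count_training_runs(23, 10, 3)
  expect_identical(runs$per_stimulus, 230L)
  expect_identical(runs$total, 690L)
  dummy <- vector("list", 23)
  dry <- run_loso_protocol(dummy, n_seeds = 10, dry_run = TRUE)
  expect_identical(dry$runs, 230L)
  expect_error(run_loso_protocol(dummy[1], n_seeds = 1), ">= 2")

  prs <- fixture_protocol_small()
  for (stim in names(prs)) {
    expect_length(prs[[stim]]$fold_accuracy, 8L)
    expect_identical(prs[[stim]]$runs, 16L)
  }
  # injected face effect decodes better than the null control stimulus
  expect_gt(mean(prs$face$fold_accuracy), mean(prs$house$fold_accuracy))
})

test_that("stimulus accuracy comparisons run 3 Bonferroni-corrected tests", {
  acc <- rep(0.6, 23)
  same <- compare_stimulus_accuracies(acc, acc, acc)
  expect_identical(same$n_tests, 3L)
  expect_equal(same$pairwise$p_bonferroni, rep(1, 3))
  set.seed(1)
  house <- 0.5 + rnorm(23, sd = 0.02)
  face <- house + 0.2
  res <- compare_stimulus_accuracies(face, face - 0.01, house)
  fh <- res$pairwise[res$pairwise$a == "face" & res$pairwise$b == "house", ]
  expect_lt(fh$p_bonferroni, 0.05)
  expect_identical(fh$direction, ">")
  expect_lt(res$vs_chance$p[res$vs_chance$stimulus == "face"], 0.001)
  expect_error(compare_stimulus_accuracies(acc, acc, acc[-1]), "equal")
})
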