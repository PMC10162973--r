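# Shared fixtures, built lazily and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Small effect spec reused across tests: strong, fast to generate.
test_effects <- function() default_effect_specs()

# A reduced two-stimulus cohort (face-like effect + null control).
fixture_cohort_small <- function() {
  fixture("cohort_small", function() {
    effs <- default_effect_specs()[c("face", "house")]
    reduce_cohort(generate_cohort(8, 12, effects = effs, seed = 101))
  })
}

# LOSO protocol on the small cohort (2 seeds), both stimuli, with the
# standardized test sets attached -- feeds decoder, relevance and selection
# tests.
fixture_protocol_small <- function() {
  fixture("protocol_small", function() {
    red <- fixture_cohort_small()
    out <- list()
    for (stim in names(red)) {
      ds <- lapply(red[[stim]], `[[`, "decoder")
      pr <- run_loso_protocol(ds, n_seeds = 2)
      pr$std_tests <- lapply(seq_along(ds), function(s)
        list(X = apply_scaler(pr$test_sets[[s]]$X, pr$scalers[[s]]),
             y = pr$test_sets[[s]]$y))
      out[[stim]] <- pr
    }
    out
  })
}

fixture_relevance_small <- function() {
  fixture("relevance_small", function() {
    prs <- fixture_protocol_small()
    lapply(prs, function(pr) {
      maps <- lapply(seq_along(pr$models), function(s)
        fold_relevance_map(pr$models[[s]], pr$std_tests[[s]]))
      list(maps = maps, RS = relevance_scores(maps))
    })
  })
}

# Exhaustive signed-rank oracle: enumerate all 2^n sign assignments of the
# non-zero absolute differences (independent of the implementation path).
enumerate_signed_rank <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  if (alternative == "greater") {
    mean(Vs >= V_obs)
  } else {
    p_lo <- mean(Vs <= V_obs)
    p_hi <- mean(Vs >= V_obs)
    min(1, 2 * min(p_lo, p_hi))
  }
}

# Tiny standardized training problem with linearly separable classes.
separable_problem <- function(n_per_class = 20, seed = 9) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- array(rnorm(n * 68 * 100, sd = 0.3), c(n, 68, 100))
  y <- rep(c("upright", "inverted"), each = n_per_class)
  X[y == "inverted", 5, 40:60] <- X[y == "inverted", 5, 40:60] + 3
  list(X = X, y = y)
}
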