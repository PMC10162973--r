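#' Enumerate the training runs of the cross-validation protocol
#'
#' @param n_subjects Number of subjects (= folds).
#' @param n_seeds Random initializations per fold.
#' @param n_stimuli Stimulus types decoded independently.
#' @return List with `per_stimulus` and `total` run counts.
#' @export
count_training_runs <- function(n_subjects, n_seeds = 10L, n_stimuli = 3L) {
  per <- as.integer(n_subjects) * as.integer(n_seeds)
  list(per_stimulus = per, total = per * as.integer(n_stimuli))
}

# Stratified validation split: `frac` of training trials, at least one per
# class, reproducible from `seed`.
validation_split <- function(y01, frac = 0.1, seed = 0L) {
  with_seed(seed, {
    val_idx <- integer(0)
    for (cls in c(0L, 1L)) {
      cls_idx <- which(y01 == cls)
      n_val <- max(1L, round(frac * length(cls_idx)))
      val_idx <- c(val_idx, sample(cls_idx, n_val))
    }
    sort(val_idx)
  })
}

# Concatenate decoder-ready datasets of several subjects.
bind_datasets <- function(datasets) {
  Xs <- lapply(datasets, function(d) d$X)
  X <- do.call(abind3, Xs)
  y <- unlist(lapply(datasets, function(d) d$y), use.names = FALSE)
  list(X = X, y = y)
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))),
                    d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Leave-one-subject-out decoding protocol
#'
#' For every held-out subject, the remaining subjects' trials form the
#' training pool; a stratified 10% of them is held out as the validation
#' set for early stopping; all sets are standardized with the training-pool
#' mean and SD; one decoder is trained per seed, evaluated on the held-out
#' subject, and the metrics are averaged over seeds, giving one accuracy
#' and confusion matrix per fold.
#'
#' @param datasets List of decoder-ready `stimulus_dataset` objects, one per
#'   subject (same stimulus type).
#' @param n_seeds Number of random initializations per fold; training seeds
#'   are `0 .. n_seeds - 1`.
#' @param config A [decoder_config()].
#' @param hyper A [decoder_hyper()].
#' @param val_frac Fraction of training trials held out for validation.
#' @param dry_run When `TRUE`, no model is fitted; the protocol is only
#'   enumerated (`runs` in the result).
#' @param keep_models Keep the trained models (needed for relevance
#'   analysis); they are grouped per fold.
#' @return List with `fold_accuracy` (one per subject), `fold_confusion`,
#'   `runs` (total trainings), `models`, `scalers`, `test_sets`.
#' @export
run_loso_protocol <- function(datasets, n_seeds = 10L,
                              config = decoder_config(),
                              hyper = decoder_hyper(), val_frac = 0.1,
                              dry_run = FALSE, keep_models = TRUE) {
  n_sub <- length(datasets)
  if (n_sub < 2L) stop("the protocol needs >= 2 subjects", call. = FALSE)
  runs <- as.integer(n_sub) * as.integer(n_seeds)
  if (dry_run)
    return(list(fold_accuracy = rep(NA_real_, n_sub), runs = runs,
                models = NULL))
  fold_accuracy <- numeric(n_sub)
  fold_confusion <- vector("list", n_sub)
  models <- vector("list", n_sub)
  scalers <- vector("list", n_sub)
  test_sets <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    pool <- bind_datasets(datasets[-s])
    test <- datasets[[s]]
    accs <- numeric(n_seeds)
    confs <- vector("list", n_seeds)
    fold_models <- vector("list", n_seeds)
    for (i in seq_len(n_seeds)) {
      seed <- i - 1L
      vidx <- validation_split(as.integer(pool$y == "inverted"),
                               frac = val_frac,
                               seed = derive_seed(seed, s))
      train <- list(X = pool$X[-vidx, , , drop = FALSE], y = pool$y[-vidx])
      val <- list(X = pool$X[vidx, , , drop = FALSE], y = pool$y[vidx])
      std <- standardize_split(train$X, val$X, test$X)
      model <- build_decoder(config, seed = seed)
      model$meta$fold <- s
      model <- train_decoder(model, list(X = std$train, y = train$y),
                             list(X = std$val, y = val$y),
                             seed = seed, hyper = hyper)
      ev <- evaluate_decoder(model, list(X = std$test, y = test$y))
      accs[i] <- ev$accuracy
      confs[[i]] <- ev$confusion
      fold_models[[i]] <- model
      if (i == 1L) scalers[[s]] <- std$scaler
    }
    fold_accuracy[s] <- mean(accs)
    fold_confusion[[s]] <- Reduce(`+`, confs) / n_seeds
    models[[s]] <- if (keep_models) fold_models else NULL
    test_sets[[s]] <- test
  }
  list(fold_accuracy = fold_accuracy, fold_confusion = fold_confusion,
       runs = runs, models = models, scalers = scalers,
       test_sets = test_sets)
}

#' Compare stimulus-specific decoding accuracies
#'
#' Paired Wilcoxon signed-rank tests between all stimulus pairs (3 tests,
#' Bonferroni factor 3) plus one-sample signed-rank tests of each stimulus
#' against the 0.5 chance level.
#'
#' @param acc_face,acc_body,acc_house Per-fold accuracy vectors of equal
#'   length.
#' @return List with `pairwise` (data frame: pair, statistic, p, corrected
#'   p, direction) and `vs_chance` (data frame per stimulus).
#' @export
compare_stimulus_accuracies <- function(acc_face, acc_body, acc_house) {
  accs <- list(face = acc_face, body = acc_body, house = acc_house)
  n <- lengths(accs)
  if (length(unique(n)) != 1L)
    stop("accuracy vectors must have equal length", call. = FALSE)
  pairs <- utils::combn(names(accs), 2L)
  pw <- data.frame(a = pairs[1, ], b = pairs[2, ], statistic = NA_real_,
                   p = NA_real_, p_bonferroni = NA_real_,
                   direction = NA_character_)
  for (i in seq_len(ncol(pairs))) {
    w <- wilcoxon_signed_rank(accs[[pairs[1, i]]], accs[[pairs[2, i]]],
                              alternative = "two.sided")
    pw$statistic[i] <- w$statistic
    pw$p[i] <- w$p.value
    md <- stats::median(accs[[pairs[1, i]]] - accs[[pairs[2, i]]])
    pw$direction[i] <- if (md > 0) ">" else if (md < 0) "<" else "="
  }
  pw$p_bonferroni <- pmin(1, pw$p * ncol(pairs))
  vc <- data.frame(stimulus = names(accs), statistic = NA_real_,
                   p = NA_real_)
  for (i in seq_along(accs)) {
    w <- wilcoxon_signed_rank(accs[[i]], rep(0.5, length(accs[[i]])),
                              alternative = "greater")
    vc$statistic[i] <- w$statistic
    vc$p[i] <- w$p.value
  }
  list(pairwise = pw, vs_chance = vc, n_tests = ncol(pairs))
}
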