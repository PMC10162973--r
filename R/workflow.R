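#' End-to-end pipeline configuration
#'
#' Bundles every tunable of the analysis: cohort size, condition effects,
#' decoder architecture and optimizer, relevance propagation, statistics,
#' and seeds. Every stochastic stage has an explicit seed so a rerun with
#' the same configuration reproduces the deterministic stages bit for bit.
#'
#' @param n_subjects,trials_per_condition Cohort size.
#' @param effects Named list of [effect_spec()] per stimulus; the first two
#'   are treated as social, the element named `"house"` as control.
#' @param n_seeds Decoder initializations per cross-validation fold.
#' @param decoder A [decoder_config()].
#' @param hyper A [decoder_hyper()].
#' @param lrp An [lrp_config()].
#' @param alpha Significance level of the selection criteria.
#' @param n_perm Permutations of the cluster tests.
#' @param seed Master seed (cohort generation, permutations).
#' @param out_dir Output directory of [run_pipeline()].
#' @param freqs Frequency grid of the time-frequency analysis, Hz.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 8L, trials_per_condition = 16L,
                            effects = default_effect_specs(),
                            n_seeds = 3L,
                            decoder = decoder_config(),
                            hyper = decoder_hyper(),
                            lrp = lrp_config(),
                            alpha = 0.05, n_perm = 5000L, seed = 1L,
                            out_dir = tempfile("invcnn-run-"),
                            freqs = 4:40) {
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 effects = effects, n_seeds = as.integer(n_seeds),
                 decoder = decoder, hyper = hyper, lrp = lrp,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), out_dir = out_dir,
                 freqs = freqs), class = "pipeline_config")
}

#' Run the full inversion-decoding pipeline
#'
#' Executes simulate -> reduce -> decode (leave-one-subject-out x seeds x
#' stimuli) -> explain -> select -> signatures, writing per-stage artifacts
#' and a manifest (seeds, configuration digest, file hashes) under
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param dry_run When `TRUE`, only enumerate the training protocol.
#' @return Invisible report list: `metrics` (per-fold accuracies),
#'   `comparison`, `relevance` (score tables), `selection` (per social
#'   stimulus), `signatures`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), dry_run = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stimuli <- names(config$effects)
  if (dry_run) {
    runs <- count_training_runs(config$n_subjects, config$n_seeds,
                                length(stimuli))
    return(invisible(list(dry_run = TRUE, runs = runs)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    if (grepl("\\.csv$", name)) utils::write.csv(obj, path, row.names = FALSE)
    else saveRDS(obj, path)
    files <<- c(files, path)
    path
  }

  cohort <- generate_cohort(config$n_subjects, config$trials_per_condition,
                            config$effects, seed = config$seed)
  reduced <- reduce_cohort(cohort)
  put(reduced, "reduced_cohort.rds")

  metrics <- list(); protocols <- list()
  for (stim in stimuli) {
    datasets <- lapply(reduced[[stim]], `[[`, "decoder")
    pr <- run_loso_protocol(datasets, n_seeds = config$n_seeds,
                            config = config$decoder, hyper = config$hyper)
    protocols[[stim]] <- pr
    metrics[[stim]] <- pr$fold_accuracy
  }
  metrics_df <- do.call(rbind, lapply(stimuli, function(stim)
    data.frame(stimulus = stim, fold = seq_along(metrics[[stim]]),
               accuracy = metrics[[stim]])))
  put(metrics_df, "fold_metrics.csv")

  comparison <- if (length(stimuli) >= 3L)
    compare_stimulus_accuracies(metrics[[1]], metrics[[2]], metrics[[3]])
  else NULL

  relevance <- list()
  for (stim in stimuli) {
    pr <- protocols[[stim]]
    fold_maps <- lapply(seq_along(pr$models), function(s) {
      std_test <- list(X = apply_scaler(pr$test_sets[[s]]$X, pr$scalers[[s]]),
                       y = pr$test_sets[[s]]$y)
      fold_relevance_map(pr$models[[s]], std_test, config$lrp)
    })
    relevance[[stim]] <- relevance_scores(fold_maps)
  }
  rs_df <- do.call(rbind, lapply(stimuli, function(stim) {
    data.frame(stimulus = stim, roi = colnames(relevance[[stim]]),
               mean_score = colMeans(relevance[[stim]]))
  }))
  put(rs_df, "relevance_scores.csv")

  control <- if ("house" %in% stimuli) "house" else stimuli[length(stimuli)]
  social <- setdiff(stimuli, control)
  selection <- list()
  for (stim in social) {
    selection[[stim]] <- select_relevant_rois(relevance[[stim]],
                                              relevance[[control]],
                                              alpha = config$alpha)
    put(selection[[stim]]$summary, paste0("selection_", stim, ".csv"))
  }

  sig_rois <- unique(unlist(lapply(selection, `[[`, "selected")))
  if (!length(sig_rois))
    sig_rois <- config$effects[[social[1]]]$effect_rois
  signatures <- list()
  for (stim in social[1]) {
    eps <- lapply(reduced[[stim]], `[[`, "epoch")
    for (roi in sig_rois) {
      ri <- roi_index(roi)
      erps <- lapply(eps, compute_erp)
      up <- t(vapply(erps, function(e) e$upright[ri, ],
                     numeric(dim(eps[[1]]$X)[3])))
      inv <- t(vapply(erps, function(e) e$inverted[ri, ],
                      numeric(dim(eps[[1]]$X)[3])))
      ct <- cluster_test_time(inv, up, n_perm = config$n_perm,
                              seed = derive_seed(config$seed, ri))
      T <- dim(eps[[1]]$X)[3]
      times <- eps[[1]]$t0 + (seq_len(T) - 1) / eps[[1]]$fs
      post <- times >= 0
      erds <- lapply(eps, function(ep)
        erds_condition_average(ep, roi, freqs = config$freqs))
      arr_u <- array(0, c(length(eps), length(config$freqs), sum(post)))
      arr_i <- arr_u
      for (s in seq_along(eps)) {
        arr_u[s, , ] <- erds[[s]]$upright$power[, post]
        arr_i[s, , ] <- erds[[s]]$inverted$power[, post]
      }
      valid <- coi_mask(config$freqs, times, eps[[1]]$fs)[, post]
      tf <- cluster_test_timefreq(arr_i, arr_u, n_perm = config$n_perm,
                                  seed = derive_seed(config$seed, ri + 68L),
                                  valid = valid)
      signatures[[paste(stim, roi, sep = ":")]] <-
        list(roi = roi, stimulus = stim, erp_upright = colMeans(up),
             erp_inverted = colMeans(inv), cluster = ct, erds_cluster = tf)
    }
  }
  sig_df <- do.call(rbind, lapply(names(signatures), function(nm) {
    s <- signatures[[nm]]
    data.frame(stimulus = s$stimulus, roi = s$roi,
               n_clusters = length(s$cluster$clusters),
               n_significant = sum(s$cluster$sig),
               min_p = if (length(s$cluster$p)) min(s$cluster$p) else NA_real_,
               n_erds_significant = sum(s$erds_cluster$sig))
  }))
  put(sig_df, "signature_clusters.csv")

  manifest <- list(
    seed = config$seed, n_seeds = config$n_seeds,
    n_subjects = config$n_subjects,
    trials_per_condition = config$trials_per_condition,
    stimuli = stimuli,
    r_version = as.character(getRversion()),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(metrics = metrics, comparison = comparison,
                 relevance = relevance, selection = selection,
                 signatures = signatures, manifest = manifest,
                 out_dir = config$out_dir))
}
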