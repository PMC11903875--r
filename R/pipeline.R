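# End-to-end orchestration: simulate -> preprocess -> features ->
# hypnodensity (with QC) -> information metrics -> cohort models ->
# spectral interpretation, under a single config and deterministic seeding.

#' Pipeline run configuration
#'
#' All defaults are the analysis constants used throughout the package:
#' 0.5-40 Hz band pass, k-fold(10) staging scheme, QC threshold 0.4,
#' divergence floor 1e-6, iteration counts 60 (classification repeats),
#' 120 (regression repeats), 1000 (subject-accuracy iterations), 30
#' (size-balanced subsamples), 500 (matched subsamples), KS matching level
#' 0.1 and saturation level 0.05.
#'
#' @param seed Global integer seed; every stage derives its own seed from
#'   it.
#' @param lowcut,highcut Band-pass edges in Hz.
#' @param scheme,k Staging cross-validation scheme and fold count.
#' @param qc_threshold Balanced-accuracy exclusion threshold.
#' @param epsilon Probability floor for the divergence.
#' @param staging_nrounds,cohort_nrounds Boosting rounds for staging and
#'   cohort models.
#' @param n_repeats,n_repeats_regress,n_iter_subject,n_subsamples,n_matched
#'   Iteration counts.
#' @param matching_alpha,saturation_alpha Significance levels.
#' @param fs,epochs_per_subject Synthetic-recording geometry.
#' @param classify_grid Feature-count prefixes evaluated by the cohort
#'   classifier.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, lowcut = 0.5, highcut = 40,
                       scheme = "k_fold", k = 10, qc_threshold = 0.4,
                       epsilon = 1e-6, staging_nrounds = 60,
                       cohort_nrounds = 100, n_repeats = 60,
                       n_repeats_regress = 120, n_iter_subject = 1000,
                       n_subsamples = 30, n_matched = 500,
                       matching_alpha = 0.1, saturation_alpha = 0.05,
                       fs = 128, epochs_per_subject = 240,
                       classify_grid = c(1, 2, 4, 8, 16)) {
  structure(as.list(environment()), class = "run_config")
}

#' Process one subject through the epoch-level stages
#'
#' Preprocess, epoch, extract features, fit the personalized hypnodensity,
#' apply QC, compute the information-metric series, the 16-feature summary,
#' the band-power fractions and the stage self-transitions. The raw signal
#' is not retained.
#'
#' @param subject A `synthetic_subject` (or a list with `recording`,
#'   `hypnogram`, `metadata`).
#' @param config A [run_config()].
#' @param subject_index Index used for seed derivation.
#' @return List: `metadata`, `summary`, `series`, `band_fractions`
#'   (epoch x channel x band), `band_original_indices`, `self_transition`
#'   (5x5), `balanced_accuracy`, `qc`, `hd_probs`, `lambda`.
#' @export
process_subject <- function(subject, config = run_config(), subject_index = 1L) {
  rec <- preprocess(subject$recording, config$lowcut, config$highcut)
  eps <- make_epochs(rec, subject$hypnogram)
  feats <- extract_features(eps)
  hd <- fit_hypnodensity(feats, scheme = config$scheme, k = config$k,
                         nrounds = config$staging_nrounds,
                         seed = child_seed(config$seed, 7000L + subject_index))
  qc <- qc_exclude(hd, config$qc_threshold)
  series <- compute_series(hd, epsilon = config$epsilon)
  bands <- epoch_psd(eps)
  list(metadata = subject$metadata,
       summary = summarize_subject(series),
       series = series,
       band_fractions = bands$fractions,
       band_original_indices = bands$original_indices,
       self_transition = self_transition(subject$hypnogram),
       balanced_accuracy = hd$balanced_accuracy,
       qc = qc,
       hd_probs = hd$probs,
       lambda = subject$recording$intrusion_lambda)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates the cohort subject by subject (recordings are discarded after
#' feature extraction), fits all personalized staging models, logs and
#' applies QC exclusions, assembles the cohort table, and runs the
#' cohort-level analyses: MRMR ranking, sequential repeated
#' cross-validated 3-class classification (plus a label-permuted null at
#' the largest prefix), group statistics, and the spectral interpretation
#' correlations.
#'
#' @param config A [run_config()].
#' @param specs Group specifications, default [default_group_specs()].
#' @param output_dir Optional directory; when given, the cohort summary,
#'   performance curve and correlation tables are written as CSV together
#'   with a small JSON manifest.
#' @param do_classify,do_regress Toggle the cohort-model stages.
#' @param progress Print per-subject progress lines.
#' @return List with `table` (cohort data.frame), `subjects` (per-subject
#'   results of [process_subject()]), `excluded` (subject ids), `mrmr`,
#'   `curve`, `null_score`, `stats_H`, `stats_dKL`, `interp` (per-subject
#'   correlation tables), `selftrans` (data.frame from
#'   [correlate_instability_selftransition()]), `regression`.
#' @export
run_pipeline <- function(config = run_config(), specs = default_group_specs(),
                         output_dir = NULL, do_classify = TRUE,
                         do_regress = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  n_per <- vapply(specs, `[[`, integer(1), "n_subjects")
  total <- sum(n_per)
  group_of <- rep(seq_along(specs), n_per)

  results <- vector("list", total)
  for (sidx in seq_len(total)) {
    subj <- simulate_one_subject(specs[[group_of[sidx]]], sidx, config$seed,
                                 config$epochs_per_subject, config$fs,
                                 default_stage_profiles(),
                                 c("C3", "C4", "EOG1"))
    res <- suppressMessages(process_subject(subj, config, sidx))
    results[[sidx]] <- res
    if (progress)
      cat(sprintf("subject %d/%d (%s): balacc %.3f [%s]\n", sidx, total,
                  res$metadata$group, res$balanced_accuracy, res$qc))
  }

  kept <- vapply(results, function(r) r$qc == "keep", logical(1))
  excluded <- vapply(results, function(r) r$metadata$subject_id,
                     character(1))[!kept]
  if (length(excluded))
    message(length(excluded), " subject(s) excluded by QC: ",
            paste(excluded, collapse = ", "))
  keptres <- results[kept]
  if (!length(keptres)) stop("empty cohort: every subject excluded by QC")

  tab <- cohort_table(lapply(keptres, `[[`, "summary"),
                      lapply(keptres, `[[`, "metadata"))

  # spectral interpretation per subject: entropy-power and dkl-deltaPSD
  interp <- interp_correlations(keptres)
  wake_self <- vapply(keptres, function(r) r$self_transition["W", "W"],
                      numeric(1))
  selftrans <- if (nrow(tab) >= 10)
    correlate_instability_selftransition(tab, wake_self) else NULL

  mrmr <- curve <- null_score <- regression <- NULL
  if (do_classify && length(unique(tab$group)) >= 2) {
    mrmr <- mrmr_rank(tab, "group", seed = child_seed(config$seed, 9001L))
    curve <- sequential_cv_classify(
      tab, mrmr, n_features_grid = config$classify_grid,
      n_repeats = config$n_repeats, n_subsamples = config$n_subsamples,
      nrounds = config$cohort_nrounds, seed = child_seed(config$seed, 9002L))
    # label-permuted null at the largest prefix
    ntab <- tab
    set.seed(child_seed(config$seed, 9003L))
    ntab$group <- sample(ntab$group)
    null_curve <- sequential_cv_classify(
      ntab, mrmr, n_features_grid = max(config$classify_grid),
      n_repeats = config$n_repeats, n_subsamples = config$n_subsamples,
      nrounds = config$cohort_nrounds, seed = child_seed(config$seed, 9004L))
    null_score <- null_curve$summary$balacc_mean[1]
  }
  if (do_regress) {
    rk <- mrmr_rank(tab, "waso_min", seed = child_seed(config$seed, 9005L))
    regression <- sequential_cv_regress(
      tab, "waso_min", rk, n_features_grid = length(rk),
      n_repeats = config$n_repeats_regress, nrounds = config$cohort_nrounds,
      seed = child_seed(config$seed, 9006L))
  }

  stats_H <- if (length(unique(tab$group)) >= 2 &&
                 all(table(tab$group) >= 5)) group_stats(tab, "H") else NULL
  stats_dKL <- if (!is.null(stats_H)) group_stats(tab, "dKL") else NULL

  out <- list(table = tab, subjects = keptres, excluded = excluded,
              mrmr = mrmr, curve = curve, null_score = null_score,
              stats_H = stats_H, stats_dKL = stats_dKL,
              interp = interp, selftrans = selftrans,
              regression = regression, config = config)
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

# Per-subject correlations between the information metrics and band power,
# for the analyzed stages and all six bands.
interp_correlations <- function(keptres) {
  stages <- c("W", "N2", "N3", "REM")
  bands <- names(BANDS)
  rows <- list()
  for (r in keptres) {
    bt <- structure(list(fractions = r$band_fractions,
                         original_indices = r$band_original_indices,
                         channel_labels = dimnames(r$band_fractions)[[2]]),
                    class = "band_power_table")
    for (s in stages) for (b in bands) {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = r$metadata$subject_id, group = r$metadata$group,
        stage = s, band = b,
        r_entropy_power = as.numeric(correlate_entropy_power(r$series, bt, s, b)),
        r_dkl_dpsd = as.numeric(correlate_instability_deltapsd(r$series, bt, s, b)))
    }
  }
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(out, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$table, file.path(output_dir, "cohort_summary.csv"),
            row.names = FALSE)
  write.csv(out$interp, file.path(output_dir, "interpretation.csv"),
            row.names = FALSE)
  if (!is.null(out$curve))
    write.csv(out$curve$summary, file.path(output_dir, "performance_curve.csv"),
              row.names = FALSE)
  if (!is.null(out$stats_H))
    write.csv(rbind(cbind(metric = "H", out$stats_H),
                    cbind(metric = "dKL", out$stats_dKL)),
              file.path(output_dir, "group_stats.csv"), row.names = FALSE)
  manifest <- list(
    seed = out$config$seed,
    n_subjects = nrow(out$table) + length(out$excluded),
    n_excluded = length(out$excluded),
    config = out$config[setdiff(names(out$config), "")],
    files = list.files(output_dir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(output_dir)
}
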