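# Personalized hypnodensity estimation: an intra-subject cross-validated
# gradient-boosted staging model whose scores are turned into calibrated
# per-epoch stage probability distributions.

staging_params <- function(seed) {
  list(objective = "multi:softprob", eval_metric = "mlogloss", num_class = 5,
       eta = 0.1, max_depth = 6, subsample = 0.8, colsample_bytree = 0.8,
       gamma = 0.1, nthread = 1, seed = seed)
}

# Stratified fold assignment: epochs of each stage spread round-robin.
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Per-class sigmoid (Platt) calibration fitted on held-out margins.
# Returns a function mapping an n x 5 margin matrix to probabilities.
fit_platt <- function(margins, y, softmax) {
  models <- vector("list", 5)
  for (cl in 1:5) {
    pos <- y == cl
    if (sum(pos) >= 1 && sum(!pos) >= 1) {
      df <- data.frame(y = as.numeric(pos), m = margins[, cl])
      models[[cl]] <- suppressWarnings(glm(y ~ m, data = df, family = binomial()))
    }
  }
  function(marg, soft) {
    p <- matrix(0, nrow(marg), 5)
    for (cl in 1:5) {
      if (!is.null(models[[cl]])) {
        p[, cl] <- suppressWarnings(
          predict(models[[cl]], newdata = data.frame(m = marg[, cl]),
                  type = "response"))
      } else {
        # class absent from the calibration split: fall back to the
        # model's softmax output so the stage keeps a defined probability
        p[, cl] <- soft[, cl]
      }
    }
    p <- pmax(p, 0)
    rs <- rowSums(p)
    bad <- rs <= 0
    if (any(bad)) { p[bad, ] <- 1 / 5; rs[bad] <- 1 }
    p / rs
  }
}

#' Fit a personalized hypnodensity model
#'
#' Trains an intra-subject gradient-boosted decision-tree stager
#' (learning rate 0.1, depth 6, 80% example and 80% feature subsampling,
#' regularization gamma 0.1) under k-fold or leave-one-out cross-validation
#' and converts its scores into calibrated stage probabilities: within each
#' training fold, an inner stratified 80/20 split provides held-out margins
#' on which per-class sigmoid (Platt) fits are estimated; the calibrated
#' class probabilities are renormalized to sum to 1. Leave-one-out is
#' k-fold with `k = n_epochs`, so the two schemes coincide exactly at that
#' k.
#'
#' @param features An `epoch_feature_matrix` from [extract_features()].
#' @param scheme `"k_fold"` (default) or `"leave_one_out"`.
#' @param k Folds for `"k_fold"` (default 10).
#' @param nrounds Boosting rounds per fold model (default 60).
#' @param seed Integer seed controlling folds, inner splits and the tree
#'   sampler.
#' @return A `hypnodensity` object: `probs` (n x 5, columns W, N1, N2, N3,
#'   REM; rows sum to 1), `predicted_stage` (argmax, ties broken toward the
#'   lower stage index), `expert_stage`, `balanced_accuracy`,
#'   `original_indices`.
#' @export
fit_hypnodensity <- function(features, scheme = c("k_fold", "leave_one_out"),
                             k = 10, nrounds = 60, seed = 1L) {
  stopifnot(inherits(features, "epoch_feature_matrix"))
  scheme <- match.arg(scheme)
  X <- features$values
  stage <- features$stage_labels
  n <- nrow(X)
  y <- match(stage, STAGES)               # 1..5
  if (length(unique(y)) < 2)
    stop("cannot train personalized model: only one stage present")
  if (scheme == "leave_one_out" || k >= n) k <- n

  fold <- if (k == n) seq_len(n) else stratified_folds(y, k, seed)
  probs <- matrix(NA_real_, n, 5, dimnames = list(NULL, STAGES))

  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    fseed <- child_seed(seed, f)
    # inner stratified 80/20 split of the training epochs for calibration
    set.seed(fseed)
    calib <- integer(0)
    for (cl in unique(y[train])) {
      idx <- train[y[train] == cl]
      n_cal <- floor(0.2 * length(idx))
      if (length(idx) >= 2 && n_cal >= 1)
        calib <- c(calib, sample(idx, n_cal))
    }
    inner <- setdiff(train, calib)
    if (length(unique(y[inner])) < 2) { inner <- train; calib <- train }

    dtrain <- xgboost::xgb.DMatrix(X[inner, , drop = FALSE], label = y[inner] - 1)
    booster <- xgboost::xgb.train(params = staging_params(fseed),
                                  data = dtrain, nrounds = nrounds, verbose = 0)
    as_m5 <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 5, byrow = TRUE)
    dcal <- xgboost::xgb.DMatrix(X[calib, , drop = FALSE])
    cal_margin <- as_m5(predict(booster, dcal, outputmargin = TRUE))
    calibrate <- fit_platt(cal_margin, y[calib], NULL)

    dtest <- xgboost::xgb.DMatrix(X[test, , drop = FALSE])
    test_margin <- as_m5(predict(booster, dtest, outputmargin = TRUE))
    test_soft <- as_m5(predict(booster, dtest))
    probs[test, ] <- calibrate(test_margin, test_soft)
  }

  predicted <- STAGES[apply(probs, 1, which.max)]
  present <- intersect(STAGES, unique(stage))
  recall <- vapply(present, function(s)
    mean(predicted[stage == s] == s), numeric(1))
  structure(list(probs = probs,
                 predicted_stage = predicted,
                 expert_stage = stage,
                 balanced_accuracy = mean(recall),
                 original_indices = features$original_indices,
                 scheme = scheme, k = k),
            class = "hypnodensity")
}

#' Quality-control decision for a fitted hypnodensity
#'
#' A subject is excluded when the staging balanced accuracy is strictly
#' lower than the threshold (default 0.4); a balanced accuracy exactly at
#' the threshold is kept.
#'
#' @param hd A `hypnodensity`.
#' @param threshold Exclusion threshold (default 0.4).
#' @return `"keep"` or `"exclude"`.
#' @export
qc_exclude <- function(hd, threshold = 0.4) {
  stopifnot(inherits(hd, "hypnodensity"))
  decision <- if (hd$balanced_accuracy < threshold) "exclude" else "keep"
  message(sprintf("QC: balanced accuracy %.3f -> %s",
                  hd$balanced_accuracy, decision))
  decision
}

#' Persist a hypnodensity as CSV
#'
#' Columns: `epoch_index`, `expert_stage`, `p_W`, `p_N1`, `p_N2`, `p_N3`,
#' `p_REM`.
#' @param hd A `hypnodensity`.
#' @param path Output path.
#' @export
write_hypnodensity_csv <- function(hd, path) {
  df <- data.frame(epoch_index = hd$original_indices,
                   expert_stage = hd$expert_stage)
  pr <- as.data.frame(hd$probs)
  names(pr) <- paste0("p_", STAGES)
  write.csv(cbind(df, pr), path, row.names = FALSE)
  invisible(path)
}
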