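# Cohort-level inference on the 16-feature subject summaries: MRMR feature
# ranking, sequential-inclusion repeated cross-validated classification and
# regression, demographic matching, per-subject accuracy, group statistics.

#' Assemble a cohort table from subject summaries
#'
#' @param summaries List of 16-value vectors from [summarize_subject()].
#' @param metadata List of subject metadata lists (as produced by
#'   [simulate_cohort()]).
#' @return data.frame: subject_id, group, demographics, sleep metrics and
#'   the 16 metric features.
#' @export
cohort_table <- function(summaries, metadata) {
  stopifnot(length(summaries) == length(metadata))
  feat <- do.call(rbind, lapply(summaries, function(s)
    as.data.frame(as.list(s[summary_feature_names()]))))
  meta <- do.call(rbind, lapply(metadata, function(m)
    data.frame(subject_id = m$subject_id, group = m$group, sex = m$sex,
               age = m$age, bmi = m$bmi, tst_min = m$tst_min,
               sol_min = m$sol_min, waso_min = m$waso_min, se_pct = m$se_pct,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(meta$subject_id)) stop("duplicate subject ids")
  cbind(meta, feat)
}

cohort_params <- function(n_classes, seed, nrounds = 100) {
  p <- list(eta = 0.1, subsample = 0.8, colsample_bytree = 0.8, gamma = 0.1,
            nthread = 1, seed = seed)
  if (n_classes > 2) {
    p$objective <- "multi:softprob"; p$num_class <- n_classes
    p$max_depth <- 6
  } else if (n_classes == 2) {
    p$objective <- "binary:logistic"
    p$max_depth <- 3                    # binary tasks use shallower trees
  } else {
    p$objective <- "reg:squarederror"
    p$max_depth <- 6
  }
  p
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy ordering maximizing relevance minus redundancy at each step.
#' Relevance is the out-of-bag permutation importance of a random forest
#' fit to the target; redundancy is the mean absolute Pearson correlation
#' with the already-selected features. Missing feature values are
#' median-imputed for the forest fit and ignored pairwise in the
#' correlations. Deterministic given `seed`.
#'
#' @param table Cohort data.frame.
#' @param target Column name of the target (`"group"` for classification or
#'   a sleep-metric column for regression).
#' @param features Feature columns to rank (default the 16 summary
#'   features).
#' @param seed Integer seed for the forest.
#' @return Character vector: the features in selection order.
#' @export
mrmr_rank <- function(table, target = "group",
                      features = summary_feature_names(), seed = 1L) {
  if (length(features) < 1) stop("no features to rank")
  X <- table[, features, drop = FALSE]
  yv <- table[[target]]
  y <- if (is.character(yv) || is.factor(yv)) factor(yv) else as.numeric(yv)
  set.seed(seed)
  Ximp <- randomForest::na.roughfix(X)
  rf <- randomForest::randomForest(Ximp, y, importance = TRUE, ntree = 500)
  impm <- randomForest::importance(rf, type = 1, scale = FALSE)
  imp <- setNames(impm[, 1], rownames(impm))   # [, 1] drops names at p = 1
  imp[!is.finite(imp)] <- 0
  relevance <- imp[features]

  cm <- abs(suppressWarnings(cor(X, use = "pairwise.complete.obs")))
  cm[!is.finite(cm)] <- 0

  selected <- names(which.max(relevance))
  remaining <- setdiff(features, selected)
  while (length(remaining)) {
    red <- rowMeans(cm[remaining, selected, drop = FALSE])
    score <- relevance[remaining] - red
    nxt <- if (all(is.na(score))) remaining[1] else remaining[which.max(score)]
    selected <- c(selected, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  selected
}

# Stratified k-fold assignment over a factor.
strat_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(sample(seq_len(k)), length(idx))
  }
  fold
}

# Size-balanced subsample: every class reduced to the smallest class size.
balanced_subsample <- function(y) {
  tab <- table(y)
  m <- min(tab)
  unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    if (length(idx) > m) sample(idx, m) else idx
  }), use.names = FALSE)
}

macro_auc <- function(y, prob) {
  # one-vs-rest AUC, macro-averaged over classes
  aucs <- vapply(seq_along(levels(y)), function(ci) {
    lab <- as.integer(y == levels(y)[ci])
    if (length(unique(lab)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(lab, prob[, ci], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

balanced_accuracy <- function(y, pred) {
  mean(vapply(levels(y), function(cl) {
    sel <- y == cl
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] == cl)
  }, numeric(1)), na.rm = TRUE)
}

#' Sequential-inclusion repeated cross-validated classification
#'
#' For each prefix of the feature ordering, runs `n_repeats` repeats of
#' stratified `n_folds`-fold cross-validation of a gradient-boosted tree
#' classifier (learning rate 0.1, depth 6 for multiclass / 3 for binary,
#' 80%/80% subsampling, gamma 0.1). Each repeat uses one of
#' `n_subsamples` pre-drawn size-balanced subsamples (all classes reduced
#' to the smallest class size), cycled across repeats. Missing feature
#' values go to the trees' native missing-value routing.
#'
#' @param table Cohort data.frame with a `group` column.
#' @param feature_order Feature names, e.g. from [mrmr_rank()].
#' @param classes Class labels to keep (2 or 3 of them); default all.
#' @param n_features_grid Prefix sizes to evaluate (default all).
#' @param n_repeats,n_folds,n_subsamples,nrounds,seed Configuration
#'   (defaults 60 / 5 / 30 / 100).
#' @return A `performance_curve`: data.frame `summary` (n_features,
#'   balacc_mean, balacc_sd, auc_mean, auc_sd), matrix `scores` (repeats x
#'   prefixes, balanced accuracy), list `confusion` (mean confusion matrix
#'   per prefix; rows = true classes).
#' @export
sequential_cv_classify <- function(table, feature_order, classes = NULL,
                                   n_features_grid = NULL,
                                   n_repeats = 60, n_folds = 5,
                                   n_subsamples = 30, nrounds = 100,
                                   seed = 1L) {
  if (is.null(classes)) classes <- sort(unique(as.character(table$group)))
  table <- table[table$group %in% classes, , drop = FALSE]
  y_all <- factor(as.character(table$group), levels = classes)
  if (any(table(y_all) < n_folds))
    stop("every class needs at least n_folds subjects")
  if (is.null(n_features_grid)) n_features_grid <- seq_along(feature_order)

  set.seed(seed)
  pool <- lapply(seq_len(n_subsamples), function(i) balanced_subsample(y_all))

  scores <- matrix(NA_real_, n_repeats, length(n_features_grid))
  aucs <- matrix(NA_real_, n_repeats, length(n_features_grid))
  confusion <- lapply(n_features_grid, function(i)
    matrix(0, length(classes), length(classes),
           dimnames = list(classes, classes)))

  for (r in seq_len(n_repeats)) {
    set.seed(child_seed(seed, r))
    sub <- pool[[(r - 1) %% n_subsamples + 1]]
    ys <- droplevels(y_all[sub])
    fold <- strat_folds(ys, n_folds)
    for (gi in seq_along(n_features_grid)) {
      feats <- feature_order[seq_len(n_features_grid[gi])]
      Xs <- as.matrix(table[sub, feats, drop = FALSE])
      pred <- character(length(sub))
      prob <- matrix(NA_real_, length(sub), length(classes))
      for (f in seq_len(n_folds)) {
        tr <- fold != f; te <- fold == f
        prm <- cohort_params(length(classes), child_seed(seed, r * 100 + f),
                             nrounds)
        dtr <- xgboost::xgb.DMatrix(Xs[tr, , drop = FALSE],
                                    label = as.integer(ys[tr]) - 1,
                                    missing = NA)
        bst <- xgboost::xgb.train(params = prm, data = dtr,
                                  nrounds = nrounds, verbose = 0)
        p <- predict(bst, xgboost::xgb.DMatrix(Xs[te, , drop = FALSE],
                                               missing = NA))
        if (length(classes) == 2) p <- cbind(1 - p, p)
        if (!is.matrix(p)) p <- matrix(p, ncol = length(classes), byrow = TRUE)
        prob[te, ] <- p
        pred[te] <- classes[max.col(p, ties.method = "first")]
      }
      scores[r, gi] <- balanced_accuracy(ys, pred)
      aucs[r, gi] <- macro_auc(ys, prob)
      confusion[[gi]] <- confusion[[gi]] + table(factor(ys, levels = classes),
                                                 factor(pred, levels = classes))
    }
  }
  confusion <- lapply(confusion, function(m) m / n_repeats)
  structure(list(
    summary = data.frame(n_features = n_features_grid,
                         balacc_mean = colMeans(scores),
                         balacc_sd = apply(scores, 2, sd),
                         auc_mean = colMeans(aucs),
                         auc_sd = apply(aucs, 2, sd)),
    scores = scores, aucs = aucs, confusion = confusion,
    feature_order = feature_order, classes = classes),
    class = "performance_curve")
}

#' Saturation point of a performance curve
#'
#' Smallest prefix size k such that the rank-sum test between the
#' per-repeat score distributions at k and k+1 is non-significant at
#' `alpha`. A curve that keeps improving to the end returns the maximum
#' with a warning.
#'
#' @param curve A `performance_curve` (scores retained per repeat).
#' @param alpha Significance level (default 0.05).
#' @param higher_is_better `TRUE` for accuracy-type scores, `FALSE` for
#'   RMSE.
#' @return The selected number of features.
#' @export
select_feature_count <- function(curve, alpha = 0.05, higher_is_better = TRUE) {
  stopifnot(inherits(curve, "performance_curve"))
  sc <- curve$scores
  if (ncol(sc) < 2) stop("curve needs at least 2 prefix sizes")
  alt <- if (higher_is_better) "greater" else "less"
  for (k in seq_len(ncol(sc) - 1)) {
    p <- suppressWarnings(
      wilcox.test(sc[, k + 1], sc[, k], alternative = alt)$p.value)
    if (is.na(p) || p >= alpha) return(curve$summary$n_features[k])
  }
  warning("performance keeps improving at every step; returning the maximum")
  curve$summary$n_features[ncol(sc)]
}

#' Sex- and size-balanced subsample with KS-matched age and BMI
#'
#' Draws a subsample with exact sex balance and equal group sizes
#' (`n_female` females and `n_male` males per group) and accepts it iff
#' two-sample Kolmogorov-Smirnov tests between the groups give p > `alpha`
#' for age *and* BMI. Redraws up to `max_tries` times per accepted draw.
#'
#' @param table Cohort data.frame with `group`, `sex`, `age`, `bmi`.
#' @param group_a,group_b Group labels to match.
#' @param n_female,n_male Per-group sex counts (defaults 38 and 38, giving
#'   76 subjects per group).
#' @param alpha KS acceptance level (default 0.1).
#' @param n_draws Number of accepted subsamples to return (default 1; the
#'   batch analysis uses 500).
#' @param max_tries Attempt cap per accepted draw.
#' @param seed Integer seed.
#' @return For `n_draws = 1` a data.frame (the subsample); otherwise a list
#'   of data.frames.
#' @export
matched_subsample <- function(table, group_a, group_b, n_female = 38,
                              n_male = 38, alpha = 0.1, n_draws = 1,
                              max_tries = 1000, seed = 1L) {
  set.seed(seed)
  pools <- lapply(c(group_a, group_b), function(g) {
    fem <- which(table$group == g & table$sex == "F")
    mal <- which(table$group == g & table$sex == "M")
    if (length(fem) < n_female || length(mal) < n_male)
      stop("group ", g, " lacks the requested sex counts")
    list(fem = fem, mal = mal)
  })
  draws <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      idx <- unlist(lapply(pools, function(p)
        c(sample(p$fem, n_female), sample(p$mal, n_male))))
      sub <- table[idx, , drop = FALSE]
      a <- sub[sub$group == group_a, ]; b <- sub[sub$group == group_b, ]
      p_age <- suppressWarnings(ks.test(a$age, b$age)$p.value)
      p_bmi <- suppressWarnings(ks.test(a$bmi, b$bmi)$p.value)
      if (p_age > alpha && p_bmi > alpha) { ok <- TRUE; break }
    }
    if (!ok) stop("no acceptable matched subsample within ", max_tries, " tries")
    draws[[d]] <- sub
  }
  if (n_draws == 1) draws[[1]] else draws
}

#' Per-subject classification accuracy
#'
#' Fraction of test-set appearances in which each subject is correctly
#' classified across `n_iter` iterations of the size-balanced repeated
#' cross-validated binary classifier. 1 = always correct, 0 = never.
#'
#' @param table Binary cohort data.frame (exactly 2 group labels).
#' @param features Predictor columns.
#' @param n_iter Iterations (default 1000).
#' @param n_folds,n_subsamples,nrounds,seed Configuration.
#' @return Named numeric vector (by `subject_id`) in `[0, 1]`.
#' @export
subject_accuracy <- function(table, features = summary_feature_names(),
                             n_iter = 1000, n_folds = 5, n_subsamples = 30,
                             nrounds = 100, seed = 1L) {
  classes <- sort(unique(as.character(table$group)))
  if (length(classes) != 2) stop("subject_accuracy needs a binary table")
  y_all <- factor(as.character(table$group), levels = classes)
  set.seed(seed)
  pool <- lapply(seq_len(n_subsamples), function(i) balanced_subsample(y_all))
  hits <- setNames(numeric(nrow(table)), table$subject_id)
  seen <- setNames(numeric(nrow(table)), table$subject_id)
  for (r in seq_len(n_iter)) {
    set.seed(child_seed(seed, r))
    sub <- pool[[(r - 1) %% n_subsamples + 1]]
    ys <- droplevels(y_all[sub])
    Xs <- as.matrix(table[sub, features, drop = FALSE])
    fold <- strat_folds(ys, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- which(fold == f)
      prm <- cohort_params(2, child_seed(seed, r * 100 + f), nrounds)
      dtr <- xgboost::xgb.DMatrix(Xs[tr, , drop = FALSE],
                                  label = as.integer(ys[tr]) - 1, missing = NA)
      bst <- xgboost::xgb.train(params = prm, data = dtr,
                                nrounds = nrounds, verbose = 0)
      p <- predict(bst, xgboost::xgb.DMatrix(Xs[te, , drop = FALSE],
                                             missing = NA))
      pred <- classes[1 + as.integer(p > 0.5)]
      ids <- table$subject_id[sub[te]]
      hits[ids] <- hits[ids] + (pred == as.character(ys[te]))
      seen[ids] <- seen[ids] + 1
    }
  }
  out <- hits / seen
  out[seen == 0] <- NA_real_
  out
}

#' Sequential-inclusion repeated cross-validated regression
#'
#' RMSE per feature-count prefix over `n_repeats` repeats of 5-fold
#' cross-validated gradient-boosted regression (squared-error objective,
#' depth 6), plus per-subject mean out-of-fold predictions at the largest
#' prefix and their Pearson correlation with the true values.
#'
#' @param table Cohort data.frame (>= 20 subjects).
#' @param target One of `"tst_min"`, `"sol_min"`, `"waso_min"`, `"se_pct"`.
#' @param feature_order Feature names in inclusion order.
#' @param n_features_grid Prefix sizes (default all).
#' @param n_repeats,n_folds,nrounds,seed Configuration (default 120 / 5 /
#'   100).
#' @return A `performance_curve` with `summary` (n_features, rmse_mean,
#'   rmse_sd), `scores` (per-repeat RMSE), `predictions` (data.frame:
#'   subject_id, true, predicted) and `correlation`.
#' @export
sequential_cv_regress <- function(table, target, feature_order,
                                  n_features_grid = NULL, n_repeats = 120,
                                  n_folds = 5, nrounds = 100, seed = 1L) {
  if (!target %in% names(table)) stop("target column not found")
  if (nrow(table) < 20) stop("need at least 20 subjects")
  yv <- as.numeric(table[[target]])
  if (sd(yv) == 0) stop("constant target")
  if (is.null(n_features_grid)) n_features_grid <- seq_along(feature_order)

  scores <- matrix(NA_real_, n_repeats, length(n_features_grid))
  pred_sum <- numeric(nrow(table)); pred_n <- numeric(nrow(table))
  gmax <- which.max(n_features_grid)

  for (r in seq_len(n_repeats)) {
    set.seed(child_seed(seed, r))
    fold <- rep_len(sample(seq_len(n_folds)), nrow(table))
    for (gi in seq_along(n_features_grid)) {
      feats <- feature_order[seq_len(n_features_grid[gi])]
      Xs <- as.matrix(table[, feats, drop = FALSE])
      oof <- numeric(nrow(table))
      for (f in seq_len(n_folds)) {
        tr <- fold != f; te <- fold == f
        prm <- cohort_params(0, child_seed(seed, r * 100 + f), nrounds)
        dtr <- xgboost::xgb.DMatrix(Xs[tr, , drop = FALSE], label = yv[tr],
                                    missing = NA)
        bst <- xgboost::xgb.train(params = prm, data = dtr,
                                  nrounds = nrounds, verbose = 0)
        oof[te] <- predict(bst, xgboost::xgb.DMatrix(Xs[te, , drop = FALSE],
                                                     missing = NA))
      }
      scores[r, gi] <- sqrt(mean((oof - yv)^2))
      if (gi == gmax) { pred_sum <- pred_sum + oof; pred_n <- pred_n + 1 }
    }
  }
  predicted <- pred_sum / pred_n
  structure(list(
    summary = data.frame(n_features = n_features_grid,
                         rmse_mean = colMeans(scores),
                         rmse_sd = apply(scores, 2, sd)),
    scores = scores,
    predictions = data.frame(subject_id = table$subject_id, true = yv,
                             predicted = predicted),
    correlation = cor(predicted, yv),
    feature_order = feature_order, target = target),
    class = "performance_curve")
}

#' Group statistics on the summary features
#'
#' Per stage and metric: an omnibus Kruskal-Wallis test across groups plus
#' pairwise Wilcoxon rank-sum tests, all Bonferroni-corrected across the
#' full family of tests in the call. Effect direction reports which group
#' of each pair has the larger median.
#'
#' @param table Cohort data.frame (>= 2 groups, >= 5 subjects each).
#' @param metric `"H"` (entropy) or `"dKL"` (divergence); the `ave_`
#'   summary of that metric is tested.
#' @param stages Stages to test (default W, N2, N3, REM).
#' @return data.frame: stage, test, comparison, statistic, p_raw,
#'   p_bonferroni, direction.
#' @export
group_stats <- function(table, metric = c("H", "dKL"),
                        stages = c("W", "N2", "N3", "REM")) {
  metric <- match.arg(metric)
  groups <- sort(unique(as.character(table$group)))
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(table(table$group) < 5)) stop("every group needs >= 5 subjects")
  rows <- list()
  for (s in stages) {
    col <- paste0("ave_", metric, "_", s)
    vals <- table[[col]]; grp <- as.character(table$group)
    ok <- !is.na(vals)
    kw <- kruskal.test(vals[ok], factor(grp[ok]))
    rows[[length(rows) + 1]] <- data.frame(
      stage = s, test = "kruskal", comparison = "omnibus",
      statistic = unname(kw$statistic), p_raw = kw$p.value,
      direction = NA_character_)
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      a <- vals[ok & grp == groups[i]]; b <- vals[ok & grp == groups[j]]
      wt <- suppressWarnings(wilcox.test(a, b))
      dir <- if (median(a) >= median(b)) paste(groups[i], ">", groups[j])
             else paste(groups[j], ">", groups[i])
      rows[[length(rows) + 1]] <- data.frame(
        stage = s, test = "wilcoxon",
        comparison = paste(groups[i], "vs", groups[j]),
        statistic = unname(wt$statistic), p_raw = wt$p.value, direction = dir)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out
}
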