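test_that("MRMR penalizes redundancy and rewards relevance", {
  set.seed(1)
  n <- 120
  signal <- rnorm(n)
  tab <- data.frame(group = ifelse(signal + rnorm(n, 0, 0.5) > 0, "A", "B"),
                    s1 = signal,
                    s1_dup = signal,                    # exact duplicate
                    info = signal + rnorm(n, 0, 1),     # weaker but informative
                    noise = rnorm(n))
  rk <- mrmr_rank(tab, "group", features = c("s1", "s1_dup", "info", "noise"),
                  seed = 2)
  # one of the identical twins ranks first; the other is pushed back by its
  # redundancy penalty while an informative alternative remains
  expect_true(rk[1] %in% c("s1", "s1_dup"))
  expect_false(rk[2] %in% c("s1", "s1_dup"))

  rk2 <- mrmr_rank(tab, "group", features = c("s1", "noise"), seed = 2)
  expect_equal(rk2, c("s1", "noise"))

  expect_equal(mrmr_rank(tab, "group", features = "s1", seed = 2), "s1")
})

test_that("null cohorts classify at chance, planted effects above it", {
  tab0 <- make_summary_table(n_per_group = 100, groups = c("A", "B"), seed = 3)
  cv0 <- sequential_cv_classify(tab0, summary_feature_names(),
                                n_features_grid = 16, n_repeats = 60,
                                nrounds = 50, seed = 4)
  expect_equal(cv0$summary$auc_mean, 0.5, tolerance = 0.05 / 0.5)

  # a 1-SD shift of one feature has a Bayes-optimal AUC of
  # pnorm(1/sqrt(2)) ~ 0.76; the classifier should approach it
  tab1 <- make_summary_table(n_per_group = 100, groups = c("A", "B"),
                             shift = c(A = 0, B = 1), seed = 5)
  cv1 <- sequential_cv_classify(tab1, summary_feature_names(),
                                n_features_grid = 16, n_repeats = 20,
                                nrounds = 50, seed = 6)
  expect_gt(cv1$summary$auc_mean, 0.65)

  # a 2-SD shift is comfortably above 0.8
  tab2 <- make_summary_table(n_per_group = 100, groups = c("A", "B"),
                             shift = c(A = 0, B = 2), seed = 15)
  cv2 <- sequential_cv_classify(tab2, summary_feature_names(),
                                n_features_grid = 16, n_repeats = 20,
                                nrounds = 50, seed = 16)
  expect_gt(cv2$summary$auc_mean, 0.8)

  # confusion-matrix rows sum to the per-class test counts
  expect_equal(unname(rowSums(cv0$confusion[[1]])), c(100, 100))
})

test_that("a perfectly separating feature reaches near-perfect accuracy", {
  tab <- make_summary_table(n_per_group = 50, groups = c("A", "B"), seed = 7)
  tab$ave_H_W <- ifelse(tab$group == "A", rnorm(100, -3), rnorm(100, 3))
  cv <- sequential_cv_classify(tab, "ave_H_W", n_features_grid = 1,
                               n_repeats = 10, nrounds = 50, seed = 8)
  expect_gte(cv$summary$balacc_mean, 0.98)
})

fake_curve <- function(score_list) {
  structure(list(scores = do.call(cbind, score_list),
                 summary = data.frame(n_features = seq_along(score_list))),
            class = "performance_curve")
}

test_that("the saturation rule picks the first non-improving prefix", {
  set.seed(9)
  flat <- rnorm(60)
  expect_equal(select_feature_count(fake_curve(list(flat, flat + rnorm(60, 0, 1e-6),
                                                    flat))), 1)
  improving <- list(rnorm(60, 0.5, 0.02), rnorm(60, 0.8, 0.02),
                    rnorm(60, 0.8, 0.02), rnorm(60, 0.8, 0.02))
  expect_equal(select_feature_count(fake_curve(improving)), 2)
  strictly <- lapply(1:4, function(k) rnorm(60, 0.2 * k, 0.01))
  expect_warning(k <- select_feature_count(fake_curve(strictly)), "maximum")
  expect_equal(k, 4)
})

test_that("matched subsampling balances sex and size under a KS gate", {
  set.seed(10)
  tab <- make_summary_table(n_per_group = 120, groups = c("A", "B"), seed = 11)
  tab$sex <- rep(c("F", "M"), 120)
  sub <- matched_subsample(tab, "A", "B", n_female = 38, n_male = 38, seed = 12)
  expect_equal(as.vector(table(sub$group)), c(76L, 76L))
  expect_equal(sum(sub$group == "A" & sub$sex == "F"), 38L)

  # identical distributions: most first draws are accepted
  accepted_first <- mean(sapply(1:50, function(s) {
    tryCatch({
      matched_subsample(tab, "A", "B", n_female = 30, n_male = 30,
                        max_tries = 1, seed = s)
      TRUE
    }, error = function(e) FALSE)
  }))
  expect_gt(accepted_first, 0.5)

  # disjoint age ranges can never pass the KS gate
  tab$age <- ifelse(tab$group == "A", runif(240, 20, 30), runif(240, 60, 70))
  expect_error(matched_subsample(tab, "A", "B", n_female = 30, n_male = 30,
                                 max_tries = 20, seed = 13),
               "no acceptable matched subsample")
})

test_that("subject accuracy is a proportion that tracks separability", {
  set.seed(14)
  tab <- make_summary_table(n_per_group = 40, groups = c("A", "B"), seed = 15)
  feats <- summary_feature_names()
  for (fc in feats) tab[[fc]] <- rnorm(80) + ifelse(tab$group == "A", -1.5, 1.5)
  # plant one subject exactly at its class centroid
  tab[1, feats] <- -1.5
  acc <- subject_accuracy(tab, n_iter = 60, nrounds = 40, seed = 16)
  expect_true(all(acc >= 0 & acc <= 1, na.rm = TRUE))
  expect_gt(acc[[tab$subject_id[1]]], 0.9)

  # label-shuffled cohort: mean accuracy at chance
  tabn <- tab
  set.seed(17)
  tabn$group <- sample(tabn$group)
  for (fc in feats) tabn[[fc]] <- rnorm(80)
  accn <- subject_accuracy(tabn, n_iter = 60, nrounds = 40, seed = 18)
  expect_equal(mean(accn, na.rm = TRUE), 0.5, tolerance = 0.05 / 0.5)
})

test_that("regression recovers a planted functional dependence", {
  tab <- make_summary_table(n_per_group = 40, groups = c("A", "B"), seed = 19)
  tab$waso_min <- 10 + 25 * tab$ave_H_W          # noiseless function
  cv <- sequential_cv_regress(tab, "waso_min", summary_feature_names(),
                              n_features_grid = 16, n_repeats = 20,
                              nrounds = 100, seed = 20)
  expect_gt(cv$correlation, 0.95)

  # independent target: correlation compatible with zero
  set.seed(21)
  tab$sol_min <- rnorm(80, 30, 10)
  cv0 <- sequential_cv_regress(tab, "sol_min", summary_feature_names(),
                               n_features_grid = 16, n_repeats = 20,
                               nrounds = 100, seed = 22)
  expect_lt(abs(cv0$correlation), 0.15)

  # pure-noise features after the signal feature barely change the RMSE
  ord <- c("ave_H_W", setdiff(summary_feature_names(), "ave_H_W"))
  cv2 <- sequential_cv_regress(tab, "waso_min", ord,
                               n_features_grid = c(1, 16), n_repeats = 10,
                               nrounds = 100, seed = 23)
  expect_gt(cv2$summary$rmse_mean[2] / cv2$summary$rmse_mean[1], 0.95)

  tab$se_pct <- 85
  expect_error(sequential_cv_regress(tab, "se_pct", summary_feature_names()),
               "constant target")
})

test_that("group statistics control the familywise error and detect effects", {
  # type-I control: fraction of null cohorts with any corrected p < 0.05
  reject <- sapply(1:100, function(s) {
    tab <- make_summary_table(n_per_group = 30, groups = c("A", "B", "C"),
                              seed = 1000 + s)
    st <- group_stats(tab, "H")
    any(st$p_bonferroni < 0.05)
  })
  expect_lte(mean(reject), 0.05)

  # power: a 1.5-pooled-SD wake-entropy shift at n = 50 is detected
  detected <- sapply(1:20, function(s) {
    tab <- make_summary_table(n_per_group = 50, groups = c("A", "B"),
                              shift = c(A = 0, B = 1.5), seed = 2000 + s)
    st <- group_stats(tab, "H")
    w <- st$stage == "W" & st$test == "wilcoxon"
    st$p_bonferroni[w] < 0.001
  })
  expect_gte(mean(detected), 0.9)

  # Bonferroni is a plain multiplication, capped at 1
  tab <- make_summary_table(n_per_group = 10, groups = c("A", "B"), seed = 24)
  st <- group_stats(tab, "dKL")
  expect_equal(st$p_bonferroni, pmin(1, st$p_raw * nrow(st)))
})

test_that("subjects near the diagnostic threshold are misclassified most", {
  # latent severity thresholded at 0 defines the groups; features carry
  # severity plus noise, so boundary subjects are the ambiguous ones
  set.seed(26)
  n <- 80
  sev <- rnorm(n)
  tab <- make_summary_table(n_per_group = n / 2, groups = c("A", "B"), seed = 27)
  tab$group <- ifelse(sev > 0, "A", "B")
  for (fc in summary_feature_names()) tab[[fc]] <- sev + rnorm(n, 0, 0.8)
  acc <- subject_accuracy(tab, n_iter = 60, nrounds = 40, seed = 28)
  ct <- suppressWarnings(
    stats::cor.test(acc[tab$subject_id], abs(sev), method = "spearman",
                    alternative = "greater"))
  expect_lt(ct$p.value, 0.01)
})
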