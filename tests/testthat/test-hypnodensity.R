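test_that("separable clusters yield near-perfect confident staging", {
  f <- make_separable_features(n_per_stage = 50, seed = 2)
  hd <- fit_hypnodensity(f, k = 10, seed = 3)
  expect_true(all(abs(rowSums(hd$probs) - 1) < 1e-9))
  expect_true(all(hd$probs >= 0))
  expect_gt(hd$balanced_accuracy, 0.95)
  expect_gt(mean(apply(hd$probs, 1, max)), 0.8)
  # the hypnodensity argmax matches the expert stage on average
  for (s in stage_levels())
    expect_equal(names(which.max(table(
      hd$predicted_stage[hd$expert_stage == s]))), s)
})

test_that("permuted labels give chance-level balanced accuracy", {
  f <- make_separable_features(n_per_stage = 30, seed = 4)
  accs <- sapply(1:20, function(s) {
    set.seed(s)
    fp <- f
    fp$stage_labels <- sample(f$stage_labels)
    fit_hypnodensity(fp, k = 5, nrounds = 30, seed = s)$balanced_accuracy
  })
  expect_equal(mean(accs), 0.2, tolerance = 0.1 / 0.2)
})

test_that("k_fold(n) reproduces leave-one-out exactly", {
  f <- make_separable_features(n_per_stage = 12, seed = 5)  # 60 epochs
  hd_k <- fit_hypnodensity(f, scheme = "k_fold", k = 60, nrounds = 20, seed = 6)
  hd_loo <- fit_hypnodensity(f, scheme = "leave_one_out", nrounds = 20, seed = 6)
  expect_identical(hd_k$probs, hd_loo$probs)
  expect_identical(hd_k$balanced_accuracy, hd_loo$balanced_accuracy)
})

test_that("single-stage subjects cannot be staged", {
  f <- make_separable_features(n_per_stage = 10)
  f$stage_labels <- rep("N2", length(f$stage_labels))
  expect_error(fit_hypnodensity(f), "only one stage")
})

test_that("QC excludes strictly below threshold", {
  expect_message(d1 <- qc_exclude(fake_hd(0.39)), "exclude")
  expect_equal(d1, "exclude")
  expect_equal(suppressMessages(qc_exclude(fake_hd(0.41))), "keep")
  # boundary: exactly 0.40 is kept ("lower than" is strict)
  expect_equal(suppressMessages(qc_exclude(fake_hd(0.40))), "keep")
})

test_that("hypnodensity CSV round-trips the probabilities", {
  f <- make_separable_features(n_per_stage = 10, seed = 7)
  hd <- fit_hypnodensity(f, k = 5, nrounds = 20, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hypnodensity_csv(hd, path)
  back <- read.csv(path)
  expect_equal(names(back),
               c("epoch_index", "expert_stage", "p_W", "p_N1", "p_N2", "p_N3", "p_REM"))
  expect_equal(as.matrix(back[, 3:7]), hd$probs,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("injected intrusion raises hypnodensity entropy within a stage", {
  # one subject whose wake epochs come in two flavors: no mixing vs
  # lambda = 0.5 sleep-profile mixing; sleep epochs shared
  st <- c(rep("W", 40), rep("N2", 40), rep("N3", 40))
  h <- hypnogram(st)
  g0 <- group_spec("lo", 1, diag(5), wake_sleep_intrusion = 0)
  g5 <- group_spec("hi", 1, diag(5), wake_sleep_intrusion = 0.5)
  r0 <- simulate_recording(h, g0, fs = 128, seed = 41)
  r5 <- simulate_recording(h, g5, fs = 128, seed = 42)
  # combined recording: first 20 wake epochs pure, next 20 mixed
  comb <- r0
  spe <- 30 * 128
  mixed_cols <- (20 * spe + 1):(40 * spe)
  comb$signal[, mixed_cols] <- r5$signal[, mixed_cols]
  eps <- make_epochs(suppressMessages(preprocess(comb)), h)
  hd <- fit_hypnodensity(extract_features(eps), k = 10, seed = 43)
  ent <- apply(hd$probs, 1, entropy)
  expect_gt(mean(ent[21:40]), mean(ent[1:20]))
})
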