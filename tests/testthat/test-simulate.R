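absorbing_tm <- function() diag(5) |> (\(m) {dimnames(m) <- list(stage_levels(), stage_levels()); m})()

test_that("hypnogram simulation follows the Markov chain", {
  # absorbing chain: identity matrix keeps the initial stage forever
  h <- simulate_hypnogram(absorbing_tm(), 10, "W", seed = 3)
  expect_equal(h$stages, rep("W", 10))

  # determinism contract
  P <- default_group_specs(1)[[1]]$transition_matrix
  expect_identical(simulate_hypnogram(P, 200, seed = 9)$stages,
                   simulate_hypnogram(P, 200, seed = 9)$stages)

  # invalid inputs
  bad <- P; bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(simulate_hypnogram(bad, 10), "sum to 1")
  expect_error(simulate_hypnogram(P, 1), "n_epochs")
})

test_that("empirical self-transition frequency matches the chain", {
  # 2-state W<->N2 chain with self-transition 0.9
  P <- absorbing_tm()
  P["W", ] <- c(0.9, 0, 0.1, 0, 0)
  P["N2", ] <- c(0.1, 0, 0.9, 0, 0)
  h <- simulate_hypnogram(P, 10000, "W", seed = 4)
  st <- h$stages
  self_freq <- mean(st[-1] == st[-length(st)])
  expect_equal(self_freq, 0.9, tolerance = 0.01 / 0.9)
})

test_that("recordings are deterministic and reject unknown stages", {
  g <- default_group_specs(1)[[2]]
  h <- simulate_hypnogram(g$transition_matrix, 10, seed = 2)
  r1 <- simulate_recording(h, g, fs = 64, seed = 77)
  r2 <- simulate_recording(h, g, fs = 64, seed = 77)
  expect_identical(r1$signal, r2$signal)
  expect_equal(ncol(r1$signal), 10 * 30 * 64)
  expect_equal(r1$channels$role, c("EEG", "EEG", "EOG"))

  h_bad <- hypnogram(c(rep("N2", 5), "INVALID"))
  expect_error(simulate_recording(h_bad, g, fs = 64), "unknown or INVALID")
})

test_that("band structure: N3 is delta-dominant and wake delta grows with intrusion", {
  # noise-free band structure: jitter off, all mixing weights zero
  g0 <- group_spec("pure", 1, default_group_specs(1)[[1]]$transition_matrix)
  st <- c(rep("N3", 20), rep("W", 20))
  h <- hypnogram(st)
  rec <- simulate_recording(h, g0, fs = 128, seed = 5, profile_jitter_sd = 0)
  eps <- make_epochs(rec, h)
  bp <- epoch_psd(eps)
  d_n3 <- mean(bp$fractions[bp$stage_labels == "N3", , "delta"])
  d_w <- mean(bp$fractions[bp$stage_labels == "W", , "delta"])
  expect_gt(d_n3, d_w)
  expect_gt(d_n3, 0.5)

  # paired comparison: same seeds, increasing sleep-into-wake mixing
  h_w <- hypnogram(rep("W", 30))
  mean_delta <- sapply(c(0, 0.25, 0.5), function(lam) {
    vals <- sapply(1:8, function(s) {
      g <- group_spec("g", 1, g0$transition_matrix, wake_sleep_intrusion = lam)
      r <- simulate_recording(h_w, g, fs = 128, seed = 100 + s,
                              profile_jitter_sd = 0)
      e <- make_epochs(r, h_w)
      mean(epoch_psd(e)$fractions[, , "delta"])
    })
    mean(vals)
  })
  expect_true(all(diff(mean_delta) > 0))
})

test_that("cohorts are reproducible with metadata consistent with hypnograms", {
  specs <- default_group_specs(1)
  co <- simulate_cohort(specs, epochs_per_subject = 60, fs = 64, seed = 21)
  co2 <- simulate_cohort(specs, epochs_per_subject = 60, fs = 64, seed = 21)
  expect_length(co, 3)
  expect_identical(co[[2]]$recording$signal, co2[[2]]$recording$signal)
  expect_identical(co[[3]]$metadata, co2[[3]]$metadata)

  for (s in co) {
    m <- sleep_metrics_from_hypnogram(s$hypnogram)
    expect_equal(s$metadata$waso_min, unname(m["waso_min"]), tolerance = 0.5)
    expect_equal(s$metadata$tst_min, unname(m["tst_min"]), tolerance = 0.5)
    expect_equal(s$metadata$se_pct, unname(m["se_pct"]), tolerance = 0.5)
    nsamp <- ncol(s$recording$signal)
    expect_equal(nsamp, length(s$hypnogram$stages) * 30 * s$recording$fs)
  }
  expect_error(simulate_cohort(list(), 60), "empty")
  expect_error(simulate_cohort(specs, 30), "epochs_per_subject")
})
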