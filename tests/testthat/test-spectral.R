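sine_epoch_set <- function(freq, n_epochs = 2, fs = 128) {
  spe <- 30 * fs
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  arr <- array(0, dim = c(n_epochs, 1, spe))
  for (i in seq_len(n_epochs)) arr[i, 1, ] <- sin(2 * pi * freq * tt)
  structure(list(epochs = arr, stage_labels = rep("N2", n_epochs),
                 original_indices = seq_len(n_epochs), fs = fs,
                 channel_labels = "C3", channel_roles = "EEG"),
            class = "epoch_set")
}

test_that("a pure 2 Hz tone concentrates in the delta band", {
  bp <- epoch_psd(sine_epoch_set(2))
  expect_gt(bp$fractions[1, 1, "delta"], 0.95)
})

test_that("band fractions tile the grid and match white-noise bandwidth shares", {
  eps <- make_epoch_set(n_epochs = 200, channels = "C3", spe = 30 * 128,
                        fs = 128, stages = rep("N2", 200), seed = 8)
  bp <- epoch_psd(eps)
  sums <- apply(bp$fractions, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # flat spectrum: each band's share ~ its bandwidth over the 39.5 Hz span
  shares <- colMeans(bp$fractions[, 1, ])
  widths <- vapply(band_definitions(), diff, numeric(1))
  expected <- widths / 39.5
  expect_true(all(abs(shares - expected) / expected < 0.2))
})

test_that("the common grid makes band fractions rate-invariant", {
  g0 <- group_spec("pure", 1, diag(5))
  h <- hypnogram(rep("N2", 100))
  fr <- lapply(c(128, 256), function(fs) {
    r <- simulate_recording(h, g0, fs = fs, seed = 31, profile_jitter_sd = 0)
    colMeans(epoch_psd(make_epochs(r, h))$fractions[, 1, ])
  })
  expect_true(all(abs(fr[[1]] - fr[[2]]) < 0.05))
  expect_lt(abs(fr[[1]]["delta"] - fr[[2]]["delta"]) / fr[[2]]["delta"], 0.1)
})

test_that("self-transition probabilities follow the counted pairs", {
  expect_equal(self_transition(hypnogram(rep("W", 10)))["W", "W"], 1)
  alt <- self_transition(hypnogram(rep(c("W", "N2"), 10)))
  expect_equal(alt["W", "W"], 0)
  expect_equal(alt["N2", "N2"], 0)
  m <- self_transition(hypnogram(c("W", "W", "N2", "W")))
  expect_equal(m["W", "W"], 0.5)
  expect_equal(m["N2", "N2"], 0)
  # INVALID-adjacent pairs are skipped
  mi <- self_transition(hypnogram(c("W", "INVALID", "W", "W")))
  expect_equal(mi["W", "W"], 1)
  expect_true(all(is.na(mi["N2", ])))
})

test_that("degenerate inputs give missing correlations", {
  pr <- matrix(rep(c(0.6, 0.1, 0.1, 0.1, 0.1), 20), 20, byrow = TRUE,
               dimnames = list(NULL, stage_levels()))
  hd <- structure(list(probs = pr, expert_stage = rep("N2", 20),
                       original_indices = 1:20), class = "hypnodensity")
  ser <- compute_series(hd)
  eps <- make_epoch_set(n_epochs = 20, channels = "C3", spe = 512, fs = 128,
                        stages = rep("N2", 20))
  bp <- epoch_psd(eps)
  # constant entropy: correlation undefined
  expect_true(is.na(correlate_entropy_power(ser, bp, "N2", "delta")))
  # too few epochs of the stage
  expect_true(is.na(correlate_entropy_power(ser, bp, "W", "delta")))
  # identical consecutive hypnodensities: zero-variance divergence
  expect_true(is.na(correlate_instability_deltapsd(ser, bp, "N2", "delta")))
})

test_that("instability/self-transition correlation table is well-formed", {
  set.seed(9)
  tab <- make_summary_table(n_per_group = 20, groups = c("A", "B"))
  st <- runif(40, 0.5, 1)
  tab$ave_dKL_W <- 2 - st + rnorm(40, 0, 0.1)   # planted negative coupling
  out <- correlate_instability_selftransition(tab, st)
  expect_equal(out$scope, c("overall", "A", "B"))
  expect_true(all(abs(out$r) <= 1, na.rm = TRUE))
  expect_lt(out$r[1], 0)
  expect_equal(out$p_bonferroni, pmin(1, out$p_raw * 3))
})
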