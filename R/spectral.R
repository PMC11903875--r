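# Spectral interpretation: multitaper band powers on the common frequency
# grid, their relation to the information-theoretic metrics, and empirical
# stage-transition structure.

#' Multitaper band-power table for an epoch set
#'
#' Per epoch and channel: a multitaper PSD (sine tapers, 7 tapers, uniform
#' weights) interpolated onto the common 0.5-40 Hz grid at 0.5 Hz steps and
#' normalized to sum 1, then summed into the six canonical bands
#' (half-open `[low, high)` bins; gamma closed at 40 Hz). Because the bands
#' tile the grid, the six fractions sum to 1 for every epoch, and the grid
#' is identical across subjects regardless of native sampling rate.
#'
#' @param epochs An `epoch_set` (preprocessed; `fs > 80` Hz).
#' @param n_tapers Number of sine tapers (default 7).
#' @return A `band_power_table`: `fractions` (array
#'   `n_epochs x n_channels x 6`), `psd` (normalized PSD array on the
#'   grid), `grid`, `stage_labels`, `original_indices`, `channel_labels`.
#' @export
epoch_psd <- function(epochs, n_tapers = 7) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$fs
  if (fs <= 80) stop("fs must exceed 80 Hz")
  d <- dim(epochs$epochs)
  spe <- d[3]
  grid <- seq(0.5, 40, by = 0.5)
  gband <- band_of(grid)

  # sine tapers, columns orthonormal
  tt <- seq_len(spe)
  tapers <- sapply(seq_len(n_tapers), function(k)
    sqrt(2 / (spe + 1)) * sin(pi * k * tt / (spe + 1)))
  native_freq <- (0:(floor(spe / 2))) * fs / spe

  fractions <- array(NA_real_, dim = c(d[1], d[2], 6),
                     dimnames = list(NULL, epochs$channel_labels, names(BANDS)))
  psd <- array(NA_real_, dim = c(d[1], d[2], length(grid)))
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      x <- epochs$epochs[i, ch, ]
      X <- stats::mvfft(tapers * x)
      S <- rowMeans(Mod(X[seq_along(native_freq), , drop = FALSE])^2)
      Sg <- approx(native_freq, S, xout = grid, rule = 2)$y
      Sg <- Sg / sum(Sg)
      psd[i, ch, ] <- Sg
      fractions[i, ch, ] <- vapply(1:6, function(b) sum(Sg[gband == b]), numeric(1))
    }
  }
  structure(list(fractions = fractions, psd = psd, grid = grid,
                 stage_labels = epochs$stage_labels,
                 original_indices = epochs$original_indices,
                 channel_labels = epochs$channel_labels),
            class = "band_power_table")
}

band_index <- function(band) {
  b <- match(band, names(BANDS))
  if (is.na(b)) stop("unknown band: ", band)
  b
}

#' Correlate epoch entropy with band power within a stage
#'
#' Pearson (or Spearman) correlation between the per-epoch hypnodensity
#' entropy and the per-epoch band fraction, restricted to epochs of one
#' expert stage. Computed per channel; the headline value is the channel
#' mean.
#'
#' @param series An `info_metric_series` from [compute_series()].
#' @param bands A `band_power_table` from [epoch_psd()].
#' @param stage Stage label.
#' @param band Band name (e.g. `"delta"`).
#' @param min_epochs Minimum epochs of the stage (default 10); fewer gives `NA`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Channel-mean correlation with attribute `per_channel`.
#' @export
correlate_entropy_power <- function(series, bands, stage, band,
                                    min_epochs = 10, method = "pearson") {
  stopifnot(inherits(series, "info_metric_series"),
            inherits(bands, "band_power_table"))
  b <- band_index(band)
  sel <- series$epochs$stage == stage
  if (sum(sel) < min_epochs) return(structure(NA_real_, per_channel = NULL))
  rows <- match(series$epochs$epoch_index[sel], bands$original_indices)
  h <- series$epochs$entropy_bits[sel]
  per_ch <- vapply(seq_along(bands$channel_labels), function(ch) {
    f <- bands$fractions[rows, ch, b]
    if (sd(h) == 0 || sd(f) == 0) return(NA_real_)
    cor(h, f, method = method)
  }, numeric(1))
  names(per_ch) <- bands$channel_labels
  structure(mean(per_ch, na.rm = FALSE), per_channel = per_ch)
}

#' Correlate instability with the epoch-to-epoch band-power change
#'
#' For every qualifying adjacent same-stage pair, relates the divergence
#' `D_KL(P_t || P_t+1)` to the band-fraction difference
#' `PSD(t) - PSD(t+1)`.
#'
#' @inheritParams correlate_entropy_power
#' @param min_pairs Minimum qualifying pairs (default 10).
#' @return Channel-mean correlation with attribute `per_channel`.
#' @export
correlate_instability_deltapsd <- function(series, bands, stage, band,
                                           min_pairs = 10, method = "pearson") {
  stopifnot(inherits(series, "info_metric_series"),
            inherits(bands, "band_power_table"))
  b <- band_index(band)
  sel <- series$pairs$stage == stage
  if (sum(sel) < min_pairs) return(structure(NA_real_, per_channel = NULL))
  t1 <- match(series$pairs$epoch_index[sel], bands$original_indices)
  t2 <- match(series$pairs$epoch_index[sel] + 1L, bands$original_indices)
  dkl <- series$pairs$dkl_bits[sel]
  per_ch <- vapply(seq_along(bands$channel_labels), function(ch) {
    dpsd <- bands$fractions[t1, ch, b] - bands$fractions[t2, ch, b]
    if (sd(dkl) == 0 || sd(dpsd) == 0) return(NA_real_)
    cor(dkl, dpsd, method = method)
  }, numeric(1))
  names(per_ch) <- bands$channel_labels
  structure(mean(per_ch, na.rm = FALSE), per_channel = per_ch)
}

#' Empirical stage-transition matrix of a hypnogram
#'
#' Transition counts over adjacent valid-epoch pairs, row-normalized.
#' Pairs adjacent to an INVALID epoch are skipped. Rows with no outgoing
#' transitions are `NA`.
#'
#' @param hypno A [hypnogram()].
#' @return 5x5 matrix with stage dimnames; diagonal = self-transitions.
#' @export
self_transition <- function(hypno) {
  stopifnot(inherits(hypno, "hypnogram"))
  st <- hypno$stages
  n <- length(st)
  if (sum(st %in% STAGES) < 2) stop("need at least 2 valid epochs")
  counts <- matrix(0, 5, 5, dimnames = list(STAGES, STAGES))
  for (t in seq_len(n - 1)) {
    if (st[t] %in% STAGES && st[t + 1] %in% STAGES)
      counts[st[t], st[t + 1]] <- counts[st[t], st[t + 1]] + 1
  }
  rs <- rowSums(counts)
  out <- counts / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' Correlate wake instability with wake self-transition across subjects
#'
#' Pearson correlation between each subject's average wake divergence
#' (`ave_dKL_W`) and wake self-transition probability, overall and per
#' group, with Bonferroni-corrected p-values (family = all correlations in
#' the call).
#'
#' @param table Cohort data.frame containing `ave_dKL_W` and `group`.
#' @param self_transitions Numeric vector of per-subject wake
#'   self-transition probabilities, aligned with `table` rows.
#' @return data.frame with scope (`overall` or group name), `r`, `n`,
#'   `p_raw`, `p_bonferroni`.
#' @export
correlate_instability_selftransition <- function(table, self_transitions) {
  if (nrow(table) < 10) stop("need at least 10 subjects")
  scopes <- c("overall", unique(as.character(table$group)))
  res <- lapply(scopes, function(sc) {
    sel <- if (sc == "overall") rep(TRUE, nrow(table)) else table$group == sc
    x <- table$ave_dKL_W[sel]; y <- self_transitions[sel]
    ok <- complete.cases(x, y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(data.frame(scope = sc, r = NA_real_, n = sum(ok), p_raw = NA_real_))
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(scope = sc, r = unname(ct$estimate), n = sum(ok),
               p_raw = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p_raw * sum(!is.na(out$p_raw)))
  out
}
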