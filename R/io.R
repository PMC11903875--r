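# Recording + hypnogram ingestion, preprocessing (mastoid re-reference and
# zero-phase FIR band-pass) and valid-stage 30-s epoching.

#' Read a recording and its hypnogram
#'
#' Reads an EDF file and a stage CSV, infers channel roles from labels, and
#' reconciles lengths: a hypnogram longer than the signal is truncated, a
#' shorter one padded with INVALID epochs (both with a message).
#'
#' @param path EDF file.
#' @param hypnogram_path Hypnogram CSV (`epoch_index,stage`, 0-based).
#' @param aliases Stage-label aliases for the CSV.
#' @param ... Passed to [read_edf()] (channel-role configuration).
#' @return List with elements `recording` and `hypnogram`.
#' @export
read_recording <- function(path, hypnogram_path,
                           aliases = default_stage_aliases(), ...) {
  rec <- read_edf(path, ...)
  if (!any(rec$channels$role %in% c("EEG", "EOG")))
    stop("no usable channels: recording has no EEG or EOG channel")
  hyp <- read_hypnogram_csv(hypnogram_path, aliases = aliases)
  n_sig <- floor(ncol(rec$signal) / (30 * rec$fs))
  n_hyp <- length(hyp$stages)
  if (n_hyp > n_sig) {
    message("hypnogram longer than signal by ", n_hyp - n_sig,
            " epochs; extra entries dropped")
    hyp <- hypnogram(hyp$stages[seq_len(n_sig)])
  } else if (n_hyp < n_sig) {
    message("hypnogram shorter than signal by ", n_sig - n_hyp,
            " epochs; padded with INVALID")
    hyp <- hypnogram(c(hyp$stages, rep("INVALID", n_sig - n_hyp)))
  }
  list(recording = rec, hypnogram = hyp)
}

# Contralateral mastoid for a 10-20 label: odd-numbered (left) electrodes
# reference the right mastoid (M2/A2) and vice versa.
contralateral_mastoid <- function(label, mastoids) {
  num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", label)))
  if (is.na(num)) return(NA_character_)
  want <- if (num %% 2 == 1) c("M2", "A2") else c("M1", "A1")
  hit <- intersect(want, toupper(mastoids))
  if (length(hit)) mastoids[match(hit[1], toupper(mastoids))] else NA_character_
}

#' Preprocess a recording
#'
#' Re-references EEG channels to their contralateral mastoid when mastoid
#' channels (M1/M2/A1/A2) are present (otherwise the signal passes through
#' unchanged, with a message), then applies a zero-phase FIR band-pass
#' filter. The filter is a linear-phase Hamming-window design with a 0.5 Hz
#' transition band, applied forward and backward so the net phase response
#' is exactly zero.
#'
#' @param recording A `psg_recording` with `fs > 80` Hz.
#' @param lowcut,highcut Band edges in Hz (defaults 0.5 and 40).
#' @return The filtered `psg_recording`.
#' @export
preprocess <- function(recording, lowcut = 0.5, highcut = 40) {
  stopifnot(inherits(recording, "psg_recording"))
  fs <- recording$fs
  if (fs <= 80) stop("fs must exceed 80 Hz for a meaningful 40 Hz band edge")
  labels <- recording$channels$label
  mast_idx <- which(toupper(labels) %in% c("M1", "M2", "A1", "A2"))
  if (length(mast_idx)) {
    for (ch in which(recording$channels$role == "EEG")) {
      ref <- contralateral_mastoid(labels[ch], labels[mast_idx])
      if (!is.na(ref)) {
        recording$signal[ch, ] <- recording$signal[ch, ] -
          recording$signal[match(ref, labels), ]
        recording$channels$reference[ch] <- ref
      }
    }
  } else {
    message("no mastoid channels present; skipping re-referencing")
  }
  b <- bandpass_fir(fs, lowcut, highcut)
  for (ch in seq_len(nrow(recording$signal)))
    recording$signal[ch, ] <- filtfilt_fft(b, recording$signal[ch, ])
  recording
}

# Hamming-window linear-phase FIR band-pass; order from the Hamming design
# rule for a 0.5 Hz transition band.
bandpass_fir <- function(fs, lowcut, highcut) {
  trans <- 0.5
  ord <- ceiling(3.3 * fs / trans)
  if (ord %% 2 == 1) ord <- ord + 1          # even order, odd length
  signal::fir1(ord, c(lowcut, highcut) / (fs / 2), type = "pass")
}

# Zero-phase filtering via FFT: multiplying the zero-padded spectrum by
# |B(w)|^2 is exactly forward-backward linear convolution with b.
filtfilt_fft <- function(b, x) {
  n <- length(x)
  ntap <- length(b)
  nfft <- 2^ceiling(log2(n + 2 * ntap))
  B <- fft(c(b, numeric(nfft - ntap)))
  X <- fft(c(x, numeric(nfft - n)))
  y <- Re(fft(X * (B * Conj(B)), inverse = TRUE)) / nfft
  # |B|^2 is zero-phase, so the output is aligned with the input
  y[seq_len(n)]
}

#' Cut a recording into valid-stage 30-s epochs
#'
#' Consecutive non-overlapping 30-s windows from sample 1; a trailing
#' partial window is discarded; epochs whose stage is INVALID are excluded;
#' only EEG and EOG channels are carried.
#'
#' @param recording A preprocessed `psg_recording`.
#' @param hypno The matching [hypnogram()].
#' @return An `epoch_set`: `epochs` (array `n_valid x channels x samples`),
#'   `stage_labels`, `original_indices` (1-based positions in the full
#'   hypnogram), `fs`, `channel_labels`, `channel_roles`.
#' @export
make_epochs <- function(recording, hypno) {
  stopifnot(inherits(recording, "psg_recording"), inherits(hypno, "hypnogram"))
  fs <- recording$fs
  spe <- as.integer(30 * fs)
  keep_ch <- which(recording$channels$role %in% c("EEG", "EOG"))
  if (!length(keep_ch)) stop("no EEG or EOG channels")
  n_full <- floor(ncol(recording$signal) / spe)
  n <- min(n_full, length(hypno$stages))
  valid <- which(hypno$stages[seq_len(n)] %in% STAGES)
  if (!length(valid)) stop("zero valid epochs")
  arr <- array(0, dim = c(length(valid), length(keep_ch), spe))
  for (i in seq_along(valid)) {
    t <- valid[i]
    arr[i, , ] <- recording$signal[keep_ch, ((t - 1) * spe + 1):(t * spe)]
  }
  structure(list(epochs = arr,
                 stage_labels = hypno$stages[valid],
                 original_indices = as.integer(valid),
                 fs = fs,
                 channel_labels = recording$channels$label[keep_ch],
                 channel_roles = recording$channels$role[keep_ch]),
            class = "epoch_set")
}

#' Write a synthetic cohort to disk
#'
#' One EDF and one hypnogram CSV per subject, plus a cohort `metadata.csv`.
#' @param subjects List of `synthetic_subject` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- do.call(rbind, lapply(subjects, function(s)
    as.data.frame(s$metadata, stringsAsFactors = FALSE)))
  for (s in subjects) {
    id <- s$metadata$subject_id
    write_edf(s$recording, file.path(dir, paste0(id, ".edf")))
    write_hypnogram_csv(s$hypnogram, file.path(dir, paste0(id, "_hypnogram.csv")))
  }
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}
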