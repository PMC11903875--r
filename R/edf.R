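# Minimal continuous-EDF reader/writer (16-bit samples, one 30-s data
# record per epoch). Covers exactly what the pipeline needs: multichannel
# equal-rate signals with physical/digital scaling. Annotations, EDF+D and
# per-signal rates are out of scope.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled to the 16-bit digital range using a symmetric
#' physical range equal to the maximum absolute amplitude, so the
#' quantization step is `max|x| / 32767`. The data-record duration is 30 s
#' (one record per epoch); a trailing partial epoch is not written.
#'
#' @param recording A `psg_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "psg_recording"))
  fs <- recording$fs
  sig <- recording$signal
  ns <- nrow(sig)
  spr <- as.integer(30 * fs)                 # samples per record and channel
  nrec <- floor(ncol(sig) / spr)
  if (nrec < 1) stop("signal shorter than one 30-s data record")
  phys_max <- max(1e-6, max(abs(sig), na.rm = TRUE))
  # round up to 6 significant digits so the header strings are exact
  pm6 <- signif(phys_max, 6)
  if (pm6 < phys_max) pm6 <- pm6 + 10^(floor(log10(pm6)) - 5)
  phys_max <- pm6

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(recording$subject_id, 80),
    pad_field("synthetic PSG", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(nrec, 8),
    pad_field(30, 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    label = pad_field(recording$channels$label, 16),
    transducer = rep(pad_field("", 80), ns),
    dim = rep(pad_field("uV", 8), ns),
    pmin = rep(pad_field(format(-phys_max, digits = 6), 8), ns),
    pmax = rep(pad_field(format(phys_max, digits = 6), 8), ns),
    dmin = rep(pad_field(-32768, 8), ns),
    dmax = rep(pad_field(32767, 8), ns),
    prefilter = rep(pad_field("", 80), ns),
    spr = rep(pad_field(spr, 8), ns),
    reserved = rep(pad_field("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  gain <- 2 * phys_max / (32767 - (-32768))
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((sig[ch, cols] + phys_max) / gain) - 32768
      dig <- as.integer(pmin(pmax(dig, -32768), 32767))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param eeg_labels Labels treated as EEG channels.
#' @param eog_pattern Regular expression identifying EOG channels.
#' @return A `psg_recording`. Channels matching neither pattern get role
#'   `"other"`.
#' @export
read_edf <- function(path,
                     eeg_labels = c("C3", "C4", "F3", "F4", "O1", "O2", "FP1", "FZ", "CZ", "PZ"),
                     eog_pattern = "^E(OG)?[0-9]*$|^EOG") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nb) trimws(readChar(con, nb, useBytes = TRUE))
  rd(8)                                 # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)         # transducer
  for (i in seq_len(ns)) rd(8)          # physical dimension
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)         # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)         # reserved

  if (length(unique(spr)) != 1)
    stop("per-signal sampling rates differ; only equal-rate EDF is supported")
  fs <- spr[1] / recdur
  sig <- matrix(0, nrow = ns, ncol = nrec * spr[1])
  gain <- (pmax - pmin) / (dmax - dmin)
  offset <- pmin - gain * dmin
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      sig[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- dig * gain[ch] + offset[ch]
    }
  }
  up <- toupper(labels)
  roles <- ifelse(up %in% toupper(eeg_labels), "EEG",
                  ifelse(grepl(eog_pattern, up, ignore.case = TRUE), "EOG", "other"))
  structure(list(subject_id = subject_id, fs = fs,
                 channels = data.frame(label = labels, role = roles,
                                       reference = NA_character_,
                                       stringsAsFactors = FALSE),
                 signal = sig),
            class = "psg_recording")
}

#' Write a hypnogram to CSV
#'
#' Dialect: header `epoch_index,stage` with 0-based epoch indices.
#' @param hypno A [hypnogram()].
#' @param path Output path.
#' @export
write_hypnogram_csv <- function(hypno, path) {
  stopifnot(inherits(hypno, "hypnogram"))
  write.csv(data.frame(epoch_index = seq_along(hypno$stages) - 1L,
                       stage = hypno$stages),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Recognized spellings for each stage label in hypnogram files.
default_stage_aliases <- function() {
  list(W = c("W", "WAKE", "0"), N1 = c("N1", "S1", "1"),
       N2 = c("N2", "S2", "2"), N3 = c("N3", "S3", "S4", "3", "4"),
       REM = c("REM", "R", "5"))
}

#' Read a hypnogram CSV
#'
#' Expects columns `epoch_index` (0-based) and `stage`. Unrecognized stage
#' labels become INVALID.
#' @param path CSV path.
#' @param aliases Named list mapping canonical stages to accepted spellings.
#' @return A [hypnogram()].
#' @export
read_hypnogram_csv <- function(path, aliases = default_stage_aliases()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df)))
    stop("hypnogram CSV must have columns epoch_index,stage")
  if (nrow(df) == 0) stop("empty hypnogram")
  df <- df[order(df$epoch_index), ]
  lut <- stats::setNames(rep(names(aliases), lengths(aliases)),
                         toupper(unlist(aliases)))
  mapped <- lut[toupper(trimws(as.character(df$stage)))]
  mapped[is.na(mapped)] <- "INVALID"
  hypnogram(unname(mapped))
}
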