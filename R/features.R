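# Projection of each epoch into the 22-features-per-channel space used to
# train the personalized staging models.

#' Extract the canonical 22-feature set per epoch and channel
#'
#' Computes the 22 canonical time-series features for every channel of
#' every epoch, giving `22 x n_channels` columns named
#' `<channel>__<feature>`. Channels appear in recording order, features in
#' canonical order. Non-finite feature values (degenerate series) are
#' replaced by 0 so that downstream models stay total.
#'
#' @param epochs An `epoch_set` from [make_epochs()] (>= 2 epochs).
#' @return An `epoch_feature_matrix`: `values` (numeric matrix), plus
#'   `stage_labels` and `original_indices` copied from the epoch set.
#' @export
extract_features <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$epochs)
  if (d[1] < 2) stop("need at least 2 epochs")
  if (d[3] < 16) stop("epochs too short for the feature set")
  fnames <- catch22_feature_names()
  blocks <- vector("list", d[2])
  for (ch in seq_len(d[2])) {
    series <- lapply(seq_len(d[1]), function(i) epochs$epochs[i, ch, ])
    m <- catch22_compute_many(series)
    colnames(m) <- paste0(epochs$channel_labels[ch], "__", fnames)
    blocks[[ch]] <- m
  }
  values <- do.call(cbind, blocks)
  values[!is.finite(values)] <- 0
  structure(list(values = values,
                 stage_labels = epochs$stage_labels,
                 original_indices = epochs$original_indices),
            class = "epoch_feature_matrix")
}
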