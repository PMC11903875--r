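# Information-theoretic quantification of hypnodensities: per-epoch Shannon
# entropy (stage intrusions) and Kullback-Leibler divergence between
# temporally adjacent same-stage epochs (instability). Both in bits.

#' Shannon entropy of a stage probability vector
#'
#' \eqn{H(x) = -\sum_i p_i \log_2 p_i} over the five sleep stages, with the
#' convention \eqn{0 \log 0 = 0}. A Dirac distribution (all mass on one
#' stage) has entropy 0; the uniform distribution attains the maximum
#' \eqn{\log_2 5 \approx 2.32} bits. High entropy of a hypnodensity reads as
#' a high level of intrusion of other stages into the epoch.
#'
#' @param p Numeric vector of stage probabilities. Must be non-negative and
#'   sum to 1 within `1e-6`; it is renormalized internally.
#' @return Entropy in bits.
#' @export
#' @examples
#' entropy(c(1, 0, 0, 0, 0))          # 0
#' entropy(rep(0.2, 5))               # log2(5)
entropy <- function(p) {
  p <- check_simplex(p)
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Kullback-Leibler divergence between two stage distributions
#'
#' \eqn{D_{KL}(P \| Q) = \sum_i p_i \log_2 (p_i / q_i)} in bits. Because the
#' divergence is undefined where \eqn{q_i = 0}, both vectors are floored at
#' `epsilon` and renormalized before evaluation, which keeps the divergence
#' finite for calibrated probabilities that underflow to zero. The result is
#' non-negative and zero iff the floored distributions are equal. Note the
#' asymmetry: \eqn{D_{KL}(P\|Q) \ne D_{KL}(Q\|P)} in general.
#'
#' @param p,q Stage probability vectors (renormalized internally).
#' @param epsilon Probability floor, default `1e-6`.
#' @return Divergence in bits.
#' @export
kl_divergence <- function(p, q, epsilon = 1e-6) {
  p <- check_simplex(p)
  q <- check_simplex(q)
  if (length(p) != length(q)) stop("p and q must have the same length")
  p <- pmax(p, epsilon); p <- p / sum(p)
  q <- pmax(q, epsilon); q <- q / sum(q)
  sum(p * log2(p / q))
}

check_simplex <- function(p) {
  if (!is.numeric(p) || anyNA(p)) stop("probability vector must be numeric and non-missing")
  if (any(p < 0)) stop("probability vector has negative entries")
  s <- sum(p)
  if (abs(s - 1) > 1e-6) stop("probabilities must sum to 1 within 1e-6 (got ", format(s), ")")
  p / s
}

#' Per-epoch intrusion and instability series
#'
#' Computes, from a fitted [hypnodensity()] object, the epoch-wise entropy
#' (over all five stage probabilities, N1 included in the support), the wake
#' probability, and the Kullback-Leibler divergence
#' \eqn{D_{KL}(P_t \| P_{t+1})} for every pair of epochs that are adjacent
#' in the original hypnogram (original index t, t+1) *and* share the same
#' expert stage. Pairs spanning a stage change or an invalid-epoch gap do
#' not qualify.
#'
#' @param hd A `hypnodensity` object (see [fit_hypnodensity()]).
#' @param epsilon Probability floor passed to [kl_divergence()].
#' @return An object of class `info_metric_series`: a list with `epochs`
#'   (data.frame: `epoch_index`, `stage`, `entropy_bits`, `wake_probability`)
#'   and `pairs` (data.frame: `epoch_index` of the first epoch of the pair,
#'   `stage`, `dkl_bits`).
#' @export
compute_series <- function(hd, epsilon = 1e-6) {
  stopifnot(inherits(hd, "hypnodensity"))
  probs <- hd$probs
  n <- nrow(probs)
  if (n < 2) stop("need at least 2 epochs")
  ent <- apply(probs, 1, entropy)
  epochs <- data.frame(
    epoch_index = hd$original_indices,
    stage = hd$expert_stage,
    entropy_bits = ent,
    wake_probability = probs[, "W"],
    stringsAsFactors = FALSE
  )
  adjacent <- which(diff(hd$original_indices) == 1L &
                      hd$expert_stage[-n] == hd$expert_stage[-1])
  pairs <- data.frame(
    epoch_index = hd$original_indices[adjacent],
    stage = hd$expert_stage[adjacent],
    dkl_bits = vapply(adjacent, function(t)
      kl_divergence(probs[t, ], probs[t + 1L, ], epsilon = epsilon), numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(list(epochs = epochs, pairs = pairs), class = "info_metric_series")
}

# Stages entering the per-subject summary. N1 epochs contribute to no
# summary feature, although N1 probabilities remain in every 5-vector.
SUMMARY_STAGES <- c("W", "N2", "N3", "REM")

#' 16-feature per-subject summary of intrusions and instability
#'
#' Mean and standard deviation (n-1 denominator) of the epoch entropies and
#' of the adjacent-pair divergences, per analyzed stage (W, N2, N3, REM; N1
#' is excluded from the summarized stages). Stages with no epochs, or with
#' too few values for an SD, yield `NA` rather than zero. Feature names
#' follow the `ave_H_W` / `sd_dKL_REM` convention.
#'
#' @param series An `info_metric_series` from [compute_series()].
#' @return Named numeric vector of length 16.
#' @export
summarize_subject <- function(series) {
  stopifnot(inherits(series, "info_metric_series"))
  out <- numeric(0)
  for (s in SUMMARY_STAGES) {
    h <- series$epochs$entropy_bits[series$epochs$stage == s]
    d <- series$pairs$dkl_bits[series$pairs$stage == s]
    out[paste0("ave_H_", s)] <- if (length(h) >= 1) mean(h) else NA_real_
    out[paste0("sd_H_", s)]  <- if (length(h) >= 2) sd(h) else NA_real_
    out[paste0("ave_dKL_", s)] <- if (length(d) >= 1) mean(d) else NA_real_
    out[paste0("sd_dKL_", s)]  <- if (length(d) >= 2) sd(d) else NA_real_
  }
  out
}

#' Persist an information-metric series as CSV
#'
#' Epoch-level table (`epoch_index`, `stage`, `entropy_bits`,
#' `wake_probability`) with the qualifying-pair divergences merged in as a
#' `dkl_bits_to_next` column (`NA` where the next epoch does not qualify).
#' @param series An `info_metric_series`.
#' @param path Output path.
#' @export
write_metrics_csv <- function(series, path) {
  stopifnot(inherits(series, "info_metric_series"))
  df <- series$epochs
  df$dkl_bits_to_next <- series$pairs$dkl_bits[
    match(df$epoch_index, series$pairs$epoch_index)]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Names of the 16 summary features
#' @return Character vector of length 16.
#' @export
summary_feature_names <- function() {
  unlist(lapply(SUMMARY_STAGES, function(s)
    paste0(c("ave_H_", "sd_H_", "ave_dKL_", "sd_dKL_"), s)), use.names = FALSE)
}
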