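# Synthetic PSG cohort generator. Produces Markov-chain hypnograms and
# colored-noise recordings whose per-epoch band-power proportions follow a
# convex mixture of the epoch's own stage profile and an intruding-stage
# profile, with controllable epoch-to-epoch variation of the mixing weight.
# This gives every downstream stage of the pipeline a testbed with known,
# planted intrusion/instability structure.

#' Default stage spectral profiles
#'
#' Relative power weights over the six canonical bands
#' (delta, theta, alpha, sigma, beta, gamma) for each sleep stage,
#' following textbook AASM spectral signatures: alpha/beta-weighted wake,
#' theta-dominant N1, sigma/theta-enhanced N2, delta-dominant N3 and
#' theta/beta-mixed REM. Each profile sums to 1.
#'
#' @return Named list of 6-element numeric vectors, one per stage.
#' @export
default_stage_profiles <- function() {
  prof <- list(
    W   = c(delta = 0.15, theta = 0.10, alpha = 0.35, sigma = 0.10, beta = 0.20, gamma = 0.10),
    N1  = c(delta = 0.25, theta = 0.40, alpha = 0.15, sigma = 0.08, beta = 0.08, gamma = 0.04),
    N2  = c(delta = 0.35, theta = 0.25, alpha = 0.10, sigma = 0.20, beta = 0.07, gamma = 0.03),
    N3  = c(delta = 0.70, theta = 0.15, alpha = 0.05, sigma = 0.05, beta = 0.03, gamma = 0.02),
    REM = c(delta = 0.25, theta = 0.35, alpha = 0.10, sigma = 0.05, beta = 0.18, gamma = 0.07)
  )
  lapply(prof, function(p) p / sum(p))
}

#' Group specification for the synthetic cohort
#'
#' Bundles everything that distinguishes one sleeper group: a 5x5
#' row-stochastic stage transition matrix, the intrusion mixing weights, the
#' epoch-to-epoch variability of those weights, and a demographics model.
#'
#' @param name Group label.
#' @param n_subjects Number of subjects (>= 1).
#' @param transition_matrix 5x5 row-stochastic matrix in stage order
#'   W, N1, N2, N3, REM.
#' @param wake_sleep_intrusion Mixing weight in `[0, 1]` of sleep-profile
#'   power added to wake epochs (sleep intrusion into wakefulness).
#' @param sleep_wake_intrusion Mixing weight in `[0, 1]` of wake-profile
#'   power added to NREM/REM epochs (wake intrusion into sleep).
#' @param wake_instability_sd Step SD of the bounded random walk followed by
#'   the wake mixing weight across consecutive wake epochs.
#' @param sleep_instability_sd SD of the i.i.d. epoch-level jitter of the
#'   sleep-epoch mixing weight (clipped to `[0, 1]`).
#' @param demographics Named list: `female_prop`, `age_mean`, `age_sd`,
#'   `bmi_mean`, `bmi_sd`.
#' @return A `group_spec` object.
#' @export
group_spec <- function(name, n_subjects, transition_matrix,
                       wake_sleep_intrusion = 0, sleep_wake_intrusion = 0,
                       wake_instability_sd = 0, sleep_instability_sd = 0,
                       demographics = list(female_prop = 0.5, age_mean = 40,
                                           age_sd = 12, bmi_mean = 23.5, bmi_sd = 3)) {
  check_transition_matrix(transition_matrix)
  for (w in c(wake_sleep_intrusion, sleep_wake_intrusion))
    if (w < 0 || w > 1) stop("mixing weights must lie in [0, 1]")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 transition_matrix = transition_matrix,
                 wake_sleep_intrusion = wake_sleep_intrusion,
                 sleep_wake_intrusion = sleep_wake_intrusion,
                 wake_instability_sd = wake_instability_sd,
                 sleep_instability_sd = sleep_instability_sd,
                 demographics = demographics),
            class = "group_spec")
}

check_transition_matrix <- function(P) {
  if (!is.matrix(P) || any(dim(P) != 5) || any(P < 0) || anyNA(P))
    stop("transition matrix must be a non-negative 5x5 matrix")
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("transition matrix rows must sum to 1")
  invisible(P)
}

tmat <- function(...) {
  m <- matrix(c(...), nrow = 5, byrow = TRUE,
              dimnames = list(STAGES, STAGES))
  m / rowSums(m)
}

#' Default three-group cohort specification
#'
#' Three groups mirroring the contrasts of interest: a good-sleeper-like
#' group (GS-like: low sleep intrusion into wake, stable wakefulness), an
#' objectively-disrupted-insomnia-like group (SOSDminus-like: moderate sleep
#' intrusion into wake plus wake intrusion into sleep, more fragmented
#' sleep), and a misperception-like group (SOSDplus-like: strong sleep
#' intrusion into wake, three-fold wake instability, fragmented
#' wakefulness). Demographics follow the clinical-cohort group summaries
#' (age, sex proportion, BMI).
#'
#' @param n_subjects Per-group subject count (default 30).
#' @return List of three [group_spec()] objects.
#' @export
default_group_specs <- function(n_subjects = 30) {
  gs_tm <- tmat(
    .92, .05, .03, .00, .00,
    .08, .45, .42, .02, .03,
    .02, .03, .85, .07, .03,
    .01, .01, .08, .89, .01,
    .04, .04, .04, .00, .88)
  minus_tm <- tmat(
    .88, .06, .06, .00, .00,
    .10, .45, .38, .02, .05,
    .04, .03, .83, .07, .03,
    .02, .01, .09, .87, .01,
    .06, .04, .04, .00, .86)
  plus_tm <- tmat(
    .78, .12, .10, .00, .00,
    .08, .45, .42, .02, .03,
    .02, .03, .85, .07, .03,
    .01, .01, .08, .89, .01,
    .04, .04, .04, .00, .88)
  list(
    group_spec("GS-like", n_subjects, gs_tm,
               wake_sleep_intrusion = 0.05, sleep_wake_intrusion = 0,
               wake_instability_sd = 0.02, sleep_instability_sd = 0.02,
               demographics = list(female_prop = 0.308, age_mean = 36.2,
                                   age_sd = 11.9, bmi_mean = 24.2, bmi_sd = 2.61)),
    group_spec("SOSDminus-like", n_subjects, minus_tm,
               wake_sleep_intrusion = 0.15, sleep_wake_intrusion = 0.15,
               wake_instability_sd = 0.02, sleep_instability_sd = 0.05,
               demographics = list(female_prop = 0.697, age_mean = 46.8,
                                   age_sd = 14.1, bmi_mean = 23.1, bmi_sd = 3.86)),
    group_spec("SOSDplus-like", n_subjects, plus_tm,
               wake_sleep_intrusion = 0.30, sleep_wake_intrusion = 0,
               wake_instability_sd = 0.06, sleep_instability_sd = 0.02,
               demographics = list(female_prop = 0.744, age_mean = 40.8,
                                   age_sd = 12.1, bmi_mean = 23.0, bmi_sd = 3.56))
  )
}

#' Hypnogram container
#'
#' @param stages Character vector over W, N1, N2, N3, REM, INVALID.
#' @return A `hypnogram` object (30-s epochs).
#' @export
hypnogram <- function(stages) {
  stages <- as.character(stages)
  if (length(stages) < 2) stop("hypnogram needs at least 2 epochs")
  bad <- setdiff(unique(stages), c(STAGES, "INVALID"))
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, epoch_seconds = 30), class = "hypnogram")
}

#' Simulate an expert hypnogram from a Markov chain
#'
#' @param transition_matrix 5x5 row-stochastic matrix (stage order
#'   W, N1, N2, N3, REM; rows must sum to 1 within 1e-9).
#' @param n_epochs Number of 30-s epochs (>= 2).
#' @param initial_stage Starting stage, default "W".
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(transition_matrix, n_epochs, initial_stage = "W",
                               seed = 1L) {
  check_transition_matrix(transition_matrix)
  if (n_epochs < 2) stop("n_epochs must be >= 2")
  if (!initial_stage %in% STAGES) stop("unknown initial stage")
  set.seed(seed)
  idx <- integer(n_epochs)
  idx[1] <- match(initial_stage, STAGES)
  u <- runif(n_epochs - 1)
  cs <- t(apply(transition_matrix, 1, cumsum))
  for (t in 2:n_epochs) {
    idx[t] <- which(u[t - 1] <= cs[idx[t - 1], ])[1]
  }
  hypnogram(STAGES[idx])
}

# Mean of the four sleep-stage profiles: the "sleep signature" mixed into
# wake epochs when sleep intrudes into wakefulness.
sleep_mean_profile <- function(profiles) {
  Reduce(`+`, profiles[c("N1", "N2", "N3", "REM")]) / 4
}

#' Simulate a multichannel recording for a hypnogram
#'
#' Each 30-s epoch of each channel is band-limited Gaussian noise whose
#' expected band-power proportions follow the convex mixture
#' `(1 - lambda) * own-stage profile + lambda * intruding profile`. For wake
#' epochs the intruding profile is the mean of the four sleep-stage profiles
#' and `lambda` follows a bounded random walk (step SD
#' `wake_instability_sd`, clipped to `[0, 1]`) across consecutive wake
#' epochs; for sleep epochs the intruding profile is the wake profile and
#' `lambda` is the group's `sleep_wake_intrusion` plus i.i.d. jitter of SD
#' `sleep_instability_sd`, clipped to `[0, 1]`. Channels are independent
#' noise realizations of the same epoch-level mixture.
#'
#' @param hypno A [hypnogram()].
#' @param group A [group_spec()].
#' @param profiles Stage spectral profiles, default [default_stage_profiles()].
#' @param fs Sampling rate in Hz (>= 64 so the gamma band is representable).
#' @param channel_labels Channel names; roles are inferred (EOG-prefixed
#'   labels become EOG, the rest EEG).
#' @param seed Integer seed.
#' @param subject_id Subject identifier carried in the recording.
#' @param profile_jitter_sd SD of the epoch-level log-normal jitter applied
#'   to the mixed band weights (default 0.4). Real sleep EEG shows large
#'   epoch-to-epoch variability of within-stage band power; without it,
#'   stage clouds in feature space are unrealistically separable and a
#'   personalized stager saturates. Set to 0 for noise-free band structure.
#' @return A `psg_recording` object with an `intrusion_lambda` element
#'   giving the realized per-epoch mixing weight.
#' @export
simulate_recording <- function(hypno, group, profiles = default_stage_profiles(),
                               fs = 128, channel_labels = c("C3", "C4", "EOG1"),
                               seed = 1L, subject_id = "synthetic",
                               profile_jitter_sd = 0.4) {
  stopifnot(inherits(hypno, "hypnogram"), inherits(group, "group_spec"))
  if (fs < 64) stop("fs must be >= 64 Hz so the gamma band is representable")
  if (length(channel_labels) < 1) stop("need at least one channel")
  stages <- hypno$stages
  if (any(!stages %in% STAGES)) stop("hypnogram contains unknown or INVALID stages")
  set.seed(seed)
  n_epochs <- length(stages)
  spe <- 30L * fs                      # samples per epoch

  # epoch-level mixing weights
  lambda <- numeric(n_epochs)
  wake_prev <- NA_real_
  for (t in seq_len(n_epochs)) {
    if (stages[t] == "W") {
      if (is.na(wake_prev)) wake_prev <- group$wake_sleep_intrusion
      else wake_prev <- min(1, max(0, wake_prev + rnorm(1, 0, group$wake_instability_sd)))
      lambda[t] <- wake_prev
    } else {
      lambda[t] <- min(1, max(0, group$sleep_wake_intrusion +
                                rnorm(1, 0, group$sleep_instability_sd)))
    }
  }

  sleep_prof <- sleep_mean_profile(profiles)
  wake_prof <- profiles[["W"]]

  # per-frequency-bin band assignment for direct spectral synthesis
  kmax <- floor(spe / 2)
  freq <- (1:(kmax - 1)) * fs / spe
  bin_band <- band_of(freq)
  band_nbins <- tabulate(bin_band, nbins = 6)

  amp_rms_uV <- 20  # target RMS amplitude of each channel, microvolts

  nchan <- length(channel_labels)
  signal <- matrix(0, nrow = nchan, ncol = n_epochs * spe)
  for (t in seq_len(n_epochs)) {
    own <- profiles[[stages[t]]]
    intr <- if (stages[t] == "W") sleep_prof else wake_prof
    w <- (1 - lambda[t]) * own + lambda[t] * intr
    if (profile_jitter_sd > 0) {
      w <- w * exp(rnorm(6, 0, profile_jitter_sd))
      w <- w / sum(w)
    }
    # per-bin amplitude: flat within each band, zero outside 0.5-40 Hz,
    # total epoch variance 1
    a <- numeric(length(bin_band))
    inband <- !is.na(bin_band)
    a[inband] <- sqrt(w[bin_band[inband]] / band_nbins[bin_band[inband]])
    scale <- spe / sqrt(2 * sum(a^2))
    for (ch in seq_len(nchan)) {
      zr <- rnorm(kmax - 1); zi <- rnorm(kmax - 1)
      X <- complex(length.out = spe)
      X[2:kmax] <- a * complex(real = zr, imaginary = zi) / sqrt(2)
      X[spe:(spe - kmax + 2)] <- Conj(X[2:kmax])
      x <- Re(fft(X, inverse = TRUE)) / spe * scale
      signal[ch, ((t - 1) * spe + 1):(t * spe)] <- x * amp_rms_uV
    }
  }

  roles <- ifelse(grepl("^E(OG)?[0-9]*$|^EOG", channel_labels, ignore.case = TRUE),
                  "EOG", "EEG")
  structure(list(subject_id = subject_id, fs = fs,
                 channels = data.frame(label = channel_labels, role = roles,
                                       reference = NA_character_,
                                       stringsAsFactors = FALSE),
                 signal = signal,
                 intrusion_lambda = lambda),
            class = "psg_recording")
}

# Map frequencies to band index 1..6 (half-open [low, high); gamma closed
# at 40 Hz). Frequencies outside 0.5-40 get NA.
band_of <- function(freq) {
  b <- rep(NA_integer_, length(freq))
  edges <- BANDS
  for (i in seq_along(edges)) {
    lo <- edges[[i]][1]; hi <- edges[[i]][2]
    sel <- if (i == length(edges)) freq >= lo & freq <= hi else freq >= lo & freq < hi
    b[sel] <- i
  }
  b
}

#' Sleep-quality metrics from a hypnogram
#'
#' TST is 30 s times the number of valid non-wake epochs; SOL is the time to
#' the first non-wake valid epoch; WASO is wake time after sleep onset; SE
#' is TST over time in bed. All in minutes except SE (percent).
#'
#' @param hypno A [hypnogram()].
#' @return Named numeric vector: `tst_min`, `sol_min`, `waso_min`, `se_pct`.
#' @export
sleep_metrics_from_hypnogram <- function(hypno) {
  stopifnot(inherits(hypno, "hypnogram"))
  st <- hypno$stages
  valid <- st %in% STAGES
  epoch_min <- hypno$epoch_seconds / 60
  sleep <- valid & st != "W"
  tst <- sum(sleep) * epoch_min
  onset <- which(sleep)[1]
  sol <- if (is.na(onset)) length(st) * epoch_min else (onset - 1) * epoch_min
  waso <- if (is.na(onset)) 0 else sum(valid & st == "W" & seq_along(st) > onset) * epoch_min
  tib <- length(st) * epoch_min
  c(tst_min = tst, sol_min = sol, waso_min = waso, se_pct = 100 * tst / tib)
}

#' Simulate a cohort of synthetic subjects
#'
#' One subject per requested slot of each [group_spec()]; groups differ only
#' through their spec parameters. Per-subject seeds are derived
#' deterministically from `seed`, so identical calls give bit-identical
#' cohorts.
#'
#' @param specs List of [group_spec()] objects (total subjects >= 2).
#' @param epochs_per_subject Epochs per subject (>= 60).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param profiles Stage spectral profiles.
#' @param channel_labels Channel layout, default two EEG plus one EOG.
#' @return List of `synthetic_subject` objects, each holding `recording`,
#'   `hypnogram` and `metadata`.
#' @export
simulate_cohort <- function(specs, epochs_per_subject = 240, fs = 128, seed = 1L,
                            profiles = default_stage_profiles(),
                            channel_labels = c("C3", "C4", "EOG1")) {
  if (length(specs) == 0) stop("empty group specification list")
  stopifnot(all(vapply(specs, inherits, logical(1), "group_spec")))
  if (sum(vapply(specs, `[[`, integer(1), "n_subjects")) < 2)
    stop("cohort must contain at least 2 subjects")
  if (epochs_per_subject < 60) stop("epochs_per_subject must be >= 60")

  subjects <- list()
  sidx <- 0L
  for (g in specs) {
    for (i in seq_len(g$n_subjects)) {
      sidx <- sidx + 1L
      subjects[[sidx]] <- simulate_one_subject(g, sidx, seed,
                                               epochs_per_subject, fs,
                                               profiles, channel_labels)
    }
  }
  subjects
}

# One subject of a cohort; seeding depends only on (seed, sidx), so
# subjects can be generated independently (and streamed) while remaining
# bit-identical to a full simulate_cohort() call.
simulate_one_subject <- function(g, sidx, seed, epochs_per_subject, fs,
                                 profiles, channel_labels) {
  sseed <- child_seed(seed, sidx)
  hyp <- simulate_hypnogram(g$transition_matrix, epochs_per_subject,
                            initial_stage = "W", seed = sseed)
  rec <- simulate_recording(hyp, g, profiles = profiles, fs = fs,
                            channel_labels = channel_labels,
                            seed = sseed + 1L,
                            subject_id = sprintf("S%03d", sidx))
  set.seed(sseed + 2L)
  demo <- g$demographics
  metrics <- sleep_metrics_from_hypnogram(hyp)
  meta <- list(subject_id = sprintf("S%03d", sidx), group = g$name,
               sex = if (runif(1) < demo$female_prop) "F" else "M",
               age = max(18, rnorm(1, demo$age_mean, demo$age_sd)),
               bmi = max(15, rnorm(1, demo$bmi_mean, demo$bmi_sd)),
               tst_min = unname(metrics["tst_min"]),
               sol_min = unname(metrics["sol_min"]),
               waso_min = unname(metrics["waso_min"]),
               se_pct = unname(metrics["se_pct"]))
  structure(list(recording = rec, hypnogram = hyp, metadata = meta),
            class = "synthetic_subject")
}

# Deterministic per-subject seed derivation, kept below 2^31.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + 104729 * as.numeric(i)) %% 2147483629)
}
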