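# Shared fixture builders (everything generated in code at test time).

# Random point on the 5-simplex.
random_simplex <- function() {
  x <- -log(runif(5))
  x / sum(x)
}

# Independent brute-force oracles for the information metrics, written as
# plain elementwise loops (natural log plus change of base) so they share
# no code path with the package implementation.
oracle_entropy <- function(p) {
  p <- p / sum(p)
  acc <- 0
  for (i in seq_along(p)) if (p[i] > 0) acc <- acc - p[i] * log(p[i])
  acc / log(2)
}
oracle_kl <- function(p, q, eps = 1e-6) {
  p <- p / sum(p); q <- q / sum(q)
  p <- ifelse(p < eps, eps, p); p <- p / sum(p)
  q <- ifelse(q < eps, eps, q); q <- q / sum(q)
  acc <- 0
  for (i in seq_along(p)) acc <- acc + p[i] * (log(p[i]) - log(q[i]))
  acc / log(2)
}

# Hand-built epoch_set: n epochs x nchan channels of white noise.
make_epoch_set <- function(n_epochs = 4, channels = c("C3", "EOG1"),
                           spe = 256, fs = 128,
                           stages = rep("N2", n_epochs), seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(n_epochs * length(channels) * spe),
               dim = c(n_epochs, length(channels), spe))
  structure(list(epochs = arr, stage_labels = stages,
                 original_indices = seq_len(n_epochs), fs = fs,
                 channel_labels = channels,
                 channel_roles = ifelse(grepl("^EOG", channels), "EOG", "EEG")),
            class = "epoch_set")
}

# Feature matrix of 5 well-separated Gaussian clusters, one per stage.
make_separable_features <- function(n_per_stage = 50, dim = 6, sep = 8,
                                    seed = 1) {
  set.seed(seed)
  stages <- rep(stage_levels(), each = n_per_stage)
  centers <- matrix(rnorm(5 * dim), 5) * sep
  vals <- centers[rep(1:5, each = n_per_stage), ] + rnorm(length(stages) * dim)
  colnames(vals) <- paste0("C3__f", seq_len(dim))
  structure(list(values = vals, stage_labels = stages,
                 original_indices = seq_along(stages)),
            class = "epoch_feature_matrix")
}

# Synthetic cohort summary table (no signals): 16 features plus metadata.
make_summary_table <- function(n_per_group = 30,
                               groups = c("A", "B"),
                               shift = setNames(numeric(length(groups)), groups),
                               seed = 1) {
  set.seed(seed)
  n <- n_per_group * length(groups)
  grp <- rep(groups, each = n_per_group)
  feats <- matrix(rnorm(n * 16), n, dimnames = list(NULL, summary_feature_names()))
  feats[, "ave_H_W"] <- feats[, "ave_H_W"] + unlist(shift)[grp]
  cbind(data.frame(subject_id = sprintf("S%03d", seq_len(n)), group = grp,
                   sex = sample(c("F", "M"), n, replace = TRUE),
                   age = rnorm(n, 40, 10), bmi = rnorm(n, 23, 3),
                   tst_min = rnorm(n, 360, 40), sol_min = abs(rnorm(n, 20, 10)),
                   waso_min = abs(rnorm(n, 40, 20)), se_pct = rnorm(n, 85, 6),
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
}

# Minimal hypnodensity object (for QC-rule tests).
fake_hd <- function(balacc) {
  structure(list(balanced_accuracy = balacc), class = "hypnodensity")
}
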