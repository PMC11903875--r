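test_that("entropy matches closed forms and rejects bad input", {
  expect_equal(entropy(c(1, 0, 0, 0, 0)), 0)
  expect_equal(entropy(rep(0.2, 5)), log2(5))
  expect_equal(entropy(c(0.5, 0.5, 0, 0, 0)), 1)
  expect_error(entropy(c(-0.1, 0.5, 0.6, 0, 0)), "negative")
  expect_error(entropy(c(0.2, 0.2, 0.2, 0.2, 0.1)), "sum to 1")
})

test_that("KL divergence matches closed forms, is asymmetric and non-negative", {
  p <- c(0.3, 0.1, 0.2, 0.2, 0.2)
  expect_equal(kl_divergence(p, p), 0)
  # two-point distributions: Dirac vs fifty-fifty tends to 1 bit as the
  # floor vanishes
  expect_equal(kl_divergence(c(1, 0, 0, 0, 0), c(0.5, 0.5, 0, 0, 0),
                             epsilon = 1e-12), 1, tolerance = 1e-6)
  a <- c(0.9, 0.1, 0, 0, 0); b <- c(0.5, 0.5, 0, 0, 0)
  expect_gt(abs(kl_divergence(a, b) - kl_divergence(b, a)), 1e-6)
  expect_error(kl_divergence(c(1, 0, 0, 0, -0.0001) + 2e-5, p), "negative")
})

test_that("entropy and KL agree with an independent brute-force oracle", {
  set.seed(42)
  for (i in 1:1000) {
    p <- random_simplex()
    q <- random_simplex()
    expect_equal(entropy(p), oracle_entropy(p), tolerance = 1e-10)
    d <- kl_divergence(p, q)
    expect_equal(d, oracle_kl(p, q), tolerance = 1e-10)
    expect_gte(d, 0)
    expect_lte(entropy(p), log2(5) + 1e-12)
  }
})

make_hd <- function(probs, stages, idx = seq_along(stages)) {
  structure(list(probs = probs, expert_stage = stages,
                 original_indices = as.integer(idx)),
            class = "hypnodensity")
}

test_that("compute_series applies the same-stage temporal-adjacency rule", {
  pr <- matrix(rep(c(0.6, 0.1, 0.1, 0.1, 0.1), 3), 3, byrow = TRUE,
               dimnames = list(NULL, stage_levels()))
  s <- compute_series(make_hd(pr, c("W", "N2", "W")))
  expect_equal(nrow(s$pairs), 0)

  # identical distributions, same stage: all divergences zero
  pr6 <- matrix(rep(c(0.2, 0.2, 0.2, 0.2, 0.2), 6), 6, byrow = TRUE,
                dimnames = list(NULL, stage_levels()))
  s6 <- compute_series(make_hd(pr6, rep("N2", 6)))
  expect_equal(s6$pairs$dkl_bits, rep(0, 5))
  expect_equal(sd(s6$epochs$entropy_bits), 0)

  # a gap in original indices (an INVALID epoch was dropped) breaks adjacency
  sg <- compute_series(make_hd(pr6[1:4, ], rep("N2", 4), c(1, 2, 4, 5)))
  expect_equal(sg$pairs$epoch_index, c(1, 4))
})

test_that("pair selection matches a brute-force double loop on random series", {
  set.seed(7)
  for (rep in 1:20) {
    n <- 60
    stages <- sample(stage_levels(), n, replace = TRUE)
    idx <- sort(sample(seq_len(n + 10), n))
    pr <- t(replicate(n, random_simplex()))
    colnames(pr) <- stage_levels()
    s <- compute_series(make_hd(pr, stages, idx))
    expected <- 0
    for (i in seq_len(n - 1)) {
      if (idx[i + 1] - idx[i] == 1 && stages[i] == stages[i + 1])
        expected <- expected + 1
    }
    expect_equal(nrow(s$pairs), expected)
  }
})

test_that("subject summary has 16 features with explicit missingness", {
  expect_length(summary_feature_names(), 16)
  # 6 hand-set epochs: entropies via two-point distributions
  two_pt <- function(h) {
    # p * (1,0,...) mixture achieving a target entropy via binary search
    f <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
    u <- uniroot(function(p) f(p) - h, c(1e-9, 0.5), tol = 1e-12)$root
    c(u, 1 - u, 0, 0, 0)
  }
  pr <- rbind(two_pt(0.5), two_pt(0.7),
              two_pt(0.2), two_pt(0.2), two_pt(0.4), two_pt(0.4))
  colnames(pr) <- stage_levels()
  stages <- c("W", "W", "N2", "N2", "N2", "N2")
  sm <- summarize_subject(compute_series(make_hd(pr, stages)))
  expect_length(sm, 16)
  expect_equal(unname(sm["ave_H_W"]), 0.6, tolerance = 1e-6)
  expect_equal(unname(sm["ave_H_N2"]), 0.3, tolerance = 1e-6)
  # absent stages (N3, REM) are missing, as is the W divergence SD (only
  # one qualifying wake pair)
  expect_true(all(is.na(sm[grepl("REM|N3", names(sm))])))
  expect_true(is.na(sm["sd_dKL_W"]))
  expect_equal(sum(is.na(sm)), 9)
})

test_that("metrics CSV carries epoch metrics and pair divergences", {
  set.seed(3)
  pr <- t(replicate(6, random_simplex()))
  colnames(pr) <- stage_levels()
  hd <- structure(list(probs = pr, expert_stage = c("W","W","N2","N2","N2","W"),
                       original_indices = 1:6), class = "hypnodensity")
  s <- compute_series(hd)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(s, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 6)
  expect_equal(sum(!is.na(back$dkl_bits_to_next)), nrow(s$pairs))
  expect_equal(back$entropy_bits, s$epochs$entropy_bits, tolerance = 1e-12)
})
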