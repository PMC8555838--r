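test_that("random bases are orthonormal and seed-deterministic", {
  b <- make_basis(21, 8, seed = 3)
  expect_lt(max(abs(crossprod(b) - diag(8))), 1e-12)
  expect_identical(b, make_basis(21, 8, seed = 3))
  sq <- make_basis(6, 6, seed = 4)
  expect_equal(abs(det(sq)), 1, tolerance = 1e-10)
  expect_error(make_basis(5, 6), "exceeds")
})

test_that("weight signals hit exact variances and stay band-limited", {
  v <- c(1, 0.6, 0.36, 0)
  w <- make_weight_signals(30000, v, fps = 250, band_hz = 3,
                           n_segments = 24, seed = 5)
  pop_var <- apply(w, 2, function(c) mean((c - mean(c))^2))
  expect_equal(pop_var, v, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(max(abs(w[, 4])), 0)
  # exact decorrelation of the nonzero columns
  cc <- cov(w[, 1:3])
  expect_lt(max(abs(cc - diag(diag(cc)))), 1e-10)
  # spectral content: welch windows aligned to the independent segments
  ps <- welch_psd(w[, 1], 250, segment_s = 5, overlap = 0)
  frac <- sum(ps$psd[ps$freq <= 1.5 * 3, 1]) / sum(ps$psd[, 1])
  expect_gte(frac, 0.95)
})

test_that("noise-free signers have exactly K variance directions", {
  cfg <- tiny_config(n_signers = 1, K = 3, snr_db = Inf)
  sim <- simulate_cohort(cfg)
  ev <- svd(sim$cohort$matrix)$d^2
  expect_lt(ev[4] / ev[1], 1e-10)
})

test_that("planted variances are recovered through the whole pipeline", {
  cfg <- tiny_config(n_signers = 1, K = 4, n_markers = 10, snr_db = Inf,
                     trial_s = 2, seed = 9)
  sim <- simulate_cohort(cfg)
  fit <- pma(sim$cohort, cutoff = NULL)
  tr <- sim$truth$transforms$s1
  dbar <- sim$cohort$params$s1$mean_norm
  expected <- (tr$scale * cfg$amplitude_mm)^2 *
    sim$truth$planted_variances / dbar^2
  expect_equal(fit$eigenvalues[1:4], expected, tolerance = 1e-6,
               ignore_attr = TRUE)
  # and the planted subspace is recovered exactly
  expect_lt(max(principal_angles(sim$truth$basis, fit$rotation[, 1:4])),
            1e-4)
})

test_that("signers sharing weights differ only by the anthropometric map", {
  cfg <- tiny_config(n_signers = 1, snr_db = Inf)
  set.seed(13)
  ms <- synthetic_markerset(cfg$n_markers)
  p <- 3 * (cfg$n_markers - 1)
  basis <- make_basis(p, cfg$K, seed = 2)
  v <- cfg$variance_decay^(0:(cfg$K - 1))
  w <- make_weight_signals(200, v / sum(v), cfg$fps, cfg$band_hz,
                           n_segments = cfg$n_trials, seed = 3)
  t1 <- list(mean_offset = rnorm(p, sd = 20), scale = 1, rotation = NULL,
             permutation = NULL)
  t2 <- list(mean_offset = rnorm(p, sd = 20) + 50, scale = 1.3,
             rotation = NULL, permutation = NULL)
  s1 <- synthesize_signer(cfg, basis, w, t1, ms, "a")$trials
  s2 <- synthesize_signer(cfg, basis, w, t2, ms, "b")$trials
  trials <- lapply(c(s1, s2), reference_to_origin)
  co <- normalize_cohort(build_posture_matrix(trials))
  blk1 <- co$matrix[segment_rows(co, "a"), ]
  blk2 <- co$matrix[segment_rows(co, "b"), ]
  expect_lt(max(abs(blk1 - blk2)), 1e-8)
})

test_that("realized SNR matches the configured level within 1 dB", {
  cfg <- cohort_config(n_signers = 1, n_trials = 8, trial_s = 5, fps = 250,
                       n_markers = 20, K = 8, snr_db = 20, seed = 5)
  sim <- simulate_cohort(cfg)
  x <- unclass(sim$posture)
  b <- sim$truth$basis
  p <- ncol(x)
  k <- ncol(b)
  resid <- x - x %*% b %*% t(b)
  noise_tot <- sum(apply(resid, 2, var)) * p / (p - k)
  sig_tot <- sum(apply(x, 2, var)) - noise_tot
  expect_lt(abs(10 * log10(sig_tot / noise_tot) - 20), 1)
})

test_that("cohort generation is bitwise reproducible per seed", {
  cfg <- tiny_config(seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort$matrix, b$cohort$matrix)
  expect_identical(a$truth$basis, b$truth$basis)
  expect_identical(a$truth$weight_signals, b$truth$weight_signals)
  c2 <- simulate_cohort(tiny_config(seed = 78))
  expect_false(identical(a$cohort$matrix, c2$cohort$matrix))
})

test_that("cohort geometry follows the configuration", {
  cfg <- tiny_config(n_signers = 2, n_trials = 3, trial_s = 2, fps = 40,
                     n_markers = 6)
  sim <- simulate_cohort(cfg)
  expect_equal(dim(sim$cohort$matrix), c(2 * 3 * 2 * 40, 3 * 5))
  expect_length(segment_rows(sim$cohort, "s1"), 3 * 2 * 40)
  expect_equal(nrow(sim$cohort$segments), 6)
})

test_that("subspace recovery degrades monotonically with noise", {
  ang <- vapply(c(30, 20, 10), function(snr) {
    sim <- simulate_cohort(tiny_config(snr_db = snr, seed = 21))
    fit <- pma(sim$cohort, cutoff = NULL, keep_data = FALSE)
    max(principal_angles(sim$truth$basis, fit$rotation[, 1:3]))
  }, numeric(1))
  expect_true(all(diff(ang) > 0))
  expect_lt(ang[2], 5)   # 20 dB keeps the subspace within 5 degrees
})
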