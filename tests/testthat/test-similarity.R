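orthonormal_cols <- function(p, k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(p * k), p, k)))
}

test_that("cosine similarity identities on constructed PMs", {
  u <- orthonormal_cols(12, 3, seed = 1)
  set.seed(2)
  w <- rnorm(200)
  a <- outer(w, u[, 1])
  b <- outer(w, u[, 2])
  expect_equal(pm_cosine(a, a), 1)
  expect_lt(pm_cosine(a, b), 1e-12)          # orthogonal PCs, shared weights
  expect_equal(pm_cosine(a, 3 * a), 1)       # scale invariance
  expect_equal(pm_cosine(a, -a, mode = "signed"), -1)
  expect_equal(pm_cosine(a, -a), 1)          # abs mode folds the sign
  expect_error(pm_cosine(a, a * 0), "all-zero")
  expect_error(pm_cosine(a, b[1:10, ]), "shape")
})

test_that("rank-one factorization: shared weights reduce sim to PC dot", {
  u <- orthonormal_cols(30, 4, seed = 3)
  set.seed(4)
  w <- rnorm(500)
  mix <- (u[, 1] + u[, 3]) / sqrt(2)
  sims <- vapply(1:4, function(j) {
    pm_cosine(outer(w, mix), outer(w, u[, j]))
  }, numeric(1))
  expect_equal(sims, c(1, 0, 1, 0) / sqrt(2), tolerance = 1e-12)
  # arbitrary (non-unit) directions too: sim = |cos of the two directions|
  set.seed(5)
  d1 <- rnorm(30); d2 <- rnorm(30)
  expected <- abs(sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2)))
  expect_equal(pm_cosine(outer(w, d1), outer(w, d2)), expected,
               tolerance = 1e-12)
})

test_that("similarity of a decomposition with itself is identity-like", {
  sim <- simulate_cohort(tiny_config())
  fit1 <- pma(subset_cohort(sim$cohort, "s1"))
  sm <- similarity_matrix(fit1, fit1, n_pms = 3)
  expect_equal(unname(diag(sm$sim)), rep(1, 3), tolerance = 1e-8)
  expect_lt(max(sm$sim - diag(diag(sm$sim))), 1e-8)
  expect_false(any(sm$best_match$permuted))
})

test_that("a planted component swap is reported as a rank permutation", {
  cfg <- tiny_config(n_signers = 2, K = 4, n_markers = 10, snr_db = Inf,
                     trial_s = 2)
  perms <- list(NULL, c(1L, 2L, 4L, 3L))
  sim <- simulate_cohort(cfg, permutations = perms)
  fit_com <- pma(subset_cohort(sim$cohort, "s1"))   # identity-transformed
  fit_ind <- pma(subset_cohort(sim$cohort, "s2"))   # components 3,4 swapped
  sm <- similarity_matrix(fit_ind, fit_com, n_pms = 4)
  expect_equal(sm$best_match$common_pm, c(1L, 2L, 4L, 3L))
  expect_gt(min(sm$best_match$sim), 0.99)
  expect_true(all(sm$best_match$permuted[3:4]))
})

test_that("a within-subspace rotation flags combinations of common PMs", {
  cfg <- tiny_config(n_signers = 2, K = 4, n_markers = 10, snr_db = Inf,
                     trial_s = 2, variance_decay = 0.9)
  rots <- list(NULL, plane_rotation(4, 1, 3, 45))
  sim <- simulate_cohort(cfg, rotations = rots)
  fit_com <- pma(subset_cohort(sim$cohort, "s1"))
  fit_ind <- pma(subset_cohort(sim$cohort, "s2"))
  sm <- similarity_matrix(fit_ind, fit_com, n_pms = 4)
  # the rotated components split their similarity over two common PMs;
  # for a 45-degree rotation of components (1, 3) with planted variances
  # v, both entries of the row are sqrt(v1 / (v1 + v3)) / sqrt(2)
  expect_true(any(sm$combination))
  v <- sim$truth$planted_variances
  expected <- sqrt(v[1] / (v[1] + v[3])) / sqrt(2)
  mixed <- which(sm$combination)[1]
  expect_equal(sort(sm$sim[mixed, ], decreasing = TRUE)[1:2],
               rep(expected, 2), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("cross-projection identities: own basis, full basis, bound", {
  sim <- simulate_cohort(tiny_config(n_signers = 2))
  fits <- lapply(c("s1", "s2"), function(id) {
    pma(subset_cohort(sim$cohort, id), cutoff = NULL)
  })
  names(fits) <- c("s1", "s2")
  # own basis in both roles -> ratios exactly 1
  self <- cross_projection(fits$s1, fits$s1, n = 3)
  expect_equal(self$ratio_a, 1)
  expect_equal(self$similarity, 1)
  # complete bases capture all variance regardless of whose they are
  p <- ncol(sim$cohort$matrix)
  full <- cross_projection(fits$s1, fits$s2, n = p)
  expect_equal(full$similarity, 1, tolerance = 1e-10)
  # optimality of PCA: directed ratio <= 1 on random instances
  set.seed(11)
  for (rep in 1:20) {
    xa <- centered_gaussian(120, 8, seed = 100 + rep)
    xb <- centered_gaussian(120, 8, seed = 200 + rep)
    fa <- pma(xa, cutoff = NULL)
    fb <- pma(xb, cutoff = NULL)
    n <- sample(1:8, 1)
    cp <- cross_projection(fa, fb, n = n)
    expect_lte(cp$ratio_a, 1 + 1e-10)
    expect_lte(cp$ratio_b, 1 + 1e-10)
  }
})

test_that("shared planted subspaces give unit cross-projection at N = K", {
  cfg <- tiny_config(n_signers = 2, snr_db = Inf, share_mode = "rotated")
  sim <- simulate_cohort(cfg)
  fits <- lapply(c("s1", "s2"), function(id) {
    pma(subset_cohort(sim$cohort, id), cutoff = NULL)
  })
  cp <- cross_projection(fits[[1]], fits[[2]], n = cfg$K)
  expect_equal(cp$similarity, 1, tolerance = 1e-8)
})

test_that("leave-one-out of an exact duplicate leaves orientations fixed", {
  sim <- simulate_cohort(tiny_config(n_signers = 1, trial_s = 2))
  blk <- sim$cohort$matrix
  co <- assemble_cohort(list(a = blk, b = blk), frame_rate = 50)
  loo <- loo_robustness(co, n_pms = 3)
  expect_lt(max(loo$angles), 0.1)
  expect_true(all(loo$robust))
})

test_that("two-signer LOO angles match a brute-force double-PCA oracle", {
  sim <- simulate_cohort(tiny_config(n_signers = 2, seed = 9))
  co <- sim$cohort
  loo <- loo_robustness(co, n_pms = 3)
  # oracle: direct svd of the full matrix and of each remaining block
  v_full <- svd(co$matrix)$v
  for (id in c("s1", "s2")) {
    other <- setdiff(c("s1", "s2"), id)
    v_red <- svd(co$matrix[segment_rows(co, other), ])$v
    ang <- acos(pmin(abs(colSums(v_full[, 1:3] * v_red[, 1:3])), 1)) * 180 / pi
    expect_equal(unname(loo$angles[id, ]), ang, tolerance = 1e-6)
  }
  expect_true(all(loo$angles >= 0 & loo$angles <= 90))
})

test_that("LOO angles shrink as each signer's share of the cohort shrinks", {
  angles_for <- function(n_signers) {
    sim <- simulate_cohort(tiny_config(n_signers = n_signers, seed = 5))
    max(loo_robustness(sim$cohort, n_pms = 3)$angles)
  }
  a2 <- angles_for(2)
  a6 <- angles_for(6)
  a12 <- angles_for(12)
  expect_gt(a2, a6)
  expect_gt(a6, a12)
})

test_that("principal angles: coincident and orthogonal subspaces", {
  q <- orthonormal_cols(10, 4, seed = 12)
  expect_lt(max(principal_angles(q[, 1:2], q[, 1:2])), 1e-6)
  expect_equal(principal_angles(q[, 1:2], q[, 3:4]), c(90, 90),
               tolerance = 1e-6)
  # rotation within a plane: one angle rotates, the other stays
  mix <- cbind(q[, 1], cos(0.3) * q[, 2] + sin(0.3) * q[, 3])
  ang <- principal_angles(q[, 1:2], mix)
  expect_equal(ang, c(0, 0.3 * 180 / pi), tolerance = 1e-6)
})
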