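# shared fixtures: small synthetic cohorts and constructions used across files

tiny_config <- function(...) {
  args <- list(n_signers = 3, n_trials = 4, trial_s = 1, fps = 50,
               n_markers = 8, K = 3, snr_db = 30, seed = 42)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

random_trial <- function(n = 10, markerset = synthetic_markerset(5),
                         fps = 100, seed = 1, signer_id = "s1",
                         trial_id = "t1") {
  set.seed(seed)
  coords <- array(stats::rnorm(n * markerset$count * 3, sd = 50),
                  dim = c(n, markerset$count, 3))
  mocap_trial(coords, markerset, fps, signer_id = signer_id,
              trial_id = trial_id)
}

# Givens rotation of components (i, j) by theta degrees
plane_rotation <- function(K, i, j, theta_deg) {
  th <- theta_deg * pi / 180
  R <- diag(K)
  R[i, i] <- cos(th)
  R[j, j] <- cos(th)
  R[i, j] <- -sin(th)
  R[j, i] <- sin(th)
  R
}

# centered random matrix (for decomposition tests that need zero col means)
centered_gaussian <- function(n, p, seed = 1, sd = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p, sd = sd), n, p)
  sweep(x, 2, colMeans(x), "-")
}
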