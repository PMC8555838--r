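#' Configuration for a synthetic multi-signer cohort
#'
#' Defaults reproduce the geometry of the reference corpus: 6 signers, 24
#' recording units of 5 s at 250 fps each (30,000 frames/signer), a planted
#' 8-dimensional synergy basis whose weight dynamics concentrate below 3 Hz,
#' white measurement noise at 20 dB SNR, and 20 markers (origin + 19
#' moving), so the assembled per-signer posture matrix is 30,000 x 57.
#'
#' @param n_signers Number of signers.
#' @param n_trials Recording units per signer.
#' @param trial_s Duration of each recording unit, seconds.
#' @param fps Frame rate, Hz.
#' @param n_markers Total markers including the origin (pelvis).
#' @param K Planted synergy dimension.
#' @param variance_decay Geometric ratio of successive planted component
#'   variances (0.6: each synergy carries 60% of the previous one's power).
#' @param snr_db Signal-to-noise ratio in the analysis coordinates, dB;
#'   `Inf` disables noise.
#' @param band_hz Band edge of the weight dynamics (white noise low-passed
#'   at this frequency; filter roll-off leaves residual power up to about
#'   twice the edge).
#' @param amplitude_mm Root total movement power in mm (Euclidean, across
#'   all analysis coordinates).
#' @param share_mode How individual signers' synergy axes relate to the
#'   shared basis: `"identical"` (same axes), `"rotated"` (per-signer
#'   orthogonal rotation within the planted subspace, so individual PMs are
#'   combinations of common PMs), `"permuted"` (same axes, reordered), or
#'   `"mixed"`.
#' @param seed Integer seed; the full cohort is reproducible per seed.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_signers = 6, n_trials = 24, trial_s = 5,
                          fps = 250, n_markers = 20, K = 8,
                          variance_decay = 0.6, snr_db = 20, band_hz = 3,
                          amplitude_mm = 100,
                          share_mode = c("identical", "rotated", "permuted",
                                         "mixed"),
                          seed = 1L) {
  share_mode <- match.arg(share_mode)
  stopifnot(n_signers >= 1, n_trials >= 1, trial_s > 0, fps > 0,
            n_markers >= 2, K >= 1, variance_decay > 0,
            band_hz < fps / 2, amplitude_mm > 0)
  if (K > 3 * (n_markers - 1)) {
    stop("K exceeds the analysis dimension 3 * (n_markers - 1)")
  }
  structure(
    list(n_signers = n_signers, n_trials = n_trials, trial_s = trial_s,
         fps = fps, n_markers = n_markers, K = K,
         variance_decay = variance_decay, snr_db = snr_db,
         band_hz = band_hz, amplitude_mm = amplitude_mm,
         share_mode = share_mode, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Draw a random orthonormal synergy basis
#'
#' K orthonormal directions in an `n_dims`-dimensional posture space,
#' obtained by QR-orthogonalizing a Gaussian matrix; deterministic per seed.
#'
#' @param n_dims Ambient dimension (3 x moving markers).
#' @param K Number of basis vectors; `K <= n_dims`.
#' @param seed Optional integer seed.
#' @return `n_dims x K` matrix with orthonormal columns.
#' @export
make_basis <- function(n_dims, K, seed = NULL) {
  if (K > n_dims) stop("K (", K, ") exceeds n_dims (", n_dims, ")")
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(n_dims * K), n_dims, K)))
  # fix signs so the draw is unique given the Gaussian sample
  flip <- vapply(seq_len(K), function(j) q[which.max(abs(q[, j])), j] < 0,
                 logical(1))
  q[, flip] <- -q[, flip]
  q
}

#' Generate band-limited synergy weight signals
#'
#' Independent Gaussian signals low-passed at `band_hz` (4th-order
#' zero-phase Butterworth), one independent stretch per recording segment.
#' Columns are exactly decorrelated and rescaled so the column variances
#' equal `variances` exactly (population denominator), making planted
#' variances recoverable by the decomposition to numerical precision.
#'
#' @param n Total frames.
#' @param variances Target per-component variances (length K); zero entries
#'   yield zero columns.
#' @param fps Frame rate, Hz.
#' @param band_hz Low-pass band edge, Hz.
#' @param n_segments Number of independent segments the rows divide into.
#' @param seed Optional integer seed.
#' @return `n x K` matrix.
#' @export
make_weight_signals <- function(n, variances, fps, band_hz = 3,
                                n_segments = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(variances)
  stopifnot(n %% n_segments == 0, band_hz < fps / 2)
  seg_len <- n %/% n_segments
  w <- matrix(stats::rnorm(n * K), n, K)
  for (s in seq_len(n_segments)) {
    rows <- ((s - 1) * seg_len + 1):(s * seg_len)
    w[rows, ] <- lowpass_weights(w[rows, , drop = FALSE], fps, band_hz, 4)
  }
  nz <- which(variances > 0)
  w[, setdiff(seq_len(K), nz)] <- 0
  if (length(nz)) {
    wz <- sweep(w[, nz, drop = FALSE], 2,
                colMeans(w[, nz, drop = FALSE]), "-")
    cv <- crossprod(wz) / n
    wz <- wz %*% backsolve(chol(cv), diag(length(nz)))  # exact decorrelation
    w[, nz] <- sweep(wz, 2, sqrt(variances[nz]), "*")
  }
  w
}

# fixed marker layout template (mm, pelvis-referenced): a plausible
# upper-body spread; exact geometry is immaterial to the analysis
marker_template <- function(n_moving) {
  j <- seq_len(n_moving)
  cbind(x = 350 * cos(2 * pi * j / n_moving),
        y = 150 + 550 * j / n_moving,
        z = 120 * sin(4 * pi * j / n_moving))
}

# smooth low-frequency pelvis wander (unreferenced origin trajectory)
pelvis_trajectory <- function(n, fps, sd_mm = 8) {
  raw <- matrix(stats::rnorm(n * 3), n, 3)
  sm <- lowpass_weights(raw, fps, cutoff = min(0.5, fps / 4), order = 2)
  sm <- sweep(sm, 2, colMeans(sm), "-")
  rms <- sqrt(mean(sm^2))
  if (rms > 0) sm <- sm * (sd_mm / rms)
  sweep(sm, 2, c(0, 950, 0), "+")   # pelvis sits ~950 mm up in world frame
}

#' Synthesize one signer's recordings from planted structure
#'
#' Builds the signer's pelvis-referenced analysis coordinates as
#' `scale * (mean_offsets + amplitude * W B'^T) + noise`, where `B'` is the
#' shared basis transformed by the signer's within-subspace rotation and/or
#' component permutation, `W` the signer's weight signals, and the noise is
#' white Gaussian in the analysis coordinates at the configured SNR. The
#' origin marker follows its own smooth trajectory, and the world-frame
#' marker positions are the origin plus the referenced coordinates, cut
#' into `n_trials` recording units.
#'
#' @param config A [cohort_config()].
#' @param basis Shared `p x K` orthonormal basis (analysis coordinates).
#' @param weights The signer's `n x K` weight signals.
#' @param transform List with `mean_offset` (`p`-vector, mm), `scale`
#'   (positive scalar), `rotation` (`K x K` orthogonal or `NULL`),
#'   `permutation` (length-K integer or `NULL`).
#' @param markerset The cohort [marker_set()].
#' @param signer_id Identifier for the generated trials.
#' @return List with `trials` (list of [mocap_trial()]) and `noise_sd`.
#' @export
synthesize_signer <- function(config, basis, weights, transform, markerset,
                              signer_id) {
  p <- nrow(basis)
  n <- nrow(weights)
  b <- basis
  if (!is.null(transform$rotation)) b <- b %*% transform$rotation
  if (!is.null(transform$permutation)) b <- b[, transform$permutation,
                                              drop = FALSE]
  movement <- config$amplitude_mm * tcrossprod(weights, b)  # n x p
  signal_power <- (transform$scale * config$amplitude_mm)^2
  noise_sd <- if (is.finite(config$snr_db)) {
    sqrt(signal_power / (p * 10^(config$snr_db / 10)))
  } else {
    0
  }
  ref <- transform$scale * sweep(movement, 2, transform$mean_offset, "+")
  if (noise_sd > 0) ref <- ref + matrix(stats::rnorm(n * p, sd = noise_sd),
                                        n, p)
  org <- pelvis_trajectory(n, config$fps)
  moving <- analysis_markers(markerset)
  m_all <- markerset$count
  coords <- array(0, dim = c(n, m_all, 3),
                  dimnames = list(NULL, markerset$names, c("x", "y", "z")))
  coords[, markerset$origin, ] <- org
  for (j in seq_along(moving)) {
    cols <- (3 * (j - 1) + 1):(3 * j)
    coords[, moving[j], ] <- org + ref[, cols]
  }
  seg_len <- n %/% config$n_trials
  trials <- lapply(seq_len(config$n_trials), function(k) {
    rows <- ((k - 1) * seg_len + 1):(k * seg_len)
    mocap_trial(coords[rows, , , drop = FALSE], markerset, config$fps,
                signer_id = signer_id, trial_id = sprintf("t%02d", k))
  })
  list(trials = trials, noise_sd = noise_sd)
}

#' Generate a synthetic cohort with planted synergy structure
#'
#' Draws a shared orthonormal synergy basis, per-signer band-limited weight
#' signals with geometrically decaying planted variances (normalized to
#' unit total), per-signer anthropometric transforms (mean-posture offset
#' and uniform scale), optional per-signer within-subspace rotations or
#' component permutations according to `share_mode`, and white coordinate
#' noise at the configured SNR. Everything is reproducible from
#' `config$seed`, and the full ground truth is returned for recovery
#' scoring.
#'
#' @param config A [cohort_config()].
#' @param rotations Optional list (length `n_signers`) of `K x K` rotations
#'   overriding the `share_mode` draw (`NULL` entries = identity); used to
#'   plant specific axis changes in chosen signers.
#' @param permutations Optional list of length-K permutations, same
#'   convention.
#' @return List with `trials` (flat list of [mocap_trial()], signer-major
#'   order), `truth` (list: `basis`, `planted_variances`, `weight_signals`,
#'   `transforms`, `noise_sd`, `seed`), `markerset`, `config`.
#' @export
generate_cohort <- function(config, rotations = NULL, permutations = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  markerset <- synthetic_markerset(config$n_markers)
  p <- 3 * (config$n_markers - 1)
  v <- config$variance_decay^(seq_len(config$K) - 1)
  v <- v / sum(v)
  basis <- make_basis(p, config$K)
  template <- marker_template(config$n_markers - 1)
  n <- round(config$n_trials * config$trial_s * config$fps)

  ids <- sprintf("s%d", seq_len(config$n_signers))
  transforms <- vector("list", config$n_signers)
  names(transforms) <- ids
  weight_signals <- transforms
  all_trials <- list()
  noise_sd <- numeric(config$n_signers)
  for (i in seq_len(config$n_signers)) {
    rot <- if (!is.null(rotations)) rotations[[i]] else NULL
    perm <- if (!is.null(permutations)) permutations[[i]] else NULL
    if (is.null(rotations) && is.null(permutations)) {
      mode_i <- switch(config$share_mode,
                       identical = "identical",
                       rotated = "rotated",
                       permuted = "permuted",
                       mixed = sample(c("identical", "rotated", "permuted"),
                                      1))
      if (mode_i == "rotated" && config$K >= 2) {
        rot <- qr.Q(qr(matrix(stats::rnorm(config$K^2), config$K)))
        if (det(rot) < 0) rot[, 1] <- -rot[, 1]
      } else if (mode_i == "permuted") {
        perm <- sample(config$K)
      }
    }
    transforms[[i]] <- list(
      mean_offset = as.vector(t(template)) +
        stats::rnorm(p, sd = 20),
      scale = exp(stats::rnorm(1, 0, 0.08)),
      rotation = rot, permutation = perm
    )
    weight_signals[[i]] <- make_weight_signals(
      n, v, config$fps, config$band_hz, n_segments = config$n_trials)
    syn <- synthesize_signer(config, basis, weight_signals[[i]],
                             transforms[[i]], markerset, ids[i])
    noise_sd[i] <- syn$noise_sd
    all_trials <- c(all_trials, syn$trials)
  }
  list(trials = all_trials,
       truth = list(basis = basis, planted_variances = v,
                    weight_signals = weight_signals, transforms = transforms,
                    noise_sd = noise_sd, seed = config$seed),
       markerset = markerset, config = config)
}

#' Simulate a cohort and run it through ingestion and normalization
#'
#' Convenience wrapper: [generate_cohort()], pelvis-referencing of every
#' trial, posture-matrix assembly and per-signer normalization.
#'
#' @param config A [cohort_config()].
#' @param keep_trials Also return the raw trial list (memory-heavy for
#'   full-size cohorts).
#' @param ... Passed to [generate_cohort()].
#' @return List with `cohort` (a `"norm_cohort"`), `posture` (the
#'   unnormalized `posture_matrix`), `truth`, `markerset`, `config`, and
#'   optionally `trials`.
#' @export
simulate_cohort <- function(config, keep_trials = FALSE, ...) {
  gen <- generate_cohort(config, ...)
  trials <- lapply(gen$trials, reference_to_origin)
  posture <- build_posture_matrix(trials)
  cohort <- normalize_cohort(posture)
  out <- list(cohort = cohort, posture = posture, truth = gen$truth,
              markerset = gen$markerset, config = gen$config)
  if (keep_trials) out$trials <- gen$trials
  out
}
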