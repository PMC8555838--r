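#' Explained-variance table
#'
#' Per-PM explained variance and cumulative percentages for the leading
#' components, with an empty `description` column for the analyst's
#' interpretation of each synergy. When the fit carries filtered weights,
#' the explained variance recomputed from them is reported alongside.
#'
#' @param fit A [pma()] fit.
#' @param n_show Number of components to tabulate (default 15).
#' @return A data.frame with columns `pm`, `ev_pct`, `cum_ev_pct`,
#'   optionally `ev_pct_filtered`, and `description`.
#' @export
variance_table <- function(fit, n_show = 15) {
  tab <- summary(fit, n_show = n_show)$table
  tab$description <- ""
  tab
}

pld_planes <- list(frontal = c("x", "y"), sagittal = c("z", "y"),
                   transverse = c("x", "z"))

#' Export a principal movement as a point-light display
#'
#' Projects a resynthesized PM trajectory onto one anatomical plane and
#' writes a coordinate animation (CSV or JSON) that external tools can
#' render as a moving dot display. The coordinate convention is
#' x = mediolateral, y = vertical, z = anteroposterior, so the frontal
#' plane keeps (x, y), the sagittal plane (z, y), and the transverse plane
#' (x, z). The frames of minimum and maximum PM weighting can be flagged as
#' key frames (the gray/black extreme postures of stick-figure plots).
#'
#' @param pm A `"principal_movement"` from [pm_trajectory()].
#' @param path Output file path.
#' @param plane `"frontal"`, `"sagittal"` or `"transverse"`.
#' @param frames Optional subset of frame indices to export.
#' @param key_frames Optional named vector `c(min = ..., max = ...)` of
#'   frame indices (relative to the PM's rows) to flag, e.g. from
#'   [extreme_frames()].
#' @param format `"json"` (default; lossless round trip via [read_pld()])
#'   or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_pld <- function(pm, path, plane = c("frontal", "sagittal",
                                           "transverse"),
                       frames = NULL, key_frames = NULL,
                       format = c("auto", "json", "csv")) {
  plane <- match.arg(plane)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  }
  axes <- pld_planes[[plane]]
  traj <- pm$trajectory
  if (is.null(frames)) frames <- seq_len(nrow(traj))
  markers <- unique(sub("_[xyz]$", "", colnames(traj)))
  cols_h <- paste0(markers, "_", axes[1])
  cols_v <- paste0(markers, "_", axes[2])
  out <- data.frame(frame = frames,
                    key = ifelse(frames %in% key_frames,
                                 names(key_frames)[match(frames, key_frames)],
                                 ""))
  h <- traj[frames, cols_h, drop = FALSE]
  v <- traj[frames, cols_v, drop = FALSE]
  colnames(h) <- paste0(markers, "_h")
  colnames(v) <- paste0(markers, "_v")
  out <- cbind(out, as.data.frame(h), as.data.frame(v))
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(pm = pm$index, signer_id = pm$signer_id, plane = plane,
           axes = axes, frame_rate = pm$frame_rate, markers = markers,
           key_frames = as.list(key_frames),
           frame = frames,
           h = unname(as.matrix(h)), v = unname(as.matrix(v))),
      path, digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read back a JSON point-light display
#'
#' @param path A file written by [export_pld()] with `format = "json"`.
#' @return List with `plane`, `axes`, `markers`, `frame`, `key_frames`, and
#'   matrices `h`, `v` (frames x markers).
#' @export
read_pld <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$h <- as.matrix(x$h)
  x$v <- as.matrix(x$v)
  colnames(x$h) <- paste0(x$markers, "_h")
  colnames(x$v) <- paste0(x$markers, "_v")
  x
}

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with its standard default: cohort
#' geometry/generation, the 6 Hz 4th-order weight filter, Welch PSD
#' parameters, the component-retention policy, cosine-similarity mode and
#' the 0.7 / 0.5 similarity and 15-degree robustness thresholds. The
#' configuration round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param cohort A [cohort_config()] describing the (synthetic) input.
#' @param cutoff,order Weight low-pass filter (Hz / order).
#' @param welch_segment_s,welch_overlap,welch_window Welch PSD parameters.
#' @param n_pms `"auto"` (smallest K reaching `ev_target`) or an integer.
#' @param ev_target Cumulative explained-variance target for `"auto"`.
#' @param sim_mode `"abs"` or `"signed"` cosine similarity.
#' @param sim_high,sim_moderate Similarity thresholds.
#' @param angle_threshold Leave-one-out robustness threshold, degrees.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            cutoff = 6, order = 4,
                            welch_segment_s = 4, welch_overlap = 0.5,
                            welch_window = "hann",
                            n_pms = "auto", ev_target = 0.946,
                            sim_mode = c("abs", "signed"),
                            sim_high = 0.7, sim_moderate = 0.5,
                            angle_threshold = 15) {
  sim_mode <- match.arg(sim_mode)
  structure(
    list(cohort = cohort, cutoff = cutoff, order = order,
         welch_segment_s = welch_segment_s, welch_overlap = welch_overlap,
         welch_window = welch_window, n_pms = n_pms, ev_target = ev_target,
         sim_mode = sim_mode, sim_high = sim_high,
         sim_moderate = sim_moderate, angle_threshold = angle_threshold),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `"pipeline_config"`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, x$cohort)
  do.call(pipeline_config, c(list(cohort = cohort),
                             x[setdiff(names(x), "cohort")]))
}

#' Mean cross-projection similarity as a function of subspace size
#'
#' For every ordered pair of signers, projects one signer's movements onto
#' their own and the other's leading `N` components and accumulates the
#' directed variance ratios for `N = 1, ..., n_max`; symmetric pair values
#' are the means of the two directions, and the summary curve averages over
#' pairs.
#'
#' @param fits Named list of per-signer [pma()] fits (with stored data).
#' @param n_max Largest subspace size.
#' @return List with `pairs` (matrix, pair x N of symmetric similarities)
#'   and `mean` (length-`n_max` vector).
#' @export
cross_projection_curve <- function(fits, n_max) {
  ids <- names(fits)
  stopifnot(length(ids) >= 2)
  cumvar <- function(fit, basis_fit) {
    w <- as.matrix(fit$data) %*% basis_fit$rotation[, seq_len(n_max),
                                                    drop = FALSE]
    cumsum(apply(w, 2, stats::var))
  }
  own <- lapply(fits, function(f) cumvar(f, f))
  combos <- utils::combn(ids, 2)
  pairs <- matrix(NA_real_, ncol(combos), n_max,
                  dimnames = list(apply(combos, 2, paste, collapse = ":"),
                                  seq_len(n_max)))
  for (k in seq_len(ncol(combos))) {
    a <- combos[1, k]
    b <- combos[2, k]
    r_ab <- cumvar(fits[[a]], fits[[b]]) / own[[a]]
    r_ba <- cumvar(fits[[b]], fits[[a]]) / own[[b]]
    pairs[k, ] <- (r_ab + r_ba) / 2
  }
  list(pairs = pairs, mean = colMeans(pairs))
}

#' Run the full principal-movement pipeline
#'
#' Executes every stage on a synthetic cohort: generation, pelvis
#' referencing and assembly, per-signer normalization, the common
#' decomposition and one individual decomposition per signer, weight PSDs,
#' the three comparison procedures (leave-one-out robustness,
#' individual-vs-common cosine similarity, pairwise cross-projection), and
#' the report tables. Deterministic given the configuration (which includes
#' the seed). With `output_dir` set, tables are written as CSV/JSON along
#' with a manifest of MD5 checksums.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for report files.
#' @param verbose Log each stage and its parameters.
#' @return List with elements `cohort`, `truth`, `fit_common`,
#'   `fits_individual`, `psd`, `variance_table`, `loo`, `similarity` (per
#'   signer), `cross_projection` (curve + at `n_pms`), `n_pms`, `manifest`
#'   (when writing).
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  cc <- config$cohort
  say("simulate: %d signers x %d trials x %g s @ %g fps, K=%d, SNR=%g dB, seed=%d",
      cc$n_signers, cc$n_trials, cc$trial_s, cc$fps, cc$K, cc$snr_db, cc$seed)
  sim <- simulate_cohort(cc)
  say("normalize: %d rows x %d columns", nrow(sim$cohort$matrix),
      ncol(sim$cohort$matrix))

  n_pms_arg <- if (identical(config$n_pms, "auto")) NULL else config$n_pms
  say("decompose: cutoff=%g Hz, order=%d, n_pms=%s", config$cutoff,
      config$order, as.character(config$n_pms))
  fit_common <- pma(sim$cohort, n_pms = n_pms_arg,
                    ev_target = config$ev_target,
                    cutoff = config$cutoff, order = config$order)
  ids <- names(sim$cohort$params)
  fits_individual <- lapply(ids, function(id) {
    pma(subset_cohort(sim$cohort, id), n_pms = n_pms_arg,
        ev_target = config$ev_target,
        cutoff = config$cutoff, order = config$order)
  })
  names(fits_individual) <- ids
  n_pms <- fit_common$n_pms

  say("spectra: Welch %g s %s segments, %.0f%% overlap",
      config$welch_segment_s, config$welch_window, 100 * config$welch_overlap)
  psd <- welch_psd(fit_common$weights[, seq_len(n_pms), drop = FALSE],
                   cc$fps, segment_s = min(config$welch_segment_s,
                                           cc$trial_s),
                   overlap = config$welch_overlap,
                   window = config$welch_window)

  say("compare: LOO (threshold %g deg), cosine (%s), cross-projection",
      config$angle_threshold, config$sim_mode)
  loo <- if (length(ids) >= 2) {
    loo_robustness(sim$cohort, n_pms = n_pms,
                   threshold = config$angle_threshold, fit_full = fit_common)
  } else {
    NULL
  }
  similarity <- lapply(ids, function(id) {
    similarity_matrix(fits_individual[[id]], fit_common,
                      n_pms = n_pms, mode = config$sim_mode,
                      high = config$sim_high,
                      moderate = config$sim_moderate)
  })
  names(similarity) <- ids
  xproj <- if (length(ids) >= 2) {
    cross_projection_curve(fits_individual, n_max = n_pms)
  } else {
    NULL
  }

  vt <- variance_table(fit_common)
  out <- list(cohort = sim$cohort, truth = sim$truth,
              fit_common = fit_common, fits_individual = fits_individual,
              psd = psd, variance_table = vt, loo = loo,
              similarity = similarity,
              cross_projection = list(
                curve = xproj,
                at_n_pms = if (!is.null(xproj)) unname(xproj$mean[n_pms])),
              n_pms = n_pms, config = config)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    wr <- function(obj, name) {
      f <- file.path(output_dir, name)
      utils::write.csv(obj, f, row.names = TRUE, quote = FALSE)
      files <<- c(files, f)
    }
    utils::write.csv(vt, file.path(output_dir, "variance_table.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- file.path(output_dir, "variance_table.csv")
    if (!is.null(loo)) wr(round(loo$angles, 6), "loo_angles.csv")
    for (id in ids) {
      wr(round(similarity[[id]]$sim, 6),
         sprintf("similarity_%s.csv", id))
    }
    if (!is.null(xproj)) wr(round(xproj$pairs, 8), "cross_projection.csv")
    write_pipeline_config(config, file.path(output_dir, "config.yaml"))
    files <- c(files, file.path(output_dir, "config.yaml"))
    manifest <- data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)))
    utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    out$manifest <- manifest
    say("report: %d files in %s", length(files) + 1, output_dir)
  }
  out
}
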