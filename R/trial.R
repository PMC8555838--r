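#' Construct a motion-capture trial
#'
#' A trial is one recording unit: a `T x M x 3` array of marker coordinates
#' at a fixed frame rate. Validation is strict: any missing value is an
#' error (no gap-filling is performed anywhere in the package).
#'
#' @param coords Numeric array `T x M x 3` (frames x markers x xyz).
#' @param markerset A [marker_set()]; `M` must equal `markerset$count`.
#' @param frame_rate Sampling rate in Hz.
#' @param signer_id,trial_id Identifiers carried through the pipeline.
#' @param units Coordinate units; `"mm"` by convention.
#'
#' @return An object of class `"mocap_trial"`.
#' @export
mocap_trial <- function(coords, markerset, frame_rate,
                        signer_id = "s1", trial_id = "t1", units = "mm") {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be a T x M x 3 array")
  }
  if (dim(coords)[2] != markerset$count) {
    stop("coords has ", dim(coords)[2], " markers but the marker set declares ",
         markerset$count)
  }
  if (dim(coords)[1] < 1L) stop("trial must contain at least one frame")
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be a positive number (Hz)")
  }
  bad <- which(apply(is.na(coords), 1, any))
  if (length(bad)) {
    stop("trial '", trial_id, "' contains missing coordinates at frame(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  }
  dimnames(coords) <- list(NULL, markerset$names, c("x", "y", "z"))
  structure(
    list(coords = coords, markerset = markerset,
         frame_rate = as.numeric(frame_rate),
         signer_id = as.character(signer_id),
         trial_id = as.character(trial_id), units = units),
    class = "mocap_trial"
  )
}

#' @export
print.mocap_trial <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<mocap_trial> %s/%s: %d frames x %d markers @ %g fps (%.3g s, %s)\n",
              x$signer_id, x$trial_id, d[1], d[2], x$frame_rate,
              d[1] / x$frame_rate, x$units))
  invisible(x)
}

n_frames <- function(trial) dim(trial$coords)[1]

#' Read a marker-trajectory trial from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`csv`}{Wide format: one row per frame, header `marker_x` /
#'     `marker_y` / `marker_z` per marker (e.g. `pelvis_x`). CSV files carry
#'     no rate metadata, so `frame_rate` must be supplied.}
#'   \item{`trc`}{Tab-separated TRC with the standard five header lines;
#'     frame rate is taken from the header.}
#' }
#' C3D is a binary format for which no parser is available to this package;
#' convert such files to TRC or CSV first.
#'
#' All markers named in `markerset` must be present (extra columns are
#' ignored); coordinates are reordered to the marker-set order. Missing
#' values anywhere are an error listing the offending frames.
#'
#' @param path File path.
#' @param markerset A [marker_set()].
#' @param format `"csv"`, `"trc"`, or `"c3d"` (rejected with advice).
#'   Default guesses from the file extension.
#' @param frame_rate Hz; required for CSV, overrides the header for TRC.
#' @param signer_id,trial_id Identifiers; default from the file name.
#' @param units Coordinate units of the file.
#' @return A [mocap_trial()].
#' @export
read_trial <- function(path, markerset,
                       format = c("auto", "csv", "trc", "c3d"),
                       frame_rate = NULL,
                       signer_id = "s1",
                       trial_id = sub("\\.[^.]*$", "", basename(path)),
                       units = "mm") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     trc = "trc", c3d = "c3d", "csv")
  }
  if (format == "c3d") {
    stop("C3D is a binary format not supported by this package; ",
         "export the recording to TRC or CSV and re-run")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    if (is.null(frame_rate)) {
      stop("CSV files carry no frame-rate metadata; supply frame_rate=")
    }
    df <- utils::read.csv(path, check.names = FALSE)
    coords <- wide_to_coords(df, markerset)
  } else {
    trc <- parse_trc(path)
    if (is.null(frame_rate)) frame_rate <- trc$frame_rate
    coords <- wide_to_coords(trc$data, markerset)
  }
  mocap_trial(coords, markerset, frame_rate,
              signer_id = signer_id, trial_id = trial_id, units = units)
}

# wide data.frame with marker_x/_y/_z columns -> T x M x 3 array
wide_to_coords <- function(df, markerset) {
  want <- posture_colnames(markerset$names)
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols)) {
    missing_markers <- unique(sub("_[xyz]$", "", missing_cols))
    stop("marker(s) missing from file: ",
         paste(missing_markers, collapse = ", "))
  }
  m <- as.matrix(df[, want, drop = FALSE])
  array(m, dim = c(nrow(m), 3, markerset$count),
        dimnames = list(NULL, c("x", "y", "z"), markerset$names)) |>
    aperm(c(1, 3, 2))
}

# minimal TRC parser: header line 3 holds rate/frame counts; line 4 marker
# labels; data starts after the units row (blank lines tolerated)
parse_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("not a TRC file (too short): ", path)
  hdr <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  frame_rate <- suppressWarnings(as.numeric(hdr[1]))
  if (is.na(frame_rate) || frame_rate <= 0) {
    stop("TRC header has no valid DataRate: ", path)
  }
  labels <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  labels <- labels[labels != ""][-(1:2)]      # drop Frame#, Time
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  rows <- lapply(strsplit(data_lines, "\t", fixed = TRUE),
                 function(r) suppressWarnings(as.numeric(r)))
  nc <- 2 + 3 * length(labels)
  mat <- do.call(rbind, lapply(rows, function(r) {
    length(r) <- nc
    r
  }))
  coords <- mat[, -(1:2), drop = FALSE]
  colnames(coords) <- posture_colnames(labels)
  list(frame_rate = frame_rate, data = as.data.frame(coords))
}

#' Write a trial to disk
#'
#' Writes the wide CSV dialect or a TRC file that [read_trial()] can read
#' back; round-trips preserve coordinates to better than 1e-9 (full
#' double-precision text).
#'
#' @param trial A [mocap_trial()].
#' @param path Output path.
#' @param format `"csv"` or `"trc"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, format = c("auto", "csv", "trc")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "trc") "trc" else "csv"
  }
  wide <- coords_to_wide(trial$coords)
  if (format == "csv") {
    utils::write.csv(format(wide, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    ms <- trial$markerset
    tt <- (seq_len(nrow(wide)) - 1) / trial$frame_rate
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
      "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
      sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d",
              trial$frame_rate, trial$frame_rate, nrow(wide), ms$count,
              trial$units, trial$frame_rate, nrow(wide)),
      paste(c("Frame#", "Time",
              as.vector(rbind(ms$names, "", ""))), collapse = "\t"),
      paste(c("", "", as.vector(t(outer(c("X", "Y", "Z"),
                                        seq_len(ms$count), paste0)))),
            collapse = "\t")
    ), con)
    body <- cbind(seq_len(nrow(wide)), tt, as.matrix(wide))
    writeLines(apply(body, 1, function(r) {
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = "\t")
    }), con)
  }
  invisible(path)
}

# T x M x 3 array -> wide data.frame with marker_x/_y/_z columns
coords_to_wide <- function(coords) {
  markers <- dimnames(coords)[[2]]
  flat <- aperm(coords, c(1, 3, 2))
  dim(flat) <- c(dim(coords)[1], 3 * dim(coords)[2])
  colnames(flat) <- posture_colnames(markers)
  as.data.frame(flat)
}

#' Express all markers relative to the origin marker
#'
#' Subtracts the origin (pelvis) marker's position from every marker at every
#' frame, so the origin marker becomes (0, 0, 0) throughout. The operation is
#' idempotent and preserves inter-marker distances within each frame.
#'
#' @param trial A [mocap_trial()].
#' @return A referenced [mocap_trial()].
#' @export
reference_to_origin <- function(trial) {
  ms <- trial$markerset
  if (ms$origin_external) return(trial)
  org <- trial$coords[, ms$origin, , drop = FALSE]  # T x 1 x 3
  trial$coords <- trial$coords - org[, rep(1L, ms$count), , drop = FALSE]
  trial
}

#' Extract a fixed-duration window from a trial
#'
#' Takes `round(duration_s * frame_rate)` frames starting at `start_s`
#' (half-open frame window).
#'
#' @param trial A [mocap_trial()].
#' @param start_s Window start in seconds (0 = first frame).
#' @param duration_s Window length in seconds.
#' @return A [mocap_trial()] with the windowed frames.
#' @export
extract_segment <- function(trial, start_s = 0, duration_s) {
  fr <- trial$frame_rate
  first <- round(start_s * fr) + 1L
  n <- round(duration_s * fr)
  last <- first + n - 1L
  if (last > n_frames(trial) || first < 1L) {
    stop(sprintf(
      "window [%g s, %g s) exceeds trial '%s' (%.6g s available)",
      start_s, start_s + duration_s, trial$trial_id,
      n_frames(trial) / fr))
  }
  trial$coords <- trial$coords[first:last, , , drop = FALSE]
  trial
}
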