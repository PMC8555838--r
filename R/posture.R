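#' Assemble trials into a posture matrix
#'
#' Stacks pelvis-referenced trials into the `T_total x 3M` posture-vector
#' matrix: one row per frame, columns ordered
#' `[x1, y1, z1, ..., xM, yM, zM]` over the analysis markers. By default the
#' origin marker is dropped: after referencing, its coordinates are
#' identically zero and would contribute three constant columns. (For the
#' 21-marker set this yields 60 columns; the 20-marker synthetic default
#' yields the published 57-column geometry — the source corpus reports
#' 21 markers yet 57 columns, an inconsistency documented in the vignette.)
#'
#' A `segments` attribute records which rows belong to which
#' (signer, trial); the segments partition the rows exactly.
#'
#' @param trials List of [mocap_trial()] objects, all sharing the marker set
#'   and frame rate, already referenced via [reference_to_origin()].
#' @param drop_origin Drop the origin marker's (all-zero) columns.
#' @param check_referenced Verify that the origin marker is at zero
#'   (tolerance 1e-8); set `FALSE` for externally-referenced data.
#' @return A numeric matrix of class `"posture_matrix"` with attributes
#'   `frame_rate`, `markers` (analysis marker labels) and `segments`
#'   (data.frame: `signer_id`, `trial_id`, `start`, `end`, inclusive rows).
#' @export
build_posture_matrix <- function(trials, drop_origin = TRUE,
                                 check_referenced = TRUE) {
  stopifnot(length(trials) >= 1)
  ms <- trials[[1]]$markerset
  fr <- trials[[1]]$frame_rate
  for (tr in trials) {
    if (!identical(tr$markerset$names, ms$names)) {
      stop("trials use different marker sets")
    }
    if (tr$frame_rate != fr) {
      stop("mixed frame rates: ", fr, " vs ", tr$frame_rate,
           " (trial '", tr$trial_id, "')")
    }
    if (check_referenced && !ms$origin_external) {
      if (max(abs(tr$coords[, ms$origin, ])) > 1e-8) {
        stop("trial '", tr$trial_id, "' is not pelvis-referenced; ",
             "run reference_to_origin() first")
      }
    }
  }
  markers <- analysis_markers(ms, drop_origin)
  blocks <- lapply(trials, function(tr) {
    as.matrix(coords_to_wide(tr$coords[, markers, , drop = FALSE]))
  })
  rows <- vapply(blocks, nrow, integer(1))
  end <- cumsum(rows)
  segs <- data.frame(
    signer_id = vapply(trials, function(tr) tr$signer_id, character(1)),
    trial_id = vapply(trials, function(tr) tr$trial_id, character(1)),
    start = c(1L, utils::head(end, -1) + 1L),
    end = end,
    stringsAsFactors = FALSE
  )
  x <- do.call(rbind, blocks)
  colnames(x) <- posture_colnames(markers)
  structure(x, frame_rate = fr, markers = markers, segments = segs,
            class = c("posture_matrix", class(x)))
}

#' @export
print.posture_matrix <- function(x, ...) {
  segs <- attr(x, "segments")
  cat(sprintf(
    "<posture_matrix> %d frames x %d coords (%d markers) @ %g fps; %d trial(s), %d signer(s)\n",
    nrow(x), ncol(x), length(attr(x, "markers")), attr(x, "frame_rate"),
    nrow(segs), length(unique(segs$signer_id))))
  invisible(x)
}

#' Row indices of a signer (or trial) block
#'
#' @param x A posture matrix (or an object carrying a `segments` attribute /
#'   element).
#' @param signer_id Signer whose rows to select.
#' @param trial_id Optional trial within the signer.
#' @return Integer vector of row indices.
#' @export
segment_rows <- function(x, signer_id, trial_id = NULL) {
  segs <- attr(x, "segments")
  if (is.null(segs)) segs <- x$segments
  keep <- segs$signer_id == signer_id
  if (!is.null(trial_id)) keep <- keep & segs$trial_id == trial_id
  if (!any(keep)) stop("no segment for signer '", signer_id, "'",
                       if (!is.null(trial_id)) paste0(" trial '", trial_id, "'"))
  unlist(lapply(which(keep), function(i) segs$start[i]:segs$end[i]),
         use.names = FALSE)
}

#' Signer identifiers present in a posture matrix or cohort
#' @param x Object with a `segments` attribute or element.
#' @return Character vector in block order.
#' @export
signer_ids <- function(x) {
  segs <- attr(x, "segments")
  if (is.null(segs)) segs <- x$segments
  unique(segs$signer_id)
}
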