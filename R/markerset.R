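#' Define a marker set
#'
#' A marker set names the markers of a motion-capture configuration, in the
#' order their coordinates appear in posture vectors, and declares which
#' marker is the reference origin used for pelvis-referencing.
#'
#' @param names Character vector of unique marker labels, in posture-vector
#'   order.
#' @param origin Label of the reference marker (the coordinate origin after
#'   referencing). Must be one of `names` unless `origin_external = TRUE`.
#' @param origin_external Logical; set `TRUE` when the origin is an external
#'   fixed point not recorded as a marker.
#'
#' @return An object of class `"marker_set"`: a list with elements `names`,
#'   `count`, `origin`, `origin_external`.
#' @examples
#' ms <- marker_set(c("pelvis", "sternum", "L hand"), origin = "pelvis")
#' ms$count
#' @export
marker_set <- function(names, origin = "pelvis", origin_external = FALSE) {
  names <- as.character(names)
  if (anyDuplicated(names)) {
    stop("marker names must be unique; duplicated: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (!origin_external && !origin %in% names) {
    stop("origin marker '", origin, "' is not in the marker set")
  }
  structure(
    list(names = names, count = length(names), origin = origin,
         origin_external = origin_external),
    class = "marker_set"
  )
}

#' @export
print.marker_set <- function(x, ...) {
  cat("<marker_set> ", x$count, " markers, origin = '", x$origin, "'",
      if (x$origin_external) " (external)", "\n", sep = "")
  cat("  ", paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The 21-marker upper-body set
#'
#' The default upper-body configuration for sign-language capture: 21 markers
#' covering pelvis, trunk, head, shoulders, elbows (one per side), wrists and
#' hands, with the pelvis as reference origin.
#'
#' Note that pelvis-referencing makes the origin marker's columns identically
#' zero, so an assembled posture matrix built with the default
#' `drop_origin = TRUE` has 20 x 3 = 60 columns for this set; see
#' [build_posture_matrix()].
#'
#' @return A [marker_set()] with 21 labels and origin `"pelvis"`.
#' @export
lsf_markerset <- function() {
  marker_set(c(
    "pelvis", "stomach", "T10", "sternum", "C7",
    "LB head", "LF head", "RB head", "RF head",
    "L shoulder", "L elbow", "LB wrist", "LF wrist", "LB hand", "LF hand",
    "R shoulder", "R elbow", "RB wrist", "RF wrist", "RB hand", "RF hand"
  ), origin = "pelvis")
}

#' Generic marker set for synthetic cohorts
#'
#' Synthetic cohorts carry generic marker labels (`pelvis`, `m02`, ...,
#' `mNN`) rather than anatomical names, to make clear that no articulated
#' body model is implied. The default of 20 markers (origin plus 19 moving
#' markers) gives a 57-column posture matrix after origin-dropping, the
#' geometry of the reference corpus.
#'
#' @param n_markers Total number of markers including the origin.
#' @return A [marker_set()].
#' @export
synthetic_markerset <- function(n_markers = 20) {
  stopifnot(n_markers >= 2)
  marker_set(c("pelvis", sprintf("m%02d", seq(2, n_markers))),
             origin = "pelvis")
}

#' Markers entering the analysis (non-origin markers)
#'
#' @param markerset A [marker_set()].
#' @param drop_origin Drop the origin marker (its referenced coordinates are
#'   identically zero).
#' @return Character vector of marker labels.
#' @keywords internal
analysis_markers <- function(markerset, drop_origin = TRUE) {
  if (drop_origin && !markerset$origin_external) {
    setdiff(markerset$names, markerset$origin)
  } else {
    markerset$names
  }
}

# column labels for a posture matrix: marker_x, marker_y, marker_z per marker
posture_colnames <- function(markers) {
  as.vector(t(outer(markers, c("x", "y", "z"), paste, sep = "_")))
}
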