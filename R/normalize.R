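#' Per-signer mean posture
#'
#' Column-wise mean of a signer's posture rows: the signer's average posture
#' over all their recording units.
#'
#' @param x Numeric matrix (rows = frames).
#' @return Numeric vector of length `ncol(x)`.
#' @export
mean_posture <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty block: cannot compute a mean posture")
  colMeans(x)
}

#' Center posture rows on a mean posture
#'
#' @param x Numeric matrix.
#' @param mu Mean posture vector, length `ncol(x)`.
#' @return Centered matrix.
#' @export
center_posture <- function(x, mu = mean_posture(x)) {
  if (length(mu) != ncol(x)) {
    stop("mean posture has length ", length(mu), " but matrix has ",
         ncol(x), " columns")
  }
  sweep(x, 2, mu, "-")
}

#' Mean Euclidean norm of centered posture rows
#'
#' The mean over frames of the per-frame Euclidean norm of the posture
#' vector (not the norm of the mean, not an RMS).
#'
#' @param x Centered numeric matrix.
#' @return Positive scalar.
#' @export
mean_euclidean_norm <- function(x) {
  d <- mean(sqrt(rowSums(x^2)))
  if (d < .Machine$double.eps * 1e4) {
    stop("degenerate (constant) block: mean Euclidean norm is zero")
  }
  d
}

#' Normalize one signer's posture block
#'
#' Two-step anthropometric normalization: subtract the signer's mean posture,
#' then divide by the mean Euclidean norm of the centered rows. The returned
#' parameters invert the mapping exactly:
#' `x = mean_norm * x_norm + mean_posture` (row-wise).
#'
#' @param x Numeric matrix of one signer's posture rows.
#' @param signer_id Identifier stored with the parameters.
#' @return List with `matrix` (normalized block) and `params` (list
#'   `signer_id`, `mean_posture`, `mean_norm`).
#' @export
normalize_signer <- function(x, signer_id = "s1") {
  mu <- mean_posture(x)
  xc <- center_posture(x, mu)
  d <- mean_euclidean_norm(xc)
  list(matrix = xc / d,
       params = list(signer_id = signer_id, mean_posture = mu, mean_norm = d))
}

#' Normalize a multi-signer posture matrix into a cohort
#'
#' Applies [normalize_signer()] to each signer's block of a posture matrix
#' and reassembles the rows in signer order. Each normalized block has
#' column means of zero and a mean row Euclidean norm of one, so every
#' signer contributes equally to the variance of the combined matrix.
#'
#' @param pm A `posture_matrix` from [build_posture_matrix()], or a plain
#'   matrix with a `segments` attribute.
#' @return An object of class `"norm_cohort"`: list with elements
#'   `matrix` (normalized rows, same order), `params` (named list of
#'   per-signer normalization parameters), `segments`, `frame_rate`,
#'   `markers`.
#' @export
normalize_cohort <- function(pm) {
  segs <- attr(pm, "segments")
  if (is.null(segs)) stop("input has no segments attribute; ",
                          "build it with build_posture_matrix()")
  ids <- unique(segs$signer_id)
  x <- unclass(pm)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  params <- vector("list", length(ids))
  names(params) <- ids
  for (id in ids) {
    rows <- segment_rows(pm, id)
    ns <- normalize_signer(x[rows, , drop = FALSE], signer_id = id)
    x[rows, ] <- ns$matrix
    params[[id]] <- ns$params
  }
  structure(
    list(matrix = x, params = params, segments = segs,
         frame_rate = attr(pm, "frame_rate"), markers = attr(pm, "markers")),
    class = "norm_cohort"
  )
}

#' @export
print.norm_cohort <- function(x, ...) {
  cat(sprintf(
    "<norm_cohort> %d frames x %d coords, %d signer(s) @ %g fps\n",
    nrow(x$matrix), ncol(x$matrix), length(x$params), x$frame_rate))
  invisible(x)
}

#' Invert the normalization for a set of rows
#'
#' Maps normalized posture rows back to original coordinates:
#' `mean_norm * rows + mean_posture`.
#'
#' @param rows Normalized numeric matrix (or vector).
#' @param params One signer's normalization parameters (an element of
#'   `norm_cohort$params`).
#' @return Matrix in original units.
#' @export
denormalize <- function(rows, params) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  sweep(rows * params$mean_norm, 2, params$mean_posture, "+")
}

#' Assemble independently normalized signer blocks into one cohort
#'
#' Convenience for combining blocks normalized separately (e.g. loaded from
#' different sessions); equivalent to [normalize_cohort()] on the stacked
#' raw matrix when each block holds one signer.
#'
#' @param blocks Named list of raw per-signer posture matrices (names =
#'   signer ids), identical column counts.
#' @param frame_rate Hz.
#' @param markers Optional marker labels.
#' @return A `"norm_cohort"`.
#' @export
assemble_cohort <- function(blocks, frame_rate, markers = NULL) {
  stopifnot(length(blocks) >= 1, !is.null(names(blocks)))
  p <- ncol(blocks[[1]])
  for (b in blocks) {
    if (ncol(b) != p) stop("inconsistent column counts across signer blocks")
  }
  rows <- vapply(blocks, nrow, integer(1))
  end <- cumsum(rows)
  segs <- data.frame(signer_id = names(blocks), trial_id = "all",
                     start = c(1L, utils::head(end, -1) + 1L), end = end,
                     stringsAsFactors = FALSE)
  x <- do.call(rbind, unname(blocks))
  pm <- structure(x, frame_rate = frame_rate, markers = markers,
                  segments = segs, class = c("posture_matrix", class(x)))
  normalize_cohort(pm)
}

#' Subset a cohort to selected signers
#'
#' Keeps the stored per-signer normalization (blocks are already
#' individually normalized, so dropping a signer does not change the
#' others').
#'
#' @param cohort A `"norm_cohort"`.
#' @param keep Character vector of signer ids to keep.
#' @return A `"norm_cohort"` with the reduced rows.
#' @export
subset_cohort <- function(cohort, keep) {
  segs <- cohort$segments
  stopifnot(all(keep %in% segs$signer_id))
  sel <- segs[segs$signer_id %in% keep, , drop = FALSE]
  idx <- unlist(lapply(seq_len(nrow(sel)),
                       function(i) sel$start[i]:sel$end[i]), use.names = FALSE)
  n <- vapply(seq_len(nrow(sel)), function(i) sel$end[i] - sel$start[i] + 1L,
              integer(1))
  end <- cumsum(n)
  sel$start <- c(1L, utils::head(end, -1) + 1L)
  sel$end <- end
  structure(
    list(matrix = cohort$matrix[idx, , drop = FALSE],
         params = cohort$params[keep], segments = sel,
         frame_rate = cohort$frame_rate, markers = cohort$markers),
    class = "norm_cohort"
  )
}
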