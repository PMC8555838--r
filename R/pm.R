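#' Resynthesize one principal movement as a 3D trajectory
#'
#' Projects a single component back into coordinate space:
#' \deqn{PM_i(t) = \bar{p} + \bar{d} \, w_i(t) \, PC_i}
#' using one signer's normalization parameters (mean posture \eqn{\bar{p}}
#' and mean Euclidean norm \eqn{\bar{d}}), so the trajectory is in original
#' units and renderable as a stick figure / point-light display. With
#' `normalized = TRUE` the anthropometric mapping is omitted and the bare
#' \eqn{w_i(t) \, PC_i} matrix is returned — the representation used for
#' cosine-similarity comparisons across signers.
#'
#' At any frame where the weight is zero, the resynthesized posture equals
#' the signer's mean posture exactly.
#'
#' @param fit A [pma()] fit.
#' @param i Component index.
#' @param signer_id Whose normalization parameters (and, by default, rows)
#'   to use. Defaults to the only signer when there is exactly one.
#' @param rows Row indices of the weight signal to use; default: the
#'   signer's own rows (or all rows for fits without segments).
#' @param filtered Use the low-pass-filtered weights (default) or raw.
#' @param normalized Return the dimensionless normalized PM matrix instead
#'   of original-unit coordinates.
#' @return Object of class `"principal_movement"`: list with `trajectory`
#'   (`T x p` matrix), `index`, `signer_id`, `weighting` (the weight signal
#'   used), `markers`, `frame_rate`, `normalized`.
#' @export
pm_trajectory <- function(fit, i, signer_id = NULL, rows = NULL,
                          filtered = TRUE, normalized = FALSE) {
  stopifnot(inherits(fit, "pma"))
  if (i < 1 || i > ncol(fit$rotation)) {
    stop("component index ", i, " out of range 1..", ncol(fit$rotation))
  }
  if (is.null(signer_id) && !is.null(fit$params)) {
    if (length(fit$params) == 1L) signer_id <- names(fit$params)[1]
  }
  if (is.null(rows)) {
    rows <- if (!is.null(signer_id) && !is.null(fit$segments)) {
      segment_rows(fit, signer_id)
    } else {
      seq_len(nrow(fit$weights))
    }
  }
  w_all <- if (filtered && !is.null(fit$weights_filtered)) {
    fit$weights_filtered
  } else {
    fit$weights
  }
  w <- w_all[rows, i]
  pc <- fit$rotation[, i]
  if (normalized) {
    traj <- outer(w, pc)
  } else {
    if (is.null(signer_id) || is.null(fit$params[[signer_id]])) {
      stop("original-unit resynthesis needs a signer's normalization ",
           "parameters; pass signer_id= or use normalized = TRUE")
    }
    pr <- fit$params[[signer_id]]
    traj <- outer(pr$mean_norm * w, pc)
    traj <- sweep(traj, 2, pr$mean_posture, "+")
  }
  colnames(traj) <- rownames(fit$rotation)
  structure(
    list(trajectory = traj, index = i, signer_id = signer_id,
         weighting = w, markers = fit$markers, frame_rate = fit$frame_rate,
         normalized = normalized),
    class = "principal_movement"
  )
}

#' @export
print.principal_movement <- function(x, ...) {
  cat(sprintf("<principal_movement> PM%d%s: %d frames x %d coords%s\n",
              x$index,
              if (!is.null(x$signer_id)) paste0(" (", x$signer_id, ")") else "",
              nrow(x$trajectory), ncol(x$trajectory),
              if (x$normalized) " [normalized units]" else ""))
  invisible(x)
}

#' Frames of extreme PM weighting
#'
#' Indices (over all cohort rows) of the global minimum and maximum of a
#' component's weight signal — the postures drawn gray/black in stick-figure
#' displays. Ties are broken by the earliest frame.
#'
#' @param fit A [pma()] fit.
#' @param i Component index.
#' @param filtered Use filtered weights (default) or raw.
#' @return Named integer vector `c(min = ..., max = ...)`.
#' @export
extreme_frames <- function(fit, i, filtered = TRUE) {
  w <- if (filtered && !is.null(fit$weights_filtered)) {
    fit$weights_filtered[, i]
  } else {
    fit$weights[, i]
  }
  c(min = which.min(w), max = which.max(w))
}
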