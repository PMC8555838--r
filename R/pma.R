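#' Principal movement analysis
#'
#' Fits a principal-movement decomposition to a normalized posture matrix:
#' PCA by singular value decomposition of the (already per-signer centered
#' and scaled) cohort matrix, yielding orthonormal principal components
#' ("eigenpostures"), their eigenvalues and explained-variance fractions,
#' and the weight time series \eqn{w_i(t)} (the projection of each
#' normalized posture onto each component — the activation of that synergy
#' over time). Weights are additionally low-pass filtered with a zero-phase
#' Butterworth filter (default 4th order, 6 Hz), applied per recording
#' segment, to suppress measurement noise.
#'
#' No re-centering is performed: each signer's block is centered during
#' normalization, and subtracting a second cross-signer mean would alter
#' the per-signer structure. An assertion rejects inputs whose column means
#' are not negligible. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making results reproducible
#' across runs and platforms (a sign flip of a component together with its
#' weights leaves every derived quantity unchanged).
#'
#' @param x A `"norm_cohort"` from [normalize_cohort()], or a numeric matrix
#'   with (near-)zero column means.
#' @param n_pms Number of components to retain for reporting/reconstruction.
#'   Default `NULL`: the smallest K whose cumulative explained-variance
#'   fraction reaches `ev_target`. All components are always computed and
#'   stored.
#' @param ev_target Cumulative explained-variance target used when `n_pms`
#'   is `NULL` (default 0.946).
#' @param cutoff,order Weight filter parameters (Hz / filter order); see
#'   [lowpass_weights()]. Set `cutoff = NULL` to skip filtering.
#' @param frame_rate Required when `x` is a plain matrix and filtering is
#'   requested.
#' @param keep_data Store the input matrix in the fit (needed by
#'   [residuals.pma()] and [cross_projection()]).
#' @return An object of class `"pma"`: list with elements
#'   \describe{
#'     \item{rotation}{`p x K` orthonormal matrix, columns = components.}
#'     \item{eigenvalues}{Nonincreasing variances (`d^2 / n`).}
#'     \item{ev_fraction}{Eigenvalues normalized to sum to one.}
#'     \item{weights, weights_filtered}{`n x K` weight time series.}
#'     \item{n_pms}{Retained component count.}
#'     \item{params, segments, frame_rate, markers}{Carried from the cohort.}
#'   }
#' @seealso [summary.pma()], [predict.pma()], [pm_trajectory()],
#'   [loo_robustness()], [cross_projection()]
#' @examples
#' cfg <- cohort_config(n_signers = 2, n_trials = 2, trial_s = 1, fps = 50,
#'                      n_markers = 8, K = 3, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' fit <- pma(cohort$cohort)
#' fit
#' head(summary(fit)$table)
#' @export
pma <- function(x, n_pms = NULL, ev_target = 0.946, cutoff = 6, order = 4,
                frame_rate = NULL, keep_data = TRUE) {
  cohort <- NULL
  if (inherits(x, "norm_cohort")) {
    cohort <- x
    mat <- x$matrix
    frame_rate <- x$frame_rate
  } else {
    mat <- as.matrix(x)
  }
  n <- nrow(mat)
  p <- ncol(mat)
  if (n < p) {
    stop("matrix has fewer rows (", n, ") than columns (", p,
         "); more frames are needed for a well-posed decomposition")
  }
  scale_ref <- sqrt(mean(mat^2))
  if (scale_ref == 0) stop("input matrix is identically zero")
  cm <- colMeans(mat)
  if (max(abs(cm)) > 1e-6 * scale_ref) {
    stop("column means are not negligible (max |mean| = ",
         format(max(abs(cm))), "); center each signer's block first ",
         "(see normalize_cohort())")
  }

  sv <- svd(mat)
  v <- sv$v
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(ncol(v)), function(j) {
    v[which.max(abs(v[, j])), j] < 0
  }, logical(1))
  v[, flip] <- -v[, flip]
  weights <- sweep(sv$u, 2, sv$d, "*")
  weights[, flip] <- -weights[, flip]

  eigenvalues <- sv$d^2 / n
  ev_fraction <- eigenvalues / sum(eigenvalues)
  k_auto <- which(cumsum(ev_fraction) >= ev_target - 1e-12)[1]
  if (is.na(k_auto)) k_auto <- length(ev_fraction)
  if (is.null(n_pms)) n_pms <- k_auto
  if (n_pms > ncol(v)) stop("n_pms exceeds the number of components (",
                            ncol(v), ")")
  cn <- paste0("PC", seq_len(ncol(v)))
  dimnames(v) <- list(colnames(mat), cn)
  colnames(weights) <- cn

  segments <- if (!is.null(cohort)) cohort$segments else NULL
  wf <- NULL
  if (!is.null(cutoff)) {
    if (is.null(frame_rate)) {
      stop("frame_rate is required to filter weights; pass frame_rate= or ",
           "cutoff = NULL")
    }
    wf <- filter_by_segment(weights, frame_rate, cutoff, order, segments)
  }

  structure(
    list(rotation = v, eigenvalues = eigenvalues, ev_fraction = ev_fraction,
         weights = weights, weights_filtered = wf,
         n_pms = n_pms, ev_target = ev_target,
         cutoff = cutoff, order = order,
         frame_rate = frame_rate, segments = segments,
         params = if (!is.null(cohort)) cohort$params else NULL,
         markers = if (!is.null(cohort)) cohort$markers else NULL,
         data = if (keep_data) mat else NULL,
         call = match.call()),
    class = "pma"
  )
}

# filter weight columns, independently within each recording segment
# (recording units are unsynchronized utterances: no continuity across them)
filter_by_segment <- function(w, frame_rate, cutoff, order, segments) {
  if (is.null(segments)) return(lowpass_weights(w, frame_rate, cutoff, order))
  out <- w
  for (i in seq_len(nrow(segments))) {
    rows <- segments$start[i]:segments$end[i]
    out[rows, ] <- lowpass_weights(w[rows, , drop = FALSE],
                                   frame_rate, cutoff, order)
  }
  out
}

#' @export
print.pma <- function(x, ...) {
  k <- x$n_pms
  cat(sprintf("<pma> %d components over %d frames x %d coordinates\n",
              ncol(x$rotation), nrow(x$weights), nrow(x$rotation)))
  cat(sprintf("  retained n_pms = %d (cumulative EV %.1f%%, target %.1f%%)\n",
              k, 100 * sum(x$ev_fraction[seq_len(k)]), 100 * x$ev_target))
  if (!is.null(x$params)) {
    cat("  signers: ", paste(names(x$params), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Summarize a principal-movement decomposition
#'
#' Tabulates per-component explained variance (raw weights) alongside the
#' explained variance recomputed from the filtered weights, and cumulative
#' percentages.
#'
#' @param object A [pma()] fit.
#' @param n_show Number of components to tabulate (default: all).
#' @param ... Unused.
#' @return A `"summary.pma"` object; its `table` element is a data.frame
#'   with columns `pm`, `ev_pct`, `cum_ev_pct` and, when filtered weights
#'   exist, `ev_pct_filtered`.
#' @export
summary.pma <- function(object, n_show = length(object$ev_fraction), ...) {
  k <- min(n_show, length(object$ev_fraction))
  tab <- data.frame(
    pm = seq_len(k),
    ev_pct = 100 * object$ev_fraction[seq_len(k)],
    cum_ev_pct = 100 * cumsum(object$ev_fraction)[seq_len(k)]
  )
  if (!is.null(object$weights_filtered)) {
    vf <- apply(object$weights_filtered, 2, stats::var)
    tab$ev_pct_filtered <- 100 * (vf / sum(vf))[seq_len(k)]
  }
  structure(list(table = tab, n_pms = object$n_pms,
                 ev_target = object$ev_target,
                 n_signers = length(object$params),
                 n_frames = nrow(object$weights)),
            class = "summary.pma")
}

#' @export
print.summary.pma <- function(x, ...) {
  cat(sprintf("Principal movement analysis: %d frames", x$n_frames))
  if (!is.null(x$n_signers) && x$n_signers > 0) {
    cat(sprintf(", %d signer(s)", x$n_signers))
  }
  cat(sprintf("\nRetained %d PMs (cumulative EV target %.1f%%)\n\n",
              x$n_pms, 100 * x$ev_target))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pma <- function(object, ...) object$rotation

#' Project posture data onto fitted components
#'
#' Computes weight time series \eqn{w_i(t)} for new normalized posture rows:
#' the inner product of each row with each component.
#'
#' @param object A [pma()] fit.
#' @param newdata A `"norm_cohort"` or numeric matrix with `p` columns.
#'   Default: the training data (returns the stored weights).
#' @param filter Low-pass filter the projected weights with the fit's
#'   filter settings.
#' @param ... Unused.
#' @return `n x K` weight matrix.
#' @export
predict.pma <- function(object, newdata = NULL, filter = FALSE, ...) {
  if (is.null(newdata)) {
    return(if (filter && !is.null(object$weights_filtered))
      object$weights_filtered else object$weights)
  }
  segments <- NULL
  if (inherits(newdata, "norm_cohort")) {
    segments <- newdata$segments
    newdata <- newdata$matrix
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$rotation)) {
    stop("newdata has ", ncol(newdata), " columns; fit expects ",
         nrow(object$rotation))
  }
  w <- newdata %*% object$rotation
  if (filter) {
    w <- filter_by_segment(w, object$frame_rate, object$cutoff,
                           object$order, segments)
  }
  w
}

#' @export
fitted.pma <- function(object, n_pms = object$n_pms, ...) {
  idx <- seq_len(n_pms)
  object$weights[, idx, drop = FALSE] %*%
    t(object$rotation[, idx, drop = FALSE])
}

#' @export
residuals.pma <- function(object, n_pms = object$n_pms, ...) {
  if (is.null(object$data)) {
    stop("fit was created with keep_data = FALSE; residuals unavailable")
  }
  object$data - fitted(object, n_pms = n_pms)
}

#' Explained-variance plot for a decomposition
#'
#' Bar plot of per-PM explained variance with the cumulative curve overlaid.
#'
#' @param x A [pma()] fit.
#' @param n_show Components to display.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.pma <- function(x, n_show = 15, ...) {
  k <- min(n_show, length(x$ev_fraction))
  ev <- 100 * x$ev_fraction[seq_len(k)]
  mids <- graphics::barplot(ev, names.arg = seq_len(k),
                            xlab = "Principal movement",
                            ylab = "Explained variance (%)",
                            ylim = c(0, 105), ...)
  graphics::lines(mids, 100 * cumsum(x$ev_fraction)[seq_len(k)],
                  type = "b", pch = 19)
  graphics::abline(h = 100 * x$ev_target, lty = 2)
  invisible(x)
}

#' @export
screeplot.pma <- function(x, ...) plot.pma(x, ...)
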