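#' Cosine similarity between two principal movements
#'
#' Reshapes each PM's `T x p` matrix into a vector and computes the
#' normalized inner product
#' \deqn{sim = \frac{\sum_k a_k b_k}{\sqrt{\sum_k a_k^2}\sqrt{\sum_k b_k^2}}.}
#' Comparisons are made on *normalized* PM matrices (weights times
#' component, without the mean posture or scale), so that postural movements
#' are compared beyond anthropometric differences. Because component signs
#' are arbitrary, the default `"abs"` mode reports `|sim|` in `[0, 1]`;
#' `"signed"` returns the raw value in `[-1, 1]`.
#'
#' For two rank-one PM matrices \eqn{a = w_a PC_a^T}, \eqn{b = w_b PC_b^T}
#' the value factorizes exactly as
#' \eqn{(w_a \cdot w_b)(PC_a \cdot PC_b) / (\|w_a\| \|w_b\|)}.
#'
#' @param a,b Numeric matrices of identical shape (or
#'   `"principal_movement"` objects, which must be normalized).
#' @param mode `"abs"` (default) or `"signed"`.
#' @return Scalar similarity.
#' @export
pm_cosine <- function(a, b, mode = c("abs", "signed")) {
  mode <- match.arg(mode)
  if (inherits(a, "principal_movement")) a <- a$trajectory
  if (inherits(b, "principal_movement")) b <- b$trajectory
  if (!identical(dim(a), dim(b))) {
    stop("PM matrices differ in shape: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  }
  av <- as.numeric(a)
  bv <- as.numeric(b)
  na <- sqrt(sum(av^2))
  nb <- sqrt(sum(bv^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity is undefined for an all-zero PM")
  }
  s <- sum(av * bv) / (na * nb)
  if (mode == "abs") abs(s) else s
}

#' Similarity matrix between individual and common PMs
#'
#' Compares one signer's individual decomposition with a common (cohort)
#' decomposition, PM by PM. Both sets of PMs are built from the *same*
#' movement data — the signer's own normalized posture rows projected on
#' each basis — so entry `(i, j)` is the cosine similarity between the
#' signer's i-th individual PM and the j-th common PM. Weights are low-pass
#' filtered with the fits' filter before comparison.
#'
#' Diagnostics report, per individual PM, the best-matching common PM (PMs
#' may be similar but ranked in a different order across decompositions),
#' and flag rows with no single high match but at least two moderate
#' entries as likely *combinations* of common PMs.
#'
#' @param fit_ind The signer's individual [pma()] fit.
#' @param fit_com The common [pma()] fit.
#' @param data The signer's normalized posture rows (matrix). Default: the
#'   data stored in `fit_ind`.
#' @param n_pms Number of PMs to compare from each basis.
#' @param mode `"abs"` (default) or `"signed"` cosine.
#' @param filter Filter projected weights before comparison (default TRUE).
#' @param high,moderate Similarity thresholds (defaults 0.7 and 0.5).
#' @param combo Threshold for the combination diagnostic (default 0.4):
#'   rows with no entry `> high` but two or more entries `> combo` are
#'   flagged.
#' @return Object of class `"pm_similarity"`: list with `sim` (K x K
#'   matrix), `best_match` (data.frame: individual PM, best common PM,
#'   similarity, whether ranks permute), `high_mask`, `moderate_mask`,
#'   `combination` (logical per row), thresholds.
#' @export
similarity_matrix <- function(fit_ind, fit_com, data = fit_ind$data,
                              n_pms = fit_com$n_pms,
                              mode = c("abs", "signed"),
                              filter = TRUE,
                              high = 0.7, moderate = 0.5, combo = 0.4) {
  mode <- match.arg(mode)
  if (is.null(data)) {
    stop("no data available: pass data= or fit with keep_data = TRUE")
  }
  if (nrow(fit_ind$rotation) != nrow(fit_com$rotation)) {
    stop("decompositions live in different coordinate spaces (",
         nrow(fit_ind$rotation), " vs ", nrow(fit_com$rotation), " dims)")
  }
  if (n_pms > ncol(fit_ind$rotation) || n_pms > ncol(fit_com$rotation)) {
    stop("n_pms exceeds the available components")
  }
  data <- as.matrix(data)
  wi <- data %*% fit_ind$rotation[, seq_len(n_pms), drop = FALSE]
  wc <- data %*% fit_com$rotation[, seq_len(n_pms), drop = FALSE]
  if (filter && !is.null(fit_com$cutoff)) {
    fr <- fit_ind$frame_rate %||% fit_com$frame_rate
    wi <- lowpass_weights(wi, fr, fit_com$cutoff, fit_com$order)
    wc <- lowpass_weights(wc, fr, fit_com$cutoff, fit_com$order)
  }
  # rank-one factorization: <w_i pc_i', w_j qc_j'>_F = (w_i.w_j)(pc_i.qc_j)
  wnorm_i <- sqrt(colSums(wi^2))
  wnorm_c <- sqrt(colSums(wc^2))
  if (any(wnorm_i == 0) || any(wnorm_c == 0)) {
    stop("cosine similarity is undefined for an all-zero PM")
  }
  gram_w <- crossprod(wi, wc) / (wnorm_i %o% wnorm_c)
  gram_pc <- crossprod(fit_ind$rotation[, seq_len(n_pms), drop = FALSE],
                       fit_com$rotation[, seq_len(n_pms), drop = FALSE])
  sim <- gram_w * gram_pc
  if (mode == "abs") sim <- abs(sim)
  dimnames(sim) <- list(paste0("ind_PM", seq_len(n_pms)),
                        paste0("com_PM", seq_len(n_pms)))
  best <- apply(sim, 1, which.max)
  best_match <- data.frame(
    individual_pm = seq_len(n_pms),
    common_pm = as.integer(best),
    sim = sim[cbind(seq_len(n_pms), best)],
    permuted = as.integer(best) != seq_len(n_pms)
  )
  combination <- apply(sim, 1, function(r) {
    max(r) <= high && sum(r > combo) >= 2
  })
  structure(
    list(sim = sim, best_match = best_match,
         high_mask = sim > high, moderate_mask = sim > moderate,
         combination = combination,
         thresholds = c(high = high, moderate = moderate, combo = combo),
         mode = mode, n_pms = n_pms),
    class = "pm_similarity"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pm_similarity <- function(x, ...) {
  cat(sprintf("<pm_similarity> %d x %d (%s cosine)\n", nrow(x$sim),
              ncol(x$sim), x$mode))
  print(round(x$sim, 3))
  if (any(x$best_match$permuted)) {
    p <- x$best_match[x$best_match$permuted, ]
    cat("rank permutations: ",
        paste(sprintf("%d->%d", p$individual_pm, p$common_pm),
              collapse = ", "), "\n", sep = "")
  }
  if (any(x$combination)) {
    cat("combination-of-common-PMs flags: ",
        paste(which(x$combination), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Leave-one-out orientation robustness of the components
#'
#' Quantifies how much each principal component's orientation in posture
#' space depends on any single signer: for each signer, the decomposition
#' is refit on the cohort with that signer's rows removed, and the angle
#' `acos(|PC_i_full . PC_i_reduced|)` (degrees, unsigned axes, same-rank
#' matching) is computed for each component. Components whose angle stays
#' within `threshold` (default 15 degrees) for every left-out signer are
#' deemed robust to signer changes. A best-match angle (minimum over
#' reduced components) is also reported for diagnosing rank swaps.
#'
#' @param cohort A `"norm_cohort"` with at least two signers.
#' @param n_pms Number of leading components to assess.
#' @param threshold Robustness threshold in degrees (default 15).
#' @param fit_full Optional precomputed full-cohort [pma()] fit.
#' @return Object of class `"loo_robustness"`: list with `angles`
#'   (signers x components matrix, degrees), `best_match_angles`,
#'   `robust` (logical matrix `angles <= threshold`), `threshold`.
#' @export
loo_robustness <- function(cohort, n_pms = NULL, threshold = 15,
                           fit_full = NULL) {
  stopifnot(inherits(cohort, "norm_cohort"))
  ids <- names(cohort$params)
  if (length(ids) < 2) stop("leave-one-out needs at least two signers")
  if (is.null(fit_full)) {
    fit_full <- pma(cohort, cutoff = NULL, keep_data = FALSE)
  }
  if (is.null(n_pms)) n_pms <- fit_full$n_pms
  if (n_pms > ncol(fit_full$rotation)) {
    stop("n_pms exceeds the available components (",
         ncol(fit_full$rotation), ")")
  }
  vfull <- fit_full$rotation[, seq_len(n_pms), drop = FALSE]
  angles <- matrix(NA_real_, length(ids), n_pms,
                   dimnames = list(ids, paste0("PM", seq_len(n_pms))))
  best <- angles
  for (id in ids) {
    red <- subset_cohort(cohort, setdiff(ids, id))
    fit_red <- pma(red, cutoff = NULL, keep_data = FALSE)
    vred <- fit_red$rotation[, seq_len(n_pms), drop = FALSE]
    cosmat <- abs(crossprod(vfull, vred))        # n_pms x n_pms
    cosmat <- pmin(pmax(cosmat, -1), 1)
    angles[id, ] <- acos(diag(cosmat)) * 180 / pi
    best[id, ] <- acos(apply(cosmat, 1, max)) * 180 / pi
  }
  structure(
    list(angles = angles, best_match_angles = best,
         robust = angles <= threshold, threshold = threshold,
         n_pms = n_pms),
    class = "loo_robustness"
  )
}

#' @export
print.loo_robustness <- function(x, ...) {
  cat(sprintf(
    "<loo_robustness> %d signer(s) x %d PMs (threshold %g deg)\n",
    nrow(x$angles), ncol(x$angles), x$threshold))
  print(round(x$angles, 1))
  nonrob <- which(!x$robust, arr.ind = TRUE)
  if (nrow(nonrob)) {
    cat("non-robust: ",
        paste(sprintf("%s/%s (%.1f deg)", rownames(x$angles)[nonrob[, 1]],
                      colnames(x$angles)[nonrob[, 2]],
                      x$angles[nonrob]), collapse = "; "), "\n", sep = "")
  } else {
    cat("all components robust\n")
  }
  invisible(x)
}

#' Cross-projection similarity between two signers' PM subspaces
#'
#' Measures how much of one signer's movement variance the other signer's
#' leading components capture. The movements of signer A are projected on
#' A's own first `n` components, and the cumulative variance of the
#' projection coefficients is `V1`; projecting the same movements on B's
#' first `n` components gives `V2`. Since a PCA basis maximizes captured
#' variance, `V2 <= V1` and the ratio `V2 / V1` lies in `[0, 1]`, reaching
#' 1 when the subspaces coincide. Because the measure is directional, the
#' symmetric similarity is the mean of the two directed ratios.
#'
#' @param fit_a,fit_b [pma()] fits for the two signers, fitted with
#'   `keep_data = TRUE` (or pass `data_a` / `data_b`).
#' @param n Number of leading components (default: `fit_a$n_pms`).
#' @param data_a,data_b Normalized posture rows for each signer; defaults
#'   to the matrices stored in the fits.
#' @return Object of class `"cross_projection"`: list with
#'   `n`, `v1_a`, `v2_a` (A's movements on A's / B's basis), `ratio_a`
#'   (`v2_a / v1_a`), `v1_b`, `v2_b`, `ratio_b`, and `similarity` (mean of
#'   the two directed ratios).
#' @export
cross_projection <- function(fit_a, fit_b, n = fit_a$n_pms,
                             data_a = fit_a$data, data_b = fit_b$data) {
  if (is.null(data_a) || is.null(data_b)) {
    stop("cross-projection needs both signers' data; fit with ",
         "keep_data = TRUE or pass data_a=/data_b=")
  }
  if (n > ncol(fit_a$rotation) || n > ncol(fit_b$rotation)) {
    stop("n exceeds the rank of a decomposition")
  }
  dir_ratio <- function(x, own, other) {
    v1 <- sum(apply(x %*% own[, seq_len(n), drop = FALSE], 2, stats::var))
    v2 <- sum(apply(x %*% other[, seq_len(n), drop = FALSE], 2, stats::var))
    if (v1 <= 0) stop("zero variance on the signer's own basis")
    c(v1 = v1, v2 = v2)
  }
  a <- dir_ratio(as.matrix(data_a), fit_a$rotation, fit_b$rotation)
  b <- dir_ratio(as.matrix(data_b), fit_b$rotation, fit_a$rotation)
  structure(
    list(n = n,
         v1_a = a[["v1"]], v2_a = a[["v2"]], ratio_a = a[["v2"]] / a[["v1"]],
         v1_b = b[["v1"]], v2_b = b[["v2"]], ratio_b = b[["v2"]] / b[["v1"]],
         similarity = mean(c(a[["v2"]] / a[["v1"]], b[["v2"]] / b[["v1"]]))),
    class = "cross_projection"
  )
}

#' @export
print.cross_projection <- function(x, ...) {
  cat(sprintf(
    "<cross_projection> n = %d: ratios %.4f / %.4f, symmetric similarity %.4f\n",
    x$n, x$ratio_a, x$ratio_b, x$similarity))
  invisible(x)
}

#' Principal angles between two subspaces
#'
#' Angles (degrees, nondecreasing) between the column spans of two bases:
#' the arc-cosines of the singular values of `Qa' Qb` after
#' orthonormalization. Zero angles mean coincident subspaces; used to score
#' how well a fitted leading subspace recovers a planted synergy basis.
#'
#' @param a,b Matrices whose columns span the subspaces (`p x k`).
#' @return Numeric vector of `min(ka, kb)` angles in degrees.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  sort(acos(pmin(pmax(s, -1), 1)) * 180 / pi)
}
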