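# Zero-phase Butterworth filtering and spectral estimation of PM weights.
#
# Coefficients come from signal::butter; the forward-backward pass is done
# here with odd-reflection padding and steady-state initial conditions so
# that a constant input passes through at machine precision and edge
# transients are suppressed (signal::filtfilt starts from zero state and
# corrupts edges badly).

# one forward IIR pass with steady-state initialization at level z[1]
iir_pass <- function(b, a, z) {
  nf <- max(length(a), length(b))
  h1 <- sum(b) / sum(a)
  signal::filter(b, a, z,
                 init.x = rep(z[1], nf - 1),
                 init.y = rep(z[1] * h1, nf - 1))
}

# forward-backward filter of one numeric vector
filtfilt_ss <- function(b, a, x) {
  nf <- max(length(a), length(b))
  p <- 3L * (nf - 1L)
  n <- length(x)
  if (n <= p) {
    stop("signal too short to filter (", n, " samples, need > ", p, ")")
  }
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- iir_pass(b, a, ext)
  y <- rev(iir_pass(b, a, rev(y)))
  as.numeric(y[(p + 1):(p + n)])
}

#' Low-pass filter weight time series
#'
#' Zero-phase (forward-backward) Butterworth low-pass filter, applied
#' independently to each column. The default 4th-order, 6 Hz filter is the
#' standard choice for removing measurement noise from PM weight signals
#' while preserving the sub-3 Hz band where volitional movement power
#' concentrates. The forward-backward pass doubles the attenuation (the
#' effective magnitude response is |H(f)|^2) and introduces no phase lag.
#'
#' @param w Numeric vector or matrix (columns = PM weight signals).
#' @param frame_rate Sampling rate, Hz.
#' @param cutoff Cut-off frequency, Hz; must be below the Nyquist rate.
#' @param order Butterworth order (per pass).
#' @return Filtered object of the same shape.
#' @export
lowpass_weights <- function(w, frame_rate, cutoff = 6, order = 4) {
  if (cutoff >= frame_rate / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         frame_rate / 2, " Hz)")
  }
  bf <- signal::butter(order, cutoff / (frame_rate / 2), type = "low")
  if (is.null(dim(w))) return(filtfilt_ss(bf$b, bf$a, w))
  out <- apply(w, 2, function(col) filtfilt_ss(bf$b, bf$a, col))
  dimnames(out) <- dimnames(w)
  out
}

#' Exact magnitude response of the zero-phase Butterworth filter
#'
#' Closed-form magnitude of the digital (bilinear-transformed, prewarped)
#' Butterworth low-pass used by [lowpass_weights()]:
#' `|H(f)|^2 = 1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^(2 * order))`,
#' and the zero-phase forward-backward pass applies `|H(f)|^2` to
#' amplitudes. Useful as an independent oracle for the filter's attenuation.
#'
#' @param f Frequencies at which to evaluate, Hz.
#' @param frame_rate Sampling rate, Hz.
#' @param cutoff Cut-off frequency, Hz.
#' @param order Filter order (per pass).
#' @param zero_phase If `TRUE` (default) return the forward-backward
#'   amplitude gain `|H|^2`; otherwise the single-pass `|H|`.
#' @return Numeric vector of amplitude gains in `[0, 1]`.
#' @export
butterworth_gain <- function(f, frame_rate, cutoff = 6, order = 4,
                             zero_phase = TRUE) {
  ratio <- tan(pi * f / frame_rate) / tan(pi * cutoff / frame_rate)
  h2 <- 1 / (1 + ratio^(2 * order))
  if (zero_phase) h2 else sqrt(h2)
}

#' Welch power spectral density of weight signals
#'
#' Averaged-periodogram PSD estimate: the signal is split into
#' `segment_s`-second windows with fractional `overlap`, each window is
#' mean-detrended, tapered, and its one-sided periodogram accumulated.
#' Density scaling is used, so the integral of the PSD over frequency
#' approximates the signal variance.
#'
#' @param w Numeric vector or matrix (columns = signals).
#' @param frame_rate Sampling rate, Hz.
#' @param segment_s Segment length in seconds (default 4 s).
#' @param overlap Fractional overlap between segments in `[0, 1)`.
#' @param window `"hann"` or `"rect"`.
#' @param detrend Subtract each segment's mean before tapering.
#' @return Object of class `"weight_spectrum"`: list with `freq` (Hz, from 0
#'   to Nyquist), `psd` (matrix, bins x signals), and the estimation
#'   parameters.
#' @export
welch_psd <- function(w, frame_rate, segment_s = 4, overlap = 0.5,
                      window = c("hann", "rect"), detrend = TRUE) {
  window <- match.arg(window)
  if (is.null(dim(w))) w <- matrix(w, ncol = 1)
  n <- nrow(w)
  nseg <- round(segment_s * frame_rate)
  if (nseg > n) {
    stop("segment length (", nseg, " samples) exceeds signal length (", n, ")")
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / nseg)
  } else {
    rep(1, nseg)
  }
  u <- sum(win^2)                      # window power normalization
  nfreq <- nseg %/% 2 + 1L
  freq <- (seq_len(nfreq) - 1L) * frame_rate / nseg
  psd <- matrix(0, nfreq, ncol(w))
  for (s in starts) {
    seg <- w[s:(s + nseg - 1L), , drop = FALSE]
    if (detrend) seg <- sweep(seg, 2, colMeans(seg), "-")
    ft <- stats::mvfft(seg * win)
    pxx <- Mod(ft[seq_len(nfreq), , drop = FALSE])^2 / (frame_rate * u)
    # one-sided: double everything except DC (and Nyquist when nseg even)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nfreq] <- 1
    psd <- psd + pxx * dbl
  }
  psd <- psd / length(starts)
  colnames(psd) <- colnames(w)
  structure(
    list(freq = freq, psd = psd, frame_rate = frame_rate,
         segment_s = segment_s, overlap = overlap, window = window,
         n_segments = length(starts)),
    class = "weight_spectrum"
  )
}

#' @export
print.weight_spectrum <- function(x, ...) {
  cat(sprintf(
    "<weight_spectrum> %d signal(s), %d bins 0-%g Hz (df = %.4g Hz), %d x %gs %s segments, %.0f%% overlap\n",
    ncol(x$psd), length(x$freq), max(x$freq), x$freq[2] - x$freq[1],
    x$n_segments, x$segment_s, x$window, 100 * x$overlap))
  invisible(x)
}

#' @export
plot.weight_spectrum <- function(x, log = "y", xlim = NULL, ...) {
  graphics::matplot(x$freq, pmax(x$psd, .Machine$double.xmin), type = "l",
                    lty = 1, log = sub("x", "", log),
                    xlab = "Frequency (Hz)", ylab = "PSD (power/Hz)",
                    xlim = xlim, ...)
  invisible(x)
}
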