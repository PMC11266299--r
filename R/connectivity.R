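#' Analytic signal via the Hilbert transform
#'
#' Returns the complex analytic signal whose real part is the input and
#' whose imaginary part is its Hilbert transform, computed with the
#' one-sided-spectrum FFT method.
#'
#' @param x real numeric vector, length >= 4.
#' @return Complex vector of the same length.
#' @examples
#' t <- (0:999) / 200
#' z <- analytic_signal(cos(2 * pi * 10 * t))
#' # interior imaginary part approximates sin(2 pi 10 t)
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Cross-spectral samples of two analytic signals
#'
#' Element-wise `x * Conj(y)`; the imaginary parts of these samples carry the
#' lag information WPLI is built from.
#'
#' @param xa,ya complex vectors of equal length (analytic signals).
#' @return Complex vector of cross-spectral samples.
#' @export
cross_spectrum <- function(xa, ya) {
  if (length(xa) != length(ya)) {
    stop("cross_spectrum: inputs differ in length", call. = FALSE)
  }
  xa * Conj(ya)
}

#' Weighted phase lag index of cross-spectral samples
#'
#' `WPLI = |sum(Im C)| / sum(|Im C|)` over the cross-spectral samples `C`.
#' The estimator lies in `[0, 1]`: 1 when every sample shows the same lag
#' direction (complete phase locking), 0 when positive and negative lags
#' cancel.  Magnitude weighting makes it robust to small, noise-dominated
#' phase differences, and zero-lag (volume-conduction) coupling contributes
#' nothing because its cross-spectrum is real.
#'
#' @param cs complex vector of cross-spectral samples, e.g. from
#'   [cross_spectrum()].
#' @return WPLI value in `[0, 1]`.  The degenerate case where all imaginary
#'   parts vanish returns 0 by convention.
#' @examples
#' wpli(complex(imaginary = c(1, 2, 3)))   # 1: consistent lag direction
#' wpli(complex(imaginary = c(1, -1)))     # 0: lags cancel
#' @export
wpli <- function(cs) {
  if (length(cs) == 0) stop("empty cross-spectrum", call. = FALSE)
  im <- Im(cs)
  denom <- sum(abs(im))
  if (denom == 0) return(0)
  abs(sum(im)) / denom
}

#' WPLI connectivity matrix of one epoch
#'
#' Computes the analytic signal of every channel, then the WPLI of every
#' channel pair from their per-sample cross-spectra.  If `band` (and `fs`)
#' are supplied the epoch is band-pass filtered first; in the standard
#' pipeline the data arrive already band-limited from [band_decompose()].
#' The first and last 5% of analytic-signal samples are discarded to avoid
#' Hilbert edge effects.
#'
#' @param epoch channels-by-samples numeric matrix, >= 2 channels.
#' @param fs sampling rate in Hz; only needed when `band` is given.
#' @param band optional [band_spec()] to filter with before the transform.
#' @param edge_trim fraction of samples dropped at each end (default 0.05).
#' @return Symmetric matrix in `[0, 1]` with zero diagonal, with attribute
#'   `band` when one was supplied.
#' @export
wpli_matrix <- function(epoch, fs = NULL, band = NULL, edge_trim = 0.05) {
  epoch <- as.matrix(epoch)
  n_ch <- nrow(epoch)
  if (n_ch < 2) stop("need at least 2 channels", call. = FALSE)
  if (!is.null(band)) {
    if (is.null(fs)) stop("band filtering requires fs", call. = FALSE)
    epoch <- bandpass_rows(epoch, band$low, band$high, fs)
  }
  n <- ncol(epoch)
  keep <- seq.int(floor(n * edge_trim) + 1, n - floor(n * edge_trim))
  analytic <- t(apply(epoch, 1, analytic_signal))[, keep, drop = FALSE]
  M <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_ch - 1)) {
    for (j in (i + 1):n_ch) {
      M[i, j] <- M[j, i] <- wpli(cross_spectrum(analytic[i, ], analytic[j, ]))
    }
  }
  dimnames(M) <- list(rownames(epoch), rownames(epoch))
  attr(M, "band") <- if (is.null(band)) NULL else band$name
  M
}
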