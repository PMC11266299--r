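#' Frequency band specification
#'
#' @param name band label.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(name, low, high) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high", call. = FALSE)
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' Canonical EEG analysis bands
#'
#' Delta 1-3 Hz, theta 3-7 Hz, alpha 7-13 Hz, beta 13-30 Hz and
#' gamma 30-60 Hz.
#'
#' @return Named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  list(delta = band_spec("delta", 1, 3),
       theta = band_spec("theta", 3, 7),
       alpha = band_spec("alpha", 7, 13),
       beta  = band_spec("beta", 13, 30),
       gamma = band_spec("gamma", 30, 60))
}

# forward-backward (zero-phase) Butterworth applied row-wise
filtfilt_rows <- function(dat, filt) {
  t(apply(dat, 1, function(x) signal::filtfilt(filt, x)))
}

# Zero-phase band restriction as a high-pass/low-pass Butterworth cascade.
# The cascade is used instead of a single band-pass design because very
# asymmetric edges (e.g. 0.5 and 80 Hz at fs 200) make one joint band-pass
# numerically fragile under forward-backward filtering.
bandpass_rows <- function(dat, low, high, fs, order = 4) {
  nyq <- fs / 2
  if (high >= nyq) stop("band edge at or above Nyquist", call. = FALSE)
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  filtfilt_rows(filtfilt_rows(dat, hp), lp)
}

# second-order IIR notch (standard biquad design), zero-phase
notch_rows <- function(dat, freq, fs, q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  filt <- signal::Arma(b = b / a[1], a = a / a[1])
  filtfilt_rows(dat, filt)
}

# rational approximation p/q of a resampling ratio
resample_ratio <- function(target_fs, fs, max_den = 1000) {
  r <- target_fs / fs
  best <- c(1L, 1L)
  best_err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    err <- abs(r - p / q)
    if (err < best_err - 1e-15) {
      best <- c(p, q)
      best_err <- err
    }
    if (best_err < 1e-12) break
  }
  g <- gcd_int(best[1], best[2])
  best / g
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Preprocess a recording
#'
#' Fixed-order pipeline: drop bad channels, resample to `target_fs`
#' (polyphase, anti-aliased), zero-phase 60 Hz notch, zero-phase Butterworth
#' band restriction, and common-average re-referencing computed over the
#' remaining (good) channels as the final step, so the across-channel mean
#' of the output is zero at every sample.
#'
#' @param rec a [recording()].
#' @param target_fs output sampling rate in Hz (default 200).
#' @param notch line-noise frequency to suppress in Hz; `NULL` disables.
#' @param band length-2 numeric, band-pass edges in Hz (default 0.5-80).
#' @param notch_q quality factor of the notch (default 30, i.e. about 2 Hz
#'   wide at 60 Hz).
#' @return A preprocessed `soz_recording` containing only good channels.
#' @export
preprocess_recording <- function(rec, target_fs = 200, notch = 60,
                                 band = c(0.5, 80), notch_q = 30) {
  validate_recording(rec)
  if (target_fs > rec$fs) {
    stop("target_fs exceeds the recording sampling rate", call. = FALSE)
  }
  keep <- !rec$bad_mask
  if (!any(keep)) stop("all channels are flagged bad", call. = FALSE)
  dat <- rec$data[keep, , drop = FALSE]
  fs <- rec$fs
  if (target_fs < fs) {
    pq <- resample_ratio(target_fs, fs)
    dat <- t(apply(dat, 1, function(x) signal::resample(x, pq[1], pq[2])))
    fs <- fs * pq[1] / pq[2]
  }
  if (!is.null(notch) && notch < fs / 2) {
    dat <- notch_rows(dat, notch, fs, q = notch_q)
  }
  if (!is.null(band)) {
    dat <- bandpass_rows(dat, band[1], band[2], fs)
  }
  # common average reference, applied last
  dat <- sweep(dat, 2, colMeans(dat))
  recording(dat, fs = fs,
            channel_names = rec$channel_names[keep],
            soz_mask = rec$soz_mask[keep])
}

#' Decompose a recording into frequency bands
#'
#' Applies the zero-phase Butterworth band restriction of
#' [preprocess_recording()] once per band.
#'
#' @param rec a [recording()].
#' @param bands list of [band_spec()] objects (default [default_bands()]).
#' @return Named list of band-limited `soz_recording` objects, all with the
#'   same shape as the input.
#' @export
band_decompose <- function(rec, bands = default_bands()) {
  validate_recording(rec)
  out <- lapply(bands, function(b) {
    stopifnot(inherits(b, "band_spec"))
    if (b$high >= rec$fs / 2) {
      stop(sprintf("band '%s' reaches Nyquist at fs %g", b$name, rec$fs),
           call. = FALSE)
    }
    filtered <- bandpass_rows(rec$data, b$low, b$high, rec$fs)
    recording(filtered, fs = rec$fs, channel_names = rec$channel_names,
              soz_mask = rec$soz_mask)
  })
  names(out) <- vapply(bands, `[[`, "", "name")
  out
}

#' Slice a recording into overlapping epochs
#'
#' Epochs start at `0, shift_s, 2 * shift_s, ...` and must lie fully inside
#' the recording, giving `floor((duration - window_s) / shift_s) + 1` epochs.
#'
#' @param rec a [recording()].
#' @param window_s epoch length in seconds (default 30).
#' @param shift_s epoch-to-epoch shift in seconds (default 25).
#' @return A list of class `epoch_set` with elements `epochs` (list of
#'   channels-by-samples matrices), `starts_s`, `window_s`, `shift_s`, `fs`,
#'   `channel_names` and `soz_mask`.
#' @export
slice_windows <- function(rec, window_s = 30, shift_s = 25) {
  validate_recording(rec)
  stopifnot(window_s > 0, shift_s > 0)
  dur <- rec_duration(rec)
  if (dur < window_s) {
    stop("recording shorter than one window", call. = FALSE)
  }
  n_epochs <- floor((dur - window_s) / shift_s) + 1
  wlen <- round(window_s * rec$fs)
  starts <- (seq_len(n_epochs) - 1) * shift_s
  epochs <- lapply(starts, function(s0) {
    i0 <- round(s0 * rec$fs)
    rec$data[, (i0 + 1):(i0 + wlen), drop = FALSE]
  })
  structure(list(epochs = epochs, starts_s = starts, window_s = window_s,
                 shift_s = shift_s, fs = rec$fs,
                 channel_names = rec$channel_names,
                 soz_mask = rec$soz_mask),
            class = "epoch_set")
}

#' Rebalance SOZ representation by slice replication
#'
#' SOZ channels are under-represented in clinical implantations, so each SOZ
#' channel contributes `factor` channel-entries to the rebuilt set: its
#' consecutive `window_s`-second slices taken at `shift_s`-second offsets, in
#' chronological order.  Each non-SOZ channel contributes its first
#' `window_s`-second slice.  The result is a new recording whose "channels"
#' are these entries, with `n_nonSOZ + factor * n_SOZ` rows and an updated
#' SOZ mask marking every replicated entry.
#'
#' @param rec a [recording()] of good channels with at least one SOZ and one
#'   non-SOZ channel.
#' @param factor number of slices per SOZ channel (default 5).
#' @param window_s,shift_s slice geometry in seconds (defaults 30 and 25).
#' @return A `soz_recording` of channel entries, `window_s` seconds long.
#' @examples
#' rec <- simulate_recording(sim_config(n_channels = 6, n_soz = 2, fs = 200,
#'                                      duration = 40, seed = 1))
#' bal <- balance_soz(rec, factor = 2, window_s = 10, shift_s = 10)
#' sum(bal$soz_mask)  # 2 SOZ channels x factor 2
#' @export
balance_soz <- function(rec, factor = 5, window_s = 30, shift_s = 25) {
  validate_recording(rec)
  if (factor < 1) stop("factor must be >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (!any(rec$soz_mask)) {
    warning("no SOZ channels; returning input unchanged")
    return(rec)
  }
  if (!any(!rec$soz_mask)) {
    stop("need at least one non-SOZ channel", call. = FALSE)
  }
  need_s <- window_s + (factor - 1) * shift_s
  if (rec_duration(rec) < need_s) {
    stop(sprintf(
      "recording too short for %d distinct %gs slices at %gs shift",
      factor, window_s, shift_s), call. = FALSE)
  }
  wlen <- round(window_s * rec$fs)
  slice <- function(ch, k) {
    i0 <- round((k - 1) * shift_s * rec$fs)
    rec$data[ch, (i0 + 1):(i0 + wlen)]
  }
  rows <- list()
  names_out <- character()
  soz_out <- logical()
  for (ch in seq_len(nrow(rec$data))) {
    if (rec$soz_mask[ch]) {
      for (k in seq_len(factor)) {
        rows[[length(rows) + 1]] <- slice(ch, k)
        names_out <- c(names_out,
                       if (factor == 1) rec$channel_names[ch] else
                         sprintf("%s_s%d", rec$channel_names[ch], k))
        soz_out <- c(soz_out, TRUE)
      }
    } else {
      rows[[length(rows) + 1]] <- slice(ch, 1)
      names_out <- c(names_out, rec$channel_names[ch])
      soz_out <- c(soz_out, FALSE)
    }
  }
  recording(do.call(rbind, rows), fs = rec$fs, channel_names = names_out,
            soz_mask = soz_out)
}
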