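make_rec <- function(n_ch = 4, fs = 1000, dur = 10, f0 = NULL, seed = 1) {
  set.seed(seed)
  n <- round(fs * dur)
  t <- (0:(n - 1)) / fs
  dat <- matrix(rnorm(n_ch * n, sd = 0.1), n_ch, n)
  if (!is.null(f0)) {
    dat <- dat + matrix(rep(sin(2 * pi * f0 * t), each = n_ch), n_ch, n)
  }
  recording(dat, fs)
}

band_power <- function(x, fs, f0, half_width = 1) {
  sp <- Mod(fft(x))^2 / length(x)
  freqs <- (seq_along(x) - 1) * fs / length(x)
  sel <- freqs >= f0 - half_width & freqs <= f0 + half_width
  sum(sp[sel])
}

test_that("preprocessing resamples, re-references and keeps good channels", {
  rec <- make_rec(n_ch = 5, fs = 1000, dur = 10)
  rec$bad_mask[2] <- TRUE
  out <- preprocess_recording(rec)
  expect_equal(out$fs, 200)
  expect_equal(ncol(out$data), 2000)
  expect_equal(nrow(out$data), 4)
  expect_false("ch02" %in% out$channel_names)
  # common average reference: across-channel mean ~ 0 at every sample
  rms <- sqrt(mean(out$data^2))
  expect_lt(max(abs(colMeans(out$data))), 1e-9 * rms)
})

test_that("60 Hz line noise is attenuated by at least 30 dB", {
  rec <- make_rec(n_ch = 4, fs = 1000, dur = 10, f0 = 60)
  out <- preprocess_recording(rec)
  p_in <- band_power(rec$data[1, ], 1000, 60)
  p_out <- band_power(out$data[1, ], 200, 60)
  expect_lt(10 * log10(p_out / p_in), -30)
})

test_that("preprocessing rejects impossible configurations", {
  rec <- make_rec(n_ch = 3, fs = 100, dur = 5)
  expect_error(preprocess_recording(rec, target_fs = 400), "target_fs")
  rec$bad_mask[] <- TRUE
  expect_error(preprocess_recording(rec, target_fs = 100), "bad")
})

test_that("band decomposition isolates tones into the right band", {
  fs <- 200
  t <- (0:(fs * 10 - 1)) / fs
  mk <- function(f0) recording(rbind(sin(2 * pi * f0 * t),
                                     sin(2 * pi * f0 * t + 1)), fs)
  out <- band_decompose(mk(10))
  expect_named(out, c("delta", "theta", "alpha", "beta", "gamma"))
  for (b in out) expect_equal(dim(b$data), c(2, 2000))
  energies <- vapply(out, function(b) sum(b$data[1, ]^2), 0)
  expect_gt(energies["alpha"] / sum(energies), 0.9)
  out45 <- band_decompose(mk(45))
  e45 <- vapply(out45, function(b) sum(b$data[1, ]^2), 0)
  expect_gt(e45["gamma"], 10 * e45["beta"])
})

test_that("bands above Nyquist are rejected", {
  rec <- make_rec(n_ch = 2, fs = 100, dur = 5)
  expect_error(band_decompose(rec, list(band_spec("gamma", 30, 60))),
               "Nyquist")
})

test_that("zero-phase filtering leaves tone peaks unshifted", {
  fs <- 200
  t <- (0:(fs * 5 - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  rec <- recording(rbind(x, x), fs)
  out <- band_decompose(rec, list(band_spec("alpha", 7, 13)))$alpha
  # compare interior peak locations
  interior <- 200:800
  peaks_in <- interior[which(diff(sign(diff(x[interior]))) < 0) + 1]
  y <- out$data[1, ]
  peaks_out <- interior[which(diff(sign(diff(y[interior]))) < 0) + 1]
  expect_equal(length(peaks_in), length(peaks_out))
  expect_true(all(abs(peaks_in - peaks_out) <= 1))
})

test_that("epoch slicing follows the window/shift arithmetic", {
  rec <- make_rec(n_ch = 3, fs = 100, dur = 80)
  ep <- slice_windows(rec, window_s = 30, shift_s = 25)
  expect_length(ep$epochs, 3)
  expect_equal(ep$starts_s, c(0, 25, 50))
  expect_true(all(vapply(ep$epochs, ncol, 0L) == 3000))
  # exact-fit boundary cases
  expect_length(slice_windows(make_rec(dur = 30), 30, 25)$epochs, 1)
  expect_length(slice_windows(make_rec(dur = 30), 30, 1)$epochs, 1)
  expect_error(slice_windows(make_rec(dur = 20), 30, 25), "shorter")
})

test_that("SOZ balancing reproduces the fivefold worked example", {
  # 116 channels, 8 bad; of the 108 good ones 16 are SOZ
  fs <- 50
  dur <- 135  # >= 30 + 4 * 25 so five distinct slices exist
  set.seed(99)
  dat <- matrix(rnorm(116 * fs * dur, sd = 1), 116)
  bad <- rep(FALSE, 116)
  bad[1:8] <- TRUE
  soz <- rep(FALSE, 116)
  soz[9:24] <- TRUE
  rec <- recording(dat, fs, bad_mask = bad, soz_mask = soz)
  good <- recording(rec$data[!bad, ], fs,
                    channel_names = rec$channel_names[!bad],
                    soz_mask = rec$soz_mask[!bad])
  bal <- balance_soz(good, factor = 5)
  expect_equal(nrow(bal$data), 172)
  expect_equal(sum(bal$soz_mask), 80)
  # SOZ entries are exact slices of the source channel
  first_soz <- which(good$soz_mask)[1]
  w <- 30 * fs
  expect_identical(bal$data[which(bal$soz_mask)[1], ],
                   good$data[first_soz, 1:w])
  expect_identical(bal$data[which(bal$soz_mask)[2], ],
                   good$data[first_soz, (25 * fs + 1):(25 * fs + w)])
  # non-SOZ values are untouched copies of the first slice
  first_non <- which(!good$soz_mask)[1]
  expect_identical(bal$data[which(!bal$soz_mask)[1], ],
                   good$data[first_non, 1:w])
})

test_that("balancing arithmetic and degenerate cases", {
  rec <- make_rec(n_ch = 10, fs = 20, dur = 135)
  rec$soz_mask[c(3, 7)] <- TRUE
  bal <- balance_soz(rec, factor = 5)
  expect_equal(nrow(bal$data), 18)
  expect_equal(sum(bal$soz_mask), 10)
  bal1 <- balance_soz(rec, factor = 1)
  expect_equal(nrow(bal1$data), 10)
  expect_equal(sum(bal1$soz_mask), 2)
  expect_error(balance_soz(rec, factor = 0), "factor")
  rec$soz_mask[] <- FALSE
  expect_warning(out <- balance_soz(rec), "no SOZ")
  expect_identical(out$data, rec$data)
})

test_that("recordings round-trip through the text container", {
  rec <- make_rec(n_ch = 3, fs = 100, dur = 1)
  rec$bad_mask[2] <- TRUE
  rec$soz_mask[3] <- TRUE
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$bad_mask, rec$bad_mask)
  expect_equal(back$soz_mask, rec$soz_mask)
  expect_equal(back$data, rec$data, ignore_attr = TRUE,
               tolerance = 1e-6)
})
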