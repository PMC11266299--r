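#' Multichannel recording container
#'
#' Bundles a channels-by-samples signal matrix with its sampling rate,
#' channel names, a bad-channel mask and a seizure-onset-zone (SOZ) mask.
#' This is the object every stage of the pipeline consumes and returns.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per channel.  Defaults to
#'   `ch01`, `ch02`, ...
#' @param bad_mask logical vector flagging channels to be excluded by
#'   [preprocess_recording()].
#' @param soz_mask logical vector flagging SOZ channels (the positive class
#'   for localization).
#' @return An object of class `soz_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(400), nrow = 4), fs = 100)
#' rec
#' @export
recording <- function(data, fs, channel_names = NULL,
                      bad_mask = NULL, soz_mask = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  n_ch <- nrow(data)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(n_ch))
  }
  if (is.null(bad_mask)) bad_mask <- rep(FALSE, n_ch)
  if (is.null(soz_mask)) soz_mask <- rep(FALSE, n_ch)
  rec <- structure(
    list(data = data, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         bad_mask = as.logical(bad_mask),
         soz_mask = as.logical(soz_mask)),
    class = "soz_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "soz_recording"))
  n_ch <- nrow(rec$data)
  if (!is.finite(rec$fs) || rec$fs <= 0) {
    stop("sampling rate must be a positive number", call. = FALSE)
  }
  if (anyNA(rec$data)) stop("recording data contains NA/NaN", call. = FALSE)
  for (f in c("channel_names", "bad_mask", "soz_mask")) {
    if (length(rec[[f]]) != n_ch) {
      stop(sprintf("'%s' must have one entry per channel", f), call. = FALSE)
    }
  }
  invisible(rec)
}

#' @export
print.soz_recording <- function(x, ...) {
  cat(sprintf(
    "<soz_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  bad: %d   SOZ: %d\n", sum(x$bad_mask), sum(x$soz_mask)))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Write / read a recording as plain-text files
#'
#' Serializes a recording to a directory holding `data.tsv` (samples in rows,
#' channels in columns), a BIDS-style `channels.tsv` with columns `name`,
#' `status` (good/bad) and `soz` (yes/no), and `recording.json` with the
#' sampling rate.
#'
#' @param rec a [recording()].
#' @param dir directory to create/populate.
#' @return `write_recording()` returns `dir` invisibly; `read_recording()`
#'   returns a `soz_recording`.
#' @export
write_recording <- function(rec, dir) {
  validate_recording(rec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dat <- t(rec$data)
  colnames(dat) <- rec$channel_names
  write.table(dat, file.path(dir, "data.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ch <- data.frame(
    name = rec$channel_names,
    status = ifelse(rec$bad_mask, "bad", "good"),
    soz = ifelse(rec$soz_mask, "yes", "no"))
  write.table(ch, file.path(dir, "channels.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs), file.path(dir, "recording.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  dat <- as.matrix(read.table(file.path(dir, "data.tsv"), sep = "\t",
                              header = TRUE, check.names = FALSE))
  ch <- read.table(file.path(dir, "channels.tsv"), sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "recording.json"))
  recording(t(dat), fs = meta$fs, channel_names = ch$name,
            bad_mask = ch$status == "bad", soz_mask = ch$soz == "yes")
}
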