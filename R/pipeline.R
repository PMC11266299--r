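#' Pipeline configuration
#'
#' All tunable parameters of [run_pipeline()], with the defaults the package
#' operates at: resample to 200 Hz, 60 Hz notch, 0.5-80 Hz band restriction,
#' gamma band (30-60 Hz) for connectivity, 30 s epochs at 25 s shift,
#' proportional threshold 0.5, RBF-SVM with C = 0.5 under stratified 5-fold
#' cross-validation.
#'
#' @param target_fs resampling rate (Hz).
#' @param notch line-noise frequency (Hz).
#' @param band broadband restriction edges (Hz).
#' @param conn_band [band_spec()] used for connectivity (default gamma).
#' @param window_s,shift_s epoch geometry in seconds.
#' @param sparsity proportional-threshold operating point in `(0, 1]`.
#' @param balance_factor SOZ slice-replication factor; 1 (default) disables
#'   rebalancing, which is intended for long clinical recordings.
#' @param tau,m embedding delay/dimension overrides; `NULL` (default)
#'   selects them per recording with AMI and FNN.
#' @param tda_window_s seconds of signal delay-embedded per channel
#'   (default 30, the first window).
#' @param tda_max_points Rips subsample size per channel cloud.
#' @param tda_dims homology dimensions pooled into persistence entropy.
#' @param folds,cost SVM cross-validation folds and penalty.
#' @param standardize z-score the fused features (default `TRUE`).
#' @param seed master seed for subsampling and fold assignment.
#' @return A list of class `soz_pipeline_config`.
#' @export
soz_pipeline_config <- function(target_fs = 200, notch = 60,
                                band = c(0.5, 80),
                                conn_band = band_spec("gamma", 30, 60),
                                window_s = 30, shift_s = 25, sparsity = 0.5,
                                balance_factor = 1, tau = NULL, m = NULL,
                                tda_window_s = 30, tda_max_points = 100,
                                tda_dims = 0:2, folds = 5, cost = 0.5,
                                standardize = TRUE, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "soz_pipeline_config"
  cfg
}

select_embedding_params <- function(dat, fs, n_probe = 5, max_dim = 6) {
  # per-recording parameter selection: AMI delay and FNN dimension are
  # estimated on a spread of probe channels and combined by the median
  max_lag <- round(fs / 4)
  probe <- unique(round(seq(1, nrow(dat), length.out = min(n_probe,
                                                           nrow(dat)))))
  taus <- vapply(probe, function(ch) {
    as.integer(ami_delay(dat[ch, ], max_lag = max_lag))
  }, 0L)
  tau <- max(1L, as.integer(round(median(taus))))
  ms <- vapply(probe, function(ch) {
    as.integer(suppressWarnings(
      fnn_dimension(dat[ch, ], tau, max_dim = max_dim, max_points = 500)))
  }, 0L)
  list(tau = tau, m = max(2L, as.integer(round(median(ms)))))
}

#' Run the full SOZ localization pipeline
#'
#' Executes, on one labelled recording: preprocessing
#' ([preprocess_recording()]), optional SOZ rebalancing, connectivity-band
#' filtering, epoching, per-epoch WPLI matrices, proportional thresholding
#' and ENCS extraction; in parallel, per-channel delay embedding of the
#' first `tda_window_s` seconds of the broadband signal (AMI/FNN parameter
#' selection unless overridden), Rips persistence and persistence entropy;
#' then feature fusion, stratified cross-validated RBF-SVM classification
#' and metric computation.
#'
#' @param rec a labelled [recording()].
#' @param config a [soz_pipeline_config()].
#' @param verbose print stage progress (default `FALSE`).
#' @return List of class `soz_result` with elements `features` (fused
#'   table), `predictions` (out-of-fold labels and scores), `metrics`
#'   (confusion counts, AC/P/R/F1/AUC), `encs` (channels x epochs),
#'   `pe`, `embedding` (tau, m) and `config`.
#' @examples
#' \donttest{
#' rec <- simulate_recording(sim_config(n_channels = 12, n_soz = 3,
#'                                      duration = 35, seed = 7))
#' res <- run_pipeline(rec)
#' res$metrics$AUC
#' }
#' @export
run_pipeline <- function(rec, config = soz_pipeline_config(),
                         verbose = FALSE) {
  stopifnot(inherits(config, "soz_pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("preprocess: fs %g -> %g Hz", rec$fs, config$target_fs)
  pre <- preprocess_recording(rec, target_fs = config$target_fs,
                              notch = config$notch, band = config$band)
  if (config$balance_factor > 1) {
    say("balance: factor %d", config$balance_factor)
    pre <- balance_soz(pre, factor = config$balance_factor,
                       window_s = config$window_s,
                       shift_s = config$shift_s)
  }

  say("connectivity: %s band, %gs windows", config$conn_band$name,
      config$window_s)
  band_rec <- band_decompose(pre, bands = list(config$conn_band))[[1]]
  ep <- slice_windows(band_rec, window_s = config$window_s,
                      shift_s = config$shift_s)
  encs_mat <- vapply(ep$epochs, function(e) {
    conn <- wpli_matrix(e)
    encs(proportional_threshold(conn, config$sparsity))
  }, numeric(nrow(pre$data)))
  encs_mat <- matrix(encs_mat, nrow = nrow(pre$data))

  say("tda: embedding + Rips persistence on %d channels", nrow(pre$data))
  n_tda <- min(ncol(pre$data), round(config$tda_window_s * pre$fs))
  tda_dat <- pre$data[, seq_len(n_tda), drop = FALSE]
  if (is.null(config$tau) || is.null(config$m)) {
    emb <- select_embedding_params(tda_dat, pre$fs)
    if (!is.null(config$tau)) emb$tau <- as.integer(config$tau)
    if (!is.null(config$m)) emb$m <- as.integer(config$m)
  } else {
    emb <- list(tau = as.integer(config$tau), m = as.integer(config$m))
  }
  say("tda: tau = %d, m = %d", emb$tau, emb$m)
  pe <- vapply(seq_len(nrow(tda_dat)), function(ch) {
    cloud <- delay_embed(tda_dat[ch, ], emb$m, emb$tau)
    dgm <- rips_persistence(cloud, max_dim = 2,
                            max_points = config$tda_max_points,
                            subsample_seed = config$seed + ch)
    as.numeric(persistence_entropy(dgm, dims = config$tda_dims))
  }, 0)

  say("classify: %d-fold CV RBF-SVM (C = %g)", config$folds, config$cost)
  features <- build_features(encs_mat, pe, pre$soz_mask,
                             channels = pre$channel_names,
                             standardize = config$standardize)
  predictions <- fit_predict_cv(features, folds = config$folds,
                                cost = config$cost, seed = config$seed)
  metrics <- compute_metrics(predictions$predicted, predictions$score,
                             predictions$truth)
  structure(list(features = features, predictions = predictions,
                 metrics = metrics, encs = encs_mat, pe = pe,
                 embedding = emb, config = config),
            class = "soz_result")
}

#' @export
print.soz_result <- function(x, ...) {
  m <- x$metrics
  cat("<soz_result>\n")
  cat(sprintf("  channels: %d (SOZ %d)   epochs: %d\n",
              nrow(x$features), sum(x$features$label), ncol(x$encs)))
  cat(sprintf("  embedding: tau = %d, m = %d\n", x$embedding$tau,
              x$embedding$m))
  cat(sprintf(
    "  AC %.4f  P %.4f  R %.4f  F1 %.4f  AUC %.4f\n",
    m$AC, m$P, m$R, m$F1, m$AUC))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param result a [run_pipeline()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(result, path) {
  cfg <- result$config
  cfg$conn_band <- unclass(cfg$conn_band)
  jsonlite::write_json(
    list(metrics = result$metrics, embedding = result$embedding,
         config = unclass(cfg)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
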