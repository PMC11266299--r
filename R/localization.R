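#' Fuse per-channel network and topological features
#'
#' Builds the feature table the classifier consumes: one row per channel
#' entry, with the across-epoch mean ENCS and the persistence entropy, plus
#' the SOZ label.
#'
#' @param encs_per_epoch numeric matrix (channels x epochs) of per-epoch
#'   node degrees, or a vector for a single epoch.
#' @param pe numeric vector of per-channel persistence entropies (bits).
#' @param labels logical vector of SOZ labels.
#' @param channels optional channel names.
#' @param standardize z-score both feature columns (default `TRUE`;
#'   the RBF-SVM is scale sensitive).
#' @return data.frame with columns `channel`, `encs`, `pe`, `label`.
#' @export
build_features <- function(encs_per_epoch, pe, labels, channels = NULL,
                           standardize = TRUE) {
  if (is.vector(encs_per_epoch)) {
    encs_per_epoch <- matrix(encs_per_epoch, ncol = 1)
  }
  n_ch <- nrow(encs_per_epoch)
  if (length(pe) != n_ch || length(labels) != n_ch) {
    stop("feature inputs disagree on the number of channels", call. = FALSE)
  }
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(n_ch))
  tab <- data.frame(channel = channels,
                    encs = rowMeans(encs_per_epoch),
                    pe = as.numeric(pe),
                    label = as.logical(labels),
                    stringsAsFactors = FALSE)
  if (anyNA(tab)) stop("missing values in feature table", call. = FALSE)
  if (standardize) {
    for (col in c("encs", "pe")) {
      s <- sd(tab[[col]])
      tab[[col]] <- (tab[[col]] - mean(tab[[col]])) / max(s, .Machine$double.eps)
    }
  }
  tab
}

stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Cross-validated SVM channel classification
#'
#' Stratified k-fold cross-validation of an RBF-kernel support vector
#' machine: folds preserve the SOZ/non-SOZ proportion, each row is predicted
#' exactly once by a model that never saw it, and continuous decision scores
#' (oriented so larger means more SOZ-like) are returned for ROC analysis.
#'
#' @param features a [build_features()] table.
#' @param folds number of folds (default 5).
#' @param cost SVM penalty parameter C (default 0.5).
#' @param gamma RBF kernel width; `NULL` (default) uses
#'   `1 / (n_features * var(features))`, the scale-aware rule.
#' @param seed integer seed for the fold assignment.
#' @return data.frame with columns `channel`, `truth`, `predicted`, `score`,
#'   `fold`.
#' @export
fit_predict_cv <- function(features, folds = 5, cost = 0.5, gamma = NULL,
                           seed = 1) {
  stopifnot(all(c("encs", "pe", "label") %in% names(features)))
  y <- factor(ifelse(features$label, "SOZ", "nonSOZ"),
              levels = c("nonSOZ", "SOZ"))
  if (length(unique(y)) < 2) {
    stop("both classes must be present for cross-validation", call. = FALSE)
  }
  if (nrow(features) < folds) stop("fewer rows than folds", call. = FALSE)
  X <- as.matrix(features[, c("encs", "pe")])
  if (is.null(gamma)) gamma <- 1 / (ncol(X) * max(var(as.vector(X)), 1e-12))
  set.seed(as.integer(seed))
  fold_id <- stratified_folds(features$label, folds)
  predicted <- character(nrow(X))
  score <- numeric(nrow(X))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- e1071::svm(X[!test, , drop = FALSE], y[!test], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    pr <- predict(fit, X[test, , drop = FALSE], decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 reports the margin for the class named first in the colname
    flip <- if (startsWith(colnames(dv)[1], "SOZ")) 1 else -1
    predicted[test] <- as.character(pr)
    score[test] <- flip * dv[, 1]
  }
  data.frame(channel = features$channel, truth = features$label,
             predicted = predicted == "SOZ", score = score, fold = fold_id,
             stringsAsFactors = FALSE)
}

#' Classification metrics for SOZ localization
#'
#' Confusion counts plus accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`, their harmonic mean F1, and the area under the ROC
#' curve of the decision scores.  A degenerate precision (no positive
#' predictions) is reported as 0 with a warning.
#'
#' @param predicted logical vector of predicted labels.
#' @param scores numeric decision scores (larger = more SOZ-like); `NULL`
#'   skips the AUC.
#' @param truth logical vector of true labels.
#' @return List with elements `TP`, `TN`, `FP`, `FN`, `AC`, `P`, `R`, `F1`
#'   and `AUC` (proportions in `[0, 1]`; `AUC` is `NA` when not computable).
#' @examples
#' m <- compute_metrics(c(rep(TRUE, 9), rep(FALSE, 11)), NULL,
#'                      c(rep(TRUE, 8), FALSE, FALSE, rep(FALSE, 9), TRUE))
#' m$AC
#' @export
compute_metrics <- function(predicted, scores = NULL, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth differ in length", call. = FALSE)
  }
  tp <- sum(predicted & truth)
  tn <- sum(!predicted & !truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  ac <- (tp + tn) / length(truth)
  p <- if (tp + fp == 0) {
    warning("no positive predictions; precision reported as 0")
    0
  } else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(unique(truth)) < 2) {
      warning("AUC undefined with single-class truth")
    } else {
      roc <- pROC::roc(response = truth, predictor = scores,
                       levels = c(FALSE, TRUE), direction = "<",
                       quiet = TRUE)
      auc <- as.numeric(pROC::auc(roc))
    }
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn, AC = ac, P = p, R = r, F1 = f1,
       AUC = auc)
}

#' Paired group comparison of a per-channel feature
#'
#' For each patient the SOZ-channel mean and the non-SOZ-channel mean of the
#' feature are formed, and the per-patient differences are tested with a
#' paired t-test.
#'
#' @param values numeric per-channel feature (e.g. mean ENCS or PE).
#' @param soz logical per-channel SOZ labels.
#' @param patient patient identifier per channel; a single recording may
#'   pass a constant vector only if it has >= 2 patients' worth of data --
#'   the paired design needs at least two patients.
#' @return List with `t`, `p_value`, `df`, `mean_soz`, `sd_soz`,
#'   `mean_nonsoz`, `sd_nonsoz`, `n_patients`.
#' @export
group_compare <- function(values, soz, patient) {
  stopifnot(length(values) == length(soz), length(values) == length(patient))
  ids <- unique(patient)
  soz_means <- vapply(ids, function(pid)
    mean(values[patient == pid & soz]), 0)
  non_means <- vapply(ids, function(pid)
    mean(values[patient == pid & !soz]), 0)
  ok <- is.finite(soz_means) & is.finite(non_means)
  if (sum(ok) < 2) {
    stop("paired comparison needs at least 2 patients with both classes",
         call. = FALSE)
  }
  diffs <- soz_means[ok] - non_means[ok]
  if (sd(diffs) == 0) {
    # degenerate paired design: zero variance of the differences
    t_stat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    tt <- list(statistic = t_stat,
               p.value = if (mean(diffs) == 0) 1 else 0,
               parameter = length(diffs) - 1)
  } else {
    tt <- t.test(soz_means[ok], non_means[ok], paired = TRUE)
  }
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_soz = mean(soz_means[ok]), sd_soz = sd(soz_means[ok]),
       mean_nonsoz = mean(non_means[ok]), sd_nonsoz = sd(non_means[ok]),
       n_patients = sum(ok))
}
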