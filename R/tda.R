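mutual_information_bins <- function(x, y, n_bins) {
  bx <- cut(x, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  by <- cut(y, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' Delay selection by average mutual information
#'
#' Computes the average mutual information (AMI, equal-width histogram
#' estimator) between `x(t)` and `x(t + lag)` for lags `1..max_lag` and
#' returns the first local minimum of the curve -- the standard choice that
#' yields maximally independent yet dynamically related embedding
#' coordinates.  Two fallbacks guard the degenerate regimes: a series whose
#' lag-1 AMI is already at the histogram estimator's independence bias
#' (effectively memoryless data) returns delay 1, and a curve with no
#' interior local minimum returns the first lag below `AMI(1)/e`, else
#' `max_lag` with a warning.
#'
#' @param x numeric series, non-constant, length >= `4 * max_lag`.
#' @param max_lag largest lag to examine (samples).
#' @param n_bins histogram bins per marginal (default 16).
#' @return Integer delay in samples, with attribute `ami` (the curve) and
#'   `rule` (`"local_min"`, `"1/e"` or `"max_lag"`).
#' @export
ami_delay <- function(x, max_lag = 50, n_bins = 16) {
  x <- as.numeric(x)
  if (sd(x) == 0) stop("constant series has no AMI structure", call. = FALSE)
  if (length(x) < 4 * max_lag) {
    stop("series too short for requested max_lag", call. = FALSE)
  }
  ami <- vapply(seq_len(max_lag), function(lag) {
    n <- length(x) - lag
    mutual_information_bins(x[1:n], x[(lag + 1):(lag + n)], n_bins)
  }, 0)
  # first-order chi-square bias of the plug-in MI estimate under
  # independence; a lag-1 AMI at this level means no usable memory
  noise_floor <- (n_bins - 1)^2 / (2 * length(x) * log(2))
  rule <- "local_min"
  tau <- NA_integer_
  if (ami[1] <= 2 * noise_floor) {
    return(structure(1L, ami = ami, rule = "noise_floor"))
  }
  for (l in 2:(max_lag - 1)) {
    if (ami[l] < ami[l - 1] && ami[l] <= ami[l + 1]) {
      tau <- l
      break
    }
  }
  if (is.na(tau)) {
    below <- which(ami < ami[1] / exp(1))
    if (length(below)) {
      tau <- below[1]
      rule <- "1/e"
    } else {
      tau <- max_lag
      rule <- "max_lag"
      warning("no AMI minimum or 1/e crossing found; using max_lag")
    }
  }
  structure(as.integer(tau), ami = ami, rule = rule)
}

#' Embedding dimension by false nearest neighbours
#'
#' For each candidate dimension `m` the series is embedded at delay `tau`
#' and every point's nearest neighbour is found; the neighbour is declared
#' false if adding the next delay coordinate blows up their distance
#' (ratio above `rtol`, or jump above `atol` attractor sizes -- the standard
#' Kennel criteria).  Returns the smallest `m` whose false-neighbour
#' fraction falls below `threshold`; if none qualifies, `max_dim` with a
#' warning (characteristic of stochastic series with no finite embedding).
#'
#' @param x numeric series.
#' @param tau embedding delay in samples.
#' @param max_dim largest dimension to test (default 8).
#' @param rtol,atol Kennel thresholds (defaults 15 and 2).
#' @param threshold acceptable false-neighbour fraction (default 0.05).
#' @param max_points cap on embedded points examined (strided subsample of
#'   the cloud; temporal neighbours are still excluded by original index).
#' @return Integer dimension with attribute `fnn_fraction` (per dimension).
#' @export
fnn_dimension <- function(x, tau, max_dim = 8, rtol = 15, atol = 2,
                          threshold = 0.05, max_points = 1000) {
  x <- as.numeric(x)
  n_max <- length(x) - max_dim * tau
  if (n_max < 50) stop("series too short for FNN analysis", call. = FALSE)
  attractor_size <- sd(x)
  fracs <- numeric(max_dim)
  result <- NA_integer_
  for (m in seq_len(max_dim)) {
    emb <- delay_embed(x, m, tau)
    n_pts <- length(x) - m * tau  # points that also exist in dimension m+1
    emb <- emb[seq_len(n_pts), , drop = FALSE]
    nxt <- x[seq_len(n_pts) + m * tau]  # the (m+1)-th coordinate
    stride <- max(1L, ceiling(n_pts / max_points))
    idx <- seq(1, n_pts, by = stride)
    d <- as.matrix(dist(emb[idx, , drop = FALSE]))
    false_ct <- 0L
    for (a in seq_along(idx)) {
      row <- d[a, ]
      row[abs(idx - idx[a]) <= tau] <- Inf  # exclude temporal kin (and self)
      b <- which.min(row)
      rd <- row[b]
      extra <- abs(nxt[idx[a]] - nxt[idx[b]])
      if (rd < 1e-8 * attractor_size) {
        # numerically coincident points (exactly periodic orbits): the
        # ratio test is meaningless, only a genuine jump counts
        if (extra / attractor_size > atol) false_ct <- false_ct + 1L
      } else if (extra / rd > rtol ||
                 sqrt(rd^2 + extra^2) / attractor_size > atol) {
        false_ct <- false_ct + 1L
      }
    }
    fracs[m] <- false_ct / length(idx)
    if (fracs[m] < threshold) {
      result <- m
      break
    }
  }
  if (is.na(result)) {
    warning("false-neighbour fraction never fell below threshold; ",
            "returning max_dim")
    result <- max_dim
  }
  structure(as.integer(result), fnn_fraction = fracs[seq_len(max(result, 1))])
}

#' Takens delay embedding
#'
#' Maps a scalar series to the point cloud whose i-th row is
#' `(x_i, x_{i+tau}, ..., x_{i+(m-1) tau})`, reconstructing the attractor
#' geometry of the underlying dynamics.
#'
#' @param x numeric series of length `> (m - 1) * tau`.
#' @param m embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return Numeric matrix with `length(x) - (m - 1) * tau` rows and `m`
#'   columns.
#' @examples
#' delay_embed(1:10, m = 3, tau = 2)  # 6 points; first point (1, 3, 5)
#' @export
delay_embed <- function(x, m, tau) {
  x <- as.numeric(x)
  m <- as.integer(m)
  tau <- as.integer(tau)
  stopifnot(m >= 1, tau >= 1)
  n_pts <- length(x) - (m - 1) * tau
  if (n_pts < 1) stop("series too short for this (m, tau)", call. = FALSE)
  cols <- lapply(seq_len(m) - 1L, function(k) x[(1 + k * tau):(n_pts + k * tau)])
  do.call(cbind, cols)
}

#' Vietoris-Rips persistent homology of a point cloud
#'
#' Builds the Rips filtration (simplices appear when their diameter reaches
#' the scale parameter) up to skeleton dimension `max_dim + 1` and computes
#' the persistence pairs of homology in dimensions `0..max_dim` by boundary
#' matrix reduction over GF(2).  Classes still alive at `max_scale` are
#' reported with `death = Inf`.  Zero-persistence pairs are dropped.
#'
#' @param points numeric matrix of point coordinates (rows = points).
#' @param max_dim largest homology dimension, at most 2 (default 2).
#' @param max_scale filtration cutoff; `NULL` (default) uses `scale_frac`
#'   times the cloud diameter, which bounds the simplex count while
#'   retaining every feature born from local geometry.
#' @param scale_frac fraction of the cloud diameter used when `max_scale`
#'   is `NULL` (default 0.5).
#' @param max_points clouds larger than this are uniformly subsampled
#'   (seeded) before the filtration is built (default 400).
#' @param subsample_seed seed for that subsample (default 1).
#' @return data.frame of class `persistence_diagram` with columns
#'   `dimension`, `birth`, `death`, and attributes `max_scale`, `n_points`.
#' @examples
#' square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' rips_persistence(square, max_dim = 1, max_scale = 2)
#' @export
rips_persistence <- function(points, max_dim = 2, max_scale = NULL,
                             max_points = 400, subsample_seed = 1,
                             scale_frac = 0.5) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("empty point cloud", call. = FALSE)
  if (!all(is.finite(points))) stop("non-finite coordinates", call. = FALSE)
  if (max_dim > 2) stop("homology dimensions above 2 not supported",
                        call. = FALSE)
  if (nrow(points) > max_points) {
    set.seed(as.integer(subsample_seed))
    points <- points[sort(sample(nrow(points), max_points)), , drop = FALSE]
  }
  n <- nrow(points)
  if (n == 1) {
    dgm <- data.frame(dimension = 0L, birth = 0, death = Inf)
    attr(dgm, "max_scale") <- max_scale
    attr(dgm, "n_points") <- 1L
    class(dgm) <- c("persistence_diagram", "data.frame")
    return(dgm)
  }
  dmat <- as.matrix(dist(points))
  if (is.null(max_scale)) max_scale <- scale_frac * max(dmat)
  if (max_scale <= 0) stop("max_scale must be positive", call. = FALSE)
  res <- rips_persistence_cpp(dmat, max_scale, as.integer(max_dim))
  dgm <- data.frame(dimension = as.integer(res[, 1]), birth = res[, 2],
                    death = res[, 3])
  dgm <- dgm[order(dgm$dimension, dgm$birth, dgm$death), ]
  rownames(dgm) <- NULL
  attr(dgm, "max_scale") <- max_scale
  attr(dgm, "n_points") <- n
  class(dgm) <- c("persistence_diagram", "data.frame")
  dgm
}

#' Persistence entropy of a diagram
#'
#' Shannon entropy (base 2) of the normalized interval lifetimes: with
#' `p_i = |death_i - birth_i|` and `L = sum(p_i)`,
#' `PE = -sum (p_i / L) log2(p_i / L)`.  Low entropy means a few dominant
#' features (simple, regular topology); high entropy means many comparable
#' features (complex, irregular topology).  Essential classes
#' (infinite death) have no finite lifetime and are excluded.
#'
#' @param diagram a [rips_persistence()] result, or any data.frame with
#'   columns `dimension`, `birth`, `death`.
#' @param dims homology dimensions to pool (default `0:2`).
#' @return Entropy in bits, with attributes `n_intervals` and
#'   `total_lifetime`.
#' @examples
#' d <- data.frame(dimension = 0L, birth = 0, death = c(1, 1))
#' persistence_entropy(d)  # two equal lifetimes: exactly 1 bit
#' @export
persistence_entropy <- function(diagram, dims = 0:2) {
  stopifnot(all(c("dimension", "birth", "death") %in% names(diagram)))
  d <- diagram[diagram$dimension %in% dims & is.finite(diagram$death), ]
  life <- abs(d$death - d$birth)
  life <- life[life > 0]
  if (length(life) == 0) {
    stop("no finite positive-lifetime intervals in the requested dimensions",
         call. = FALSE)
  }
  p <- life / sum(life)
  structure(-sum(p * log2(p)),
            n_intervals = length(life), total_lifetime = sum(life))
}
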