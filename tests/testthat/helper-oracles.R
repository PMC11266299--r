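# Independent brute-force oracles used to cross-check the package
# implementations.  These are deliberately naive: direct formula evaluation,
# exhaustive enumeration, and textbook matrix reduction.

# WPLI by direct evaluation of the defining ratio on two real signals:
# analytic signals via explicit DFT half-spectrum doubling, then a plain
# loop over cross-spectral samples.
oracle_wpli_pair <- function(x, y, trim = 0.05) {
  hilb <- function(v) {
    n <- length(v)
    V <- fft(v)
    h <- numeric(n)
    if (n %% 2 == 0) {
      h[c(1, n / 2 + 1)] <- 1
      h[2:(n / 2)] <- 2
    } else {
      h[1] <- 1
      h[2:((n + 1) / 2)] <- 2
    }
    fft(V * h, inverse = TRUE) / n
  }
  n <- length(x)
  keep <- seq.int(floor(n * trim) + 1, n - floor(n * trim))
  xa <- hilb(x)[keep]
  ya <- hilb(y)[keep]
  num <- 0
  den <- 0
  for (i in seq_along(xa)) {
    ci <- xa[i] * Conj(ya[i])
    num <- num + Im(ci)
    den <- den + abs(Im(ci))
  }
  if (den == 0) 0 else abs(num) / den
}

# All-pairs shortest paths by breadth-first search on a 0/1 adjacency.
oracle_bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lvl <- 0
    while (length(frontier)) {
      lvl <- lvl + 1
      nxt <- integer()
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (d[s, v] > lvl) {
            d[s, v] <- lvl
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

oracle_path_length <- function(adj) {
  d <- oracle_bfs_distances(adj)
  off <- d[upper.tri(d)]
  mean(off[is.finite(off)])
}

# Mean local clustering by exhaustive triangle counting over all triples.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
      }
    }
    ci[v] <- 2 * tri / (k * (k - 1))
  }
  mean(ci)
}

# Vietoris-Rips persistence by textbook left-to-right boundary-matrix
# reduction over GF(2), with full simplex enumeration via combn().
# Tractable for clouds of up to ~10 points; independent of the package's
# C++ path.
oracle_rips <- function(points, max_dim = 2, max_scale) {
  dm <- as.matrix(dist(points))
  n <- nrow(dm)
  simplices <- list()
  for (d in 0:(max_dim + 1)) {
    if (d + 1 > n) break
    combs <- utils::combn(n, d + 1)
    for (c_i in seq_len(ncol(combs))) {
      vs <- combs[, c_i]
      diam <- if (d == 0) 0 else max(dm[t(utils::combn(vs, 2))])
      if (diam <= max_scale) {
        simplices[[length(simplices) + 1]] <- list(v = vs, dim = d,
                                                   diam = diam)
      }
    }
  }
  diam <- vapply(simplices, `[[`, 0, "diam")
  dims <- vapply(simplices, `[[`, 0L, "dim")
  key <- vapply(simplices, function(s)
    paste(sprintf("%03d", s$v), collapse = "-"), "")
  ord <- order(diam, dims, key)
  simplices <- simplices[ord]
  diam <- diam[ord]
  dims <- dims[ord]
  key <- key[ord]
  m <- length(simplices)
  # boundary columns as sorted index vectors
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    s <- simplices[[j]]
    if (s$dim == 0) {
      cols[[j]] <- integer()
    } else {
      faces <- vapply(seq_along(s$v), function(drop_i)
        paste(sprintf("%03d", s$v[-drop_i]), collapse = "-"), "")
      cols[[j]] <- sort(match(faces, key))
    }
  }
  low_of <- rep(NA_integer_, m)  # pivot row -> column
  pairs <- list()
  for (j in seq_len(m)) {
    col <- cols[[j]]
    while (length(col)) {
      low <- max(col)
      if (is.na(low_of[low])) break
      other <- cols[[low_of[low]]]
      col <- sort(union(setdiff(col, other), setdiff(other, col)))
    }
    cols[[j]] <- col
    if (length(col)) {
      low <- max(col)
      low_of[low] <- j
      pairs[[length(pairs) + 1]] <-
        c(dims[low], diam[low], diam[j])
    }
  }
  paired_as_birth <- !is.na(low_of)
  is_death <- vapply(cols, function(cc) length(cc) > 0, TRUE)
  for (j in seq_len(m)) {
    if (!paired_as_birth[j] && !is_death[j] && dims[j] <= max_dim) {
      pairs[[length(pairs) + 1]] <- c(dims[j], diam[j], Inf)
    }
  }
  out <- do.call(rbind, pairs)
  out <- data.frame(dimension = as.integer(out[, 1]), birth = out[, 2],
                    death = out[, 3])
  out <- out[out$death > out$birth & out$dimension <= max_dim, ]
  out[order(out$dimension, out$birth, out$death), , drop = FALSE]
}

# canonicalize a persistence diagram for comparison
dgm_key <- function(d) {
  d <- d[order(d$dimension, d$birth, d$death), ]
  sprintf("%d|%.9f|%.9f", d$dimension, d$birth,
          ifelse(is.finite(d$death), d$death, 1e18))
}

# AUC as the normalized Mann-Whitney U statistic with tie correction
oracle_auc <- function(scores, truth) {
  r <- rank(scores)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
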