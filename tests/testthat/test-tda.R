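test_that("AMI finds the low-information valley of a sinusoid", {
  fs <- 200
  t <- (0:3999) / fs
  x <- sin(2 * pi * 10 * t)  # period 20 samples
  tau <- ami_delay(x, max_lag = 40)
  # the histogram AMI of a sinusoid has a flat valley spanning the quarter
  # period (lags 2..8); its first local minimum sits at lag 3, and the
  # half-period lag 10 is an information peak (the relation degenerates to
  # a line there)
  expect_equal(attr(tau, "rule"), "local_min")
  expect_true(as.integer(tau) >= 2 && as.integer(tau) <= 8)
  curve <- attr(tau, "ami")
  expect_gt(curve[10], curve[as.integer(tau)])
  expect_gt(curve[10], curve[9])
  # affine rescaling leaves the histogram MI unchanged
  tau2 <- ami_delay(2 * x + 7, max_lag = 40)
  expect_identical(as.integer(tau), as.integer(tau2))
})

test_that("AMI falls back quickly for i.i.d. noise", {
  set.seed(3)
  x <- runif(10000)
  tau <- ami_delay(x, max_lag = 30)
  expect_true(attr(tau, "rule") != "local_min")
  expect_lte(as.integer(tau), 3)
  expect_error(ami_delay(rep(1, 1000)), "constant")
})

test_that("FNN finds the planar dimension of a limit cycle", {
  fs <- 200
  t <- (0:3999) / fs
  # incommensurate frequency so samples trace the cycle without exact
  # duplicates (an integer-period tone collapses to finitely many points,
  # where the fold at m = 1 is invisible by construction)
  x <- sin(2 * pi * 10.7 * t)
  m <- fnn_dimension(x, tau = 5)
  expect_equal(as.integer(m), 2)
  fr <- attr(m, "fnn_fraction")
  expect_lt(fr[length(fr)], 0.05)
})

test_that("FNN saturates at max_dim for i.i.d. noise", {
  set.seed(9)
  x <- rnorm(3000)
  expect_warning(m <- fnn_dimension(x, tau = 1, max_dim = 6), "threshold")
  expect_equal(as.integer(m), 6)
  expect_error(fnn_dimension(rnorm(60), tau = 10, max_dim = 8), "short")
})

test_that("delay embedding lays out coordinates per the defining map", {
  emb <- delay_embed(1:10, m = 3, tau = 2)
  expect_equal(dim(emb), c(6, 3))
  expect_equal(emb[1, ], c(1, 3, 5))
  expect_equal(emb[6, ], c(6, 8, 10))
  expect_equal(delay_embed(1:5, m = 1, tau = 3), cbind(1:5))
  expect_error(delay_embed(1:5, m = 3, tau = 3), "short")
})

test_that("a sinusoid embeds to a circle at quarter-period delay", {
  fs <- 200
  t <- (0:999) / fs
  x <- sin(2 * pi * 10 * t)
  emb <- delay_embed(x, m = 2, tau = 5)
  radii <- sqrt(rowSums(emb^2))
  expect_lt(max(abs(radii - 1)), 0.01)
})

test_that("Rips persistence reproduces analytic diagrams", {
  # single point: one essential component, nothing else
  d1 <- rips_persistence(matrix(0, 1, 2))
  expect_equal(nrow(d1), 1)
  expect_equal(d1$dimension, 0L)
  expect_equal(d1$death, Inf)
  # two points at distance 2: one merge at 2, one essential
  d2 <- rips_persistence(rbind(0, 2), max_scale = 3)
  expect_equal(sort(d2$death), c(2, Inf))
  # unit square: three merges at 1 and the loop (1, sqrt(2))
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dsq <- rips_persistence(sq, max_dim = 1, max_scale = 2)
  h0 <- dsq[dsq$dimension == 0, ]
  h1 <- dsq[dsq$dimension == 1, ]
  expect_equal(sort(h0$death), c(1, 1, 1, Inf))
  expect_equal(nrow(h1), 1)
  expect_equal(h1$birth, 1)
  expect_equal(h1$death, sqrt(2))
  expect_error(rips_persistence(matrix(0, 0, 2)), "empty")
})

test_that("Rips persistence matches brute-force matrix reduction", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    dim_p <- sample(2:3, 1)
    pts <- matrix(rnorm(n * dim_p), n)
    r <- 0.8 * max(dist(pts))
    got <- rips_persistence(pts, max_dim = 2, max_scale = r)
    want <- oracle_rips(pts, max_dim = 2, max_scale = r)
    expect_identical(dgm_key(got), dgm_key(want))
  }
})

test_that("diagrams are invariant to rigid motions", {
  set.seed(17)
  pts <- matrix(rnorm(20 * 2), 20)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- pts %*% rot + matrix(c(3, -1), 20, 2, byrow = TRUE)
  d1 <- rips_persistence(pts, max_dim = 1, max_scale = 2)
  d2 <- rips_persistence(moved, max_dim = 1, max_scale = 2)
  expect_equal(d1$birth, d2$birth, tolerance = 1e-9)
  expect_equal(d1$death, d2$death, tolerance = 1e-9)
})

test_that("noisy circle shows one dominant 1-cycle, a blob none", {
  circ <- sample_shape("circle", 40, scale = 1, noise_sd = 0.02, seed = 3)
  expect_true(all(dist(sample_shape("circle", 20, noise_sd = 0)) <= 2 + 1e-12))
  d <- rips_persistence(circ, max_dim = 1, max_scale = 2)
  h1 <- d[d$dimension == 1 & is.finite(d$death), ]
  lens <- sort(h1$death - h1$birth, decreasing = TRUE)
  expect_gte(length(lens), 1)
  if (length(lens) > 1) expect_gt(lens[1], 3 * lens[2])
  blob <- sample_shape("blob", 30, scale = 1, seed = 5)
  db <- rips_persistence(blob, max_dim = 1, max_scale = 0.8 * max(dist(blob)))
  bh1 <- db[db$dimension == 1 & is.finite(db$death), ]
  if (nrow(bh1)) {
    expect_true(all(bh1$death - bh1$birth <= 0.25 * max(dist(blob))))
  }
  expect_error(sample_shape("torus", 10), "unknown shape")
})

test_that("persistence entropy follows the lifetime distribution", {
  two_eq <- data.frame(dimension = 0L, birth = 0, death = c(1, 1))
  expect_equal(as.numeric(persistence_entropy(two_eq)), 1)
  one <- data.frame(dimension = 0L, birth = 0, death = 2)
  expect_equal(as.numeric(persistence_entropy(one)), 0)
  skew <- data.frame(dimension = c(0L, 1L), birth = c(0, 1),
                     death = c(3, 2))
  expect_equal(as.numeric(persistence_entropy(skew)),
               -0.75 * log2(0.75) - 0.25 * log2(0.25), tolerance = 1e-12)
  # essential classes are excluded; all-essential diagrams are degenerate
  ess <- data.frame(dimension = 0L, birth = 0, death = Inf)
  expect_error(persistence_entropy(ess), "finite")
})

test_that("entropy is bounded by log2 of the interval count", {
  set.seed(23)
  for (rep in 1:10) {
    k <- sample(2:30, 1)
    d <- data.frame(dimension = 0L, birth = 0, death = runif(k, 0.1, 5))
    pe <- persistence_entropy(d)
    expect_lte(as.numeric(pe), log2(k) + 1e-12)
    expect_gte(as.numeric(pe), 0)
  }
  eq <- data.frame(dimension = 0L, birth = 1, death = 1 + rep(0.5, 8))
  expect_equal(as.numeric(persistence_entropy(eq)), 3)
})
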