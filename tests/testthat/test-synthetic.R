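test_that("synthetic whitened scenes satisfy their statistical contract", {
  set.seed(40)
  sc <- generate_whitened_scene(96)
  x <- sc$pixels
  expect_lt(abs(mean(x)), 1e-2)
  expect_equal(max(abs(x)), 1)
  expect_true(all(is.finite(x)))

  # radially averaged amplitude spectrum approximately flat over the
  # passband (within a factor of 2 of its median)
  A <- Mod(fft(x))
  n <- nrow(x)
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  f <- sqrt(outer(fx^2, fx^2, "+"))
  band <- cut(f[f > 2 & f < 0.3 * n], breaks = 12)
  prof <- tapply(A[f > 2 & f < 0.3 * n], band, mean)
  expect_lt(max(prof) / median(prof), 2)
  expect_gt(min(prof) / median(prof), 0.5)

  # spatial decorrelation: pixel autocorrelation at lag 3 below 0.3
  v1 <- as.vector(x[, 1:(n - 3)])
  v2 <- as.vector(x[, 4:n])
  expect_lt(abs(cor(v1, v2)), 0.3)

  # heavy-tailed pixel statistics (kurtosis well above Gaussian)
  expect_gt(mean(x^4) / mean(x^2)^2, 6)
  expect_error(generate_whitened_scene(8), "at least 12")
})

test_that("Gabor fixtures tile orientation space with unit norm", {
  gs <- make_gabor_population(22)
  expect_length(gs, 22)
  for (g in gs) expect_equal(sum(g^2), 1)
  oris <- vapply(gs, attr, numeric(1), "orientation")
  expect_equal(oris, seq(0, 180, length.out = 23)[1:22])
  # constructed orientations are maximally diverse on the binning grid
  expect_gt(orientation_diversity_index(oris, n_bins = 22), 0.95)
  # orthogonal Gabors are nearly uncorrelated
  g0 <- make_gabor(0); g90 <- make_gabor(90)
  expect_lt(abs(rf_similarity(g0, g90)), 0.25)
  # installed fixtures invert exactly through the weight split
  W <- gabor_weights(gs)
  expect_equal(rf_from_weights(W, 7), unclass(gs[[7]]), ignore_attr = TRUE)
})

test_that("the LNP surrogate has the prescribed response statistics", {
  set.seed(41)
  g <- make_gabor(40)
  unit <- lnp_surrogate(g, gain = 2, offset = 0)
  # orthogonal stimulus with zero offset: expected count 0
  orth <- matrix(as.vector(make_gabor(130)), 12, 12)
  proj <- sum(g * orth)
  counts <- replicate(200, unit(orth))
  expect_lt(mean(counts), 2 * max(proj, 0) + 0.3)
  # matched stimulus: mean equals gain * <g, g> = gain
  counts2 <- replicate(500, unit(unclass(g)))
  expect_equal(mean(counts2), 2, tolerance = 0.2)
  expect_error(lnp_surrogate(g, gain = 0), "positive")
})

test_that("STA over noise patches recovers an LNP population's filters", {
  set.seed(42)
  gs <- make_gabor_population(6)
  n <- 15000
  S <- matrix(pmax(rnorm(n * 144, 15, 20), 0), n, 144)
  G <- vapply(gs, as.vector, numeric(144))
  counts <- matrix(rpois(n * 6, pmax(S %*% G, 0) * 0.15), n, 6)
  sta <- spike_triggered_average(S, counts)
  sims <- vapply(1:6, function(j)
    rf_similarity(sta[, j] - colMeans(S), G[, j]), numeric(1))
  expect_true(all(sims > 0.8))
})
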