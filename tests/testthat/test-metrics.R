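test_that("receptive fields invert the ON/OFF weight mapping", {
  # pure ON weights: map equals the ON weights
  W <- rbind(matrix(1:144 / 10, 144, 1), matrix(0, 144, 1))
  expect_equal(as.vector(rf_from_weights(W, 1)), 1:144 / 10)
  # equal ON and OFF cancel
  W2 <- rbind(matrix(0.5, 144, 1), matrix(0.5, 144, 1))
  expect_true(all(rf_from_weights(W2, 1) == 0))
  # a Gabor installed through its ON/OFF split is recovered exactly
  g <- make_gabor(37, phase = 0.3)
  Wg <- gabor_weights(list(g))
  expect_equal(rf_from_weights(Wg, 1), unclass(g), ignore_attr = TRUE)
})

test_that("the spike-triggered average behaves as a weighted stimulus mean", {
  set.seed(30)
  S <- matrix(rnorm(200 * 16), 200, 16)
  # one spike on one stimulus: STA is that stimulus
  cnt <- integer(200); cnt[57] <- 1L
  expect_equal(spike_triggered_average(S, cnt), S[57, ])
  # spike counts independent of the stimulus: STA approaches the mean stimulus
  cnt2 <- rpois(200, 4)
  sta <- spike_triggered_average(S, cnt2)
  expect_lt(max(abs(sta - colMeans(S))), 0.5)
  expect_warning(spike_triggered_average(S, integer(200)), "zero")
})

test_that("an LNP neuron's STA recovers its Gabor filter", {
  set.seed(31)
  g <- make_gabor(65, phase = 0.2)
  n <- 20000
  S <- matrix(pmax(rnorm(n * 144, 15, 20), 0), n, 144)
  lambda <- pmax(S %*% as.vector(g), 0) * 0.15
  cnt <- rpois(n, lambda)
  sta <- spike_triggered_average(S, cnt) - colMeans(S)
  expect_gt(rf_similarity(sta, g), 0.8)
})

test_that("cosine similarity hits its landmark values", {
  v <- rnorm(144)
  expect_equal(rf_similarity(v, v), 1)
  expect_equal(rf_similarity(v, -v), -1)
  a <- c(1, 0); b <- c(0, 1)
  expect_equal(rf_similarity(a, b), 0)
  expect_warning(expect_true(is.na(rf_similarity(v, numeric(144)))), "zero")
  sm <- rf_similarity_matrix(cbind(v, -v, v))
  expect_equal(sm[1, 2], -1)
  expect_equal(sm[1, 3], 1)
})

test_that("orientation bandwidth interpolates the 1/sqrt(2) crossing", {
  # triangular curve, zero at +/-45 deg around a 90-deg peak:
  # crossing at 45 * (1 - 1/sqrt(2)) from the peak
  th <- seq(0, 176, by = 4)
  resp <- pmax(0, 1 - abs(th - 88) / 45)  # peak on the grid
  expect_equal(orientation_bandwidth(resp, th), 45 * (1 - 1 / sqrt(2)),
               tolerance = 0.05)
  # flat curve: undefined
  expect_true(is.na(orientation_bandwidth(rep(1, length(th)), th)))
  # Gaussian curve of sd 20 deg: closed-form half width sigma*sqrt(ln 2)
  g <- exp(-(th - 88)^2 / (2 * 20^2))
  expect_equal(orientation_bandwidth(g, th), 20 * sqrt(log(2)),
               tolerance = 0.3)
  # peak at the domain edge is handled circularly
  g2 <- exp(-pmin(th, 180 - th)^2 / (2 * 20^2))
  expect_equal(orientation_bandwidth(g2, th), 20 * sqrt(log(2)),
               tolerance = 0.5)
})

test_that("the orientation diversity index follows its divergence definition", {
  # uniform histogram: ODI = 1
  pref <- rep((0:21 + 0.5) * (180 / 22), 2)
  expect_equal(orientation_diversity_index(pref, n_bins = 22), 1)
  # all mass in one of K bins: ODI = 1/K
  expect_equal(orientation_diversity_index(rep(45, 50), n_bins = 22), 1 / 22)
  # three-bin hand oracle: P = (0.5, 0.25, 0.25)
  pref3 <- c(10, 20, 70, 130)
  dkl <- 0.5 * log(0.5 / (1 / 3)) + 2 * 0.25 * log(0.25 / (1 / 3))
  expect_equal(orientation_diversity_index(pref3, n_bins = 3), exp(-dkl))
  # permutation invariance of bin contents
  expect_equal(orientation_diversity_index(c(10, 70, 130, 20), n_bins = 3),
               exp(-dkl))
  expect_warning(orientation_diversity_index(numeric(0)), "empty")
})

test_that("population sparseness hits its closed-form landmarks", {
  expect_equal(population_sparseness(c(1, 0, 0, 0)), 1)
  expect_equal(population_sparseness(c(3, 3, 3, 3)), 0)
  expect_equal(population_sparseness(c(1, 1, 0, 0)), 2 / 3)
  expect_warning(expect_true(is.na(population_sparseness(c(0, 0, 0)))),
                 "all-zero")
  m <- cbind(c(1, 0, 0, 0), c(2, 2, 2, 2))
  expect_equal(unname(population_sparseness(m)), c(1, 0))
})

test_that("mutual information per spike matches closed forms", {
  # deterministic binary code over two stimuli: 1 bit, 0.5 spikes/bin
  cnt <- rbind(rep(0, 100), rep(1, 100))
  r <- mutual_information_per_spike(cnt)
  expect_equal(r$mi, 1)
  expect_equal(r$bits_per_spike, 2)
  # identical counts everywhere: zero information
  expect_equal(mutual_information_per_spike(matrix(3, 4, 50))$mi, 0)
  # noiseless code: conditional entropy zero
  cnt3 <- rbind(rep(1, 50), rep(2, 50), rep(4, 50))
  r3 <- mutual_information_per_spike(cnt3)
  expect_equal(r3$H_r_given_s, 0)
  expect_equal(r3$mi, r3$H_r)
  expect_warning(mutual_information_per_spike(matrix(0, 3, 10)), "zero")
})

test_that("discriminability follows the projected-moments formula", {
  set.seed(32)
  # identical response distributions: d' = 0
  a <- matrix(rep(c(1, 2, 3), 10), 10, 3, byrow = TRUE)
  expect_equal(discriminability(a, a), 0)
  # two Gaussian clouds: matches the independently computed formula
  a <- matrix(rnorm(4000, 0, 1), 2000, 2)
  b <- matrix(rnorm(4000, 1, 1), 2000, 2)
  d <- colMeans(a) - colMeans(b)
  pa <- a %*% d; pb <- b %*% d
  expected <- (mean(pa) - mean(pb)) / (0.5 * (var(as.vector(pa)) +
                                                var(as.vector(pb))))
  expect_equal(discriminability(a, b), expected)
  # the data-dependent projection axis makes the printed statistic
  # symmetric under swapping the two ensembles
  expect_equal(discriminability(b, a), discriminability(a, b))
})

test_that("z-normalized reconstruction error is affine-invariant", {
  set.seed(33)
  img <- matrix(rnorm(400), 20, 20)
  expect_equal(ire(img, img), 0)
  expect_equal(ire(img, img + 5), 0)        # offset removed
  expect_equal(ire(img, 3 * img + 1), 0)    # affine rescaling removed
  expect_warning(expect_true(is.na(ire(img, matrix(1, 20, 20)))), "constant")
  expect_error(reconstruct_scene(matrix(0, 5, 5), identity, diag(144)),
               "smaller")
})

test_that("an orthonormal linear population reconstructs a scene almost perfectly", {
  set.seed(34)
  sc <- generate_whitened_scene(36)
  basis <- qr.Q(qr(matrix(rnorm(144 * 144), 144, 144)))  # orthonormal
  respond <- function(patch) as.vector(crossprod(basis, as.vector(patch)))
  rec <- reconstruct_scene(sc$pixels, respond, basis)
  expect_lt(ire(sc$pixels, rec), 0.2)
})

test_that("response correlation organizes by receptive-field similarity", {
  set.seed(35)
  n_stim <- 3000
  base <- matrix(rpois(20 * n_stim, 5), 20, n_stim)
  W <- matrix(runif(144 * 20), 144, 20)
  # duplicated neuron pair: correlation 1 in the top similarity bin
  resp <- rbind(base, base[1, , drop = FALSE])
  W2 <- cbind(W, W[, 1])
  cs <- correlation_vs_similarity(resp, W2)
  expect_equal(cs$mean_correlation[30], 1, tolerance = 1e-9)
  # independent neurons: grand mean near zero
  cs0 <- correlation_vs_similarity(base, W)
  expect_lt(abs(cs0$grand_mean), 0.05)
  # anti-correlated constructed pair
  x <- rep(c(0, 10), length.out = n_stim)
  pair <- rbind(x, 10 - x)
  csn <- correlation_vs_similarity(pair, matrix(runif(288 * 2), 288, 2))
  expect_equal(csn$grand_mean, -1)
  # constant-rate neurons are excluded and counted
  resp3 <- rbind(base[1:3, ], matrix(2, 1, n_stim))
  cs3 <- correlation_vs_similarity(resp3, matrix(runif(144 * 4), 144, 4))
  expect_equal(cs3$n_excluded, 3L)
})
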