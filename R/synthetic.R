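# Synthetic inputs and fixtures: whitened-scene surrogates, Gabor
# populations, and linear-nonlinear-Poisson surrogate neurons.

#' Generate a whitened natural-scene surrogate
#'
#' Builds a base image with natural-image-like second-order statistics
#' (a 1/f-amplitude Gaussian random field plus a sparse set of
#' hard-edged elliptical patches, which contributes the heavy-tailed
#' pixel statistics of occlusion-rich scenes), then applies the
#' whitening ramp f * exp(-(f/f0)^4) in the Fourier domain -- the
#' classic sparse-coding preprocessing -- yielding an approximately
#' zero-mean, spatially decorrelated image with a flattened amplitude
#' spectrum and a high-frequency cutoff. The result is normalized so
#' the maximum absolute pixel value is 1.
#'
#' The base image is modulated by a smooth lognormal contrast field
#' before whitening, reproducing the local-contrast nonstationarity of
#' natural scenes. The pixel statistics of the result match whitened
#' natural scenes: approximately zero mean, kurtosis in the tens (so
#' the per-scene maximum used for normalization is a rare event and
#' typical pixel magnitudes are a few percent of it), mean absolute
#' pixel value around 0.04 after normalization -- hence mean LGN rates
#' of a few Hz when the rare maximum maps to 125 Hz.
#'
#' @param size image side in pixels (default 128; must be >= 12).
#' @param cutoff_frequency whitening roll-off f0 in cycles/image
#'   (default 0.4 * size, the conventional 200 cycles for a 512-pixel
#'   image, scaled).
#' @param shape_density occluding shapes per pixel of image side.
#' @param bed relative amplitude of the Gaussian 1/f bed under the
#'   shapes.
#' @param contrast_sd log-sd of the smooth local-contrast field
#'   (default 0.6; 0 disables it).
#' @param scene_id identifier.
#' @return A \code{\link{whitened_scene}}.
#' @export
generate_whitened_scene <- function(size = 128,
                                    cutoff_frequency = 0.4 * size,
                                    shape_density = 8e-3, bed = 0.15,
                                    contrast_sd = 0.6, scene_id = NULL) {
  if (size < 12) stop("size must be at least 12")
  # frequency grid (cycles/image)
  fx <- c(0:(size %/% 2), -((size - size %/% 2 - 1):1))
  f <- sqrt(outer(fx^2, fx^2, "+"))

  # 1/f Gaussian random field
  phase <- matrix(complex(modulus = 1,
                          argument = runif(size^2, 0, 2 * pi)), size, size)
  amp <- 1 / pmax(f, 1)
  base <- Re(fft(amp * phase, inverse = TRUE)) / size

  # sparse occluding shapes with Laplacian-like amplitudes carry the
  # heavy-tailed statistics of edge-rich scenes
  n_shapes <- max(4, round(shape_density * size))
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  shapes <- matrix(0, size, size)
  for (k in seq_len(n_shapes)) {
    cx <- runif(1, 1, size); cy <- runif(1, 1, size)
    rx <- runif(1, size / 20, size / 3); ry <- runif(1, size / 20, size / 3)
    th <- runif(1, 0, pi)
    v <- sign(runif(1) - 0.5) * stats::rexp(1)
    xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    shapes <- shapes + v * ((xr / rx)^2 + (yr / ry)^2 < 1)
  }
  base <- shapes / max(sd(shapes), 1e-12) + bed * base / sd(base)

  # smooth lognormal contrast field: local-contrast nonstationarity is
  # what makes the per-scene maximum a rare event
  if (contrast_sd > 0) {
    gph <- matrix(complex(modulus = 1,
                          argument = runif(size^2, 0, 2 * pi)), size, size)
    gf <- Re(fft(exp(-(f / (size / 16))^2) * gph, inverse = TRUE)) / size
    base <- base * exp(contrast_sd * gf / sd(gf))
  }

  # whitening with high-frequency cutoff: divide by the measured
  # radially averaged amplitude of the base image (a generalization of
  # the f * exp(-(f/f0)^4) ramp that stays exact when the base is not
  # precisely 1/f), flattening the amplitude spectrum over the passband
  Fb <- fft(base)
  ring <- round(f)
  rad <- tapply(Mod(Fb), ring, mean)
  amp <- matrix(rad[as.character(ring)], nrow(f), ncol(f))
  filt <- exp(-(f / cutoff_frequency)^4) / pmax(amp, 1e-12 * max(amp))
  filt[1, 1] <- 0  # remove the mean
  wh <- Re(fft(filt * Fb, inverse = TRUE)) / size^2
  wh <- wh - mean(wh)
  wh <- wh / max(abs(wh))
  if (is.null(scene_id))
    scene_id <- sprintf("synthetic-%06d", floor(runif(1) * 1e6))
  whitened_scene(wh, scene_id)
}

#' Generate a set of synthetic whitened scenes
#'
#' @param n number of scenes.
#' @param ... passed to \code{\link{generate_whitened_scene}}.
#' @return List of \code{whitened_scene}s.
#' @export
generate_scene_set <- function(n = 10, ...) {
  lapply(seq_len(n), function(k)
    generate_whitened_scene(scene_id = sprintf("synthetic-%03d", k), ...))
}

#' Render a unit-norm Gabor patch
#'
#' An oriented sinusoid under a Gaussian envelope: the canonical V1
#' simple-cell receptive-field model, used as a ground-truth fixture.
#'
#' @param orientation degrees.
#' @param phase radians.
#' @param wavelength carrier wavelength in pixels.
#' @param sigma envelope standard deviation in pixels.
#' @param size patch side (default 12).
#' @return size x size matrix with unit Euclidean norm and attributes
#'   \code{orientation}, \code{phase}, \code{wavelength}, \code{sigma}.
#' @export
make_gabor <- function(orientation, phase = 0, wavelength = 8,
                       sigma = 3, size = 12) {
  th <- orientation * pi / 180
  cc <- seq_len(size) - (size + 1) / 2
  x <- matrix(cc, size, size, byrow = TRUE)
  y <- matrix(cc, size, size)
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  g <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / wavelength + phase)
  g <- g / sqrt(sum(g^2))
  structure(g, orientation = orientation, phase = phase,
            wavelength = wavelength, sigma = sigma)
}

#' Gabor fixture population with orientations tiling [0, 180)
#'
#' @param n number of fixtures.
#' @param ... passed to \code{\link{make_gabor}}.
#' @return List of Gabor matrices, orientations n evenly spaced values
#'   in [0, 180).
#' @export
make_gabor_population <- function(n, ...) {
  oris <- seq(0, 180, length.out = n + 1)[seq_len(n)]
  lapply(oris, function(o) make_gabor(o, ...))
}

#' Install Gabor fixtures as frozen feed-forward weights
#'
#' Splits each Gabor into its ON/OFF parts (positive part to the ON
#' rows, magnitude of the negative part to the OFF rows) and stacks
#' the columns into an LGN-afferent weight matrix, so that
#' \code{\link{rf_from_weights}} recovers each fixture exactly.
#'
#' @param gabors list from \code{\link{make_gabor_population}}.
#' @param gain multiplicative weight scale (default 1).
#' @return n_lgn x n matrix.
#' @export
gabor_weights <- function(gabors, gain = 1) {
  cols <- lapply(gabors, function(g) {
    v <- as.vector(g)
    gain * c(pmax(v, 0), pmax(-v, 0))
  })
  do.call(cbind, cols)
}

#' Linear-nonlinear-Poisson surrogate neuron
#'
#' Returns a responder \code{f(stimulus)} producing Poisson counts
#' with mean gain * max(<filter, stimulus>, 0) + offset. Stimuli may
#' be images (matrices) or ON/OFF rate arrays (collapsed to ON - OFF).
#' Used as a ground-truth oracle for STA and tuning estimators.
#'
#' @param filter a (Gabor) matrix.
#' @param gain positive scale factor.
#' @param offset baseline mean count.
#' @return Function: stimulus -> integer count (vectorized over a list).
#' @export
lnp_surrogate <- function(filter, gain = 1, offset = 0) {
  if (gain <= 0) stop("gain must be positive")
  fv <- as.vector(filter)
  function(stimulus) {
    s <- if (length(dim(stimulus)) == 3)
      as.vector(stimulus[, , 1]) - as.vector(stimulus[, , 2])
    else as.vector(stimulus)
    lambda <- gain * max(sum(fv * s), 0) + offset
    stats::rpois(1, lambda)
  }
}

#' LNP population responder over a Gabor fixture set
#'
#' @param gabors list of fixtures.
#' @param gain,offset shared LNP parameters.
#' @return Function: stimulus -> count vector (one per fixture).
#' @export
lnp_population <- function(gabors, gain = 1, offset = 0) {
  units <- lapply(gabors, lnp_surrogate, gain = gain, offset = offset)
  function(stimulus) vapply(units, function(u) u(stimulus), numeric(1))
}
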