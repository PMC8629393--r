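# Stimulus pipeline: whitened scenes -> 12x12 patches -> ON/OFF rate maps,
# plus sinusoidal gratings and Gaussian noise patches.

#' Construct a whitened scene
#'
#' Wraps a 2-D signed pixel array (whitened luminance, arbitrary units)
#' together with its per-scene normalization divisor, the maximum
#' absolute pixel value.
#'
#' @param pixels numeric matrix of finite values.
#' @param scene_id identifier string.
#' @return An object of class \code{whitened_scene}.
#' @export
whitened_scene <- function(pixels, scene_id = "scene") {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("scene pixels must be finite")
  m <- max(abs(pixels))
  if (m <= 0) m <- 1  # constant-zero scene: divisor is moot
  structure(list(pixels = pixels, scene_id = scene_id, norm = m),
            class = "whitened_scene")
}

#' Sample a normalized patch from a whitened scene
#'
#' Cuts a \code{size} x \code{size} patch at a uniformly random offset,
#' divides by the scene's maximum absolute pixel value (so patch values
#' lie in [-1, 1]), and flips the patch about the horizontal and
#' vertical axes independently, each with probability 0.5.
#'
#' @param scene a \code{whitened_scene}.
#' @param size patch side length in pixels (default 12).
#' @param flip logical; disable to get the raw cut-out (for testing).
#' @param offset optional c(row, col) 1-based top-left corner; when
#'   given, no random offset is drawn.
#' @return A \code{size} x \code{size} matrix with values in [-1, 1],
#'   with attributes \code{source} (scene id and offset) and
#'   \code{flips}.
#' @export
sample_patch <- function(scene, size = 12, flip = TRUE, offset = NULL) {
  stopifnot(inherits(scene, "whitened_scene"))
  d <- dim(scene$pixels)
  if (d[1] < size || d[2] < size)
    stop("scene (", d[1], "x", d[2], ") is smaller than the patch size ", size)
  if (is.null(offset)) {
    offset <- c(
      1L + floor(runif(1) * (d[1] - size + 1)),
      1L + floor(runif(1) * (d[2] - size + 1))
    )
  }
  p <- scene$pixels[offset[1]:(offset[1] + size - 1),
                    offset[2]:(offset[2] + size - 1)] / scene$norm
  flips <- c(horizontal = FALSE, vertical = FALSE)
  if (flip) {
    flips <- runif(2) < 0.5
    names(flips) <- c("horizontal", "vertical")
    if (flips[1]) p <- p[, ncol(p):1]  # mirror about the vertical axis
    if (flips[2]) p <- p[nrow(p):1, ]  # mirror about the horizontal axis
  }
  structure(p, source = list(scene_id = scene$scene_id, offset = offset),
            flips = flips)
}

#' Split a signed patch into nonnegative ON/OFF firing-rate planes
#'
#' Positive pixel values map to the ON plane and the magnitude of
#' negative values to the OFF plane, scaled so that unit pixel
#' magnitude corresponds to \code{r_max} Hz. At most one of ON/OFF is
#' nonzero per pixel, and ON - OFF recovers \code{r_max} times the
#' input exactly.
#'
#' @param patch signed matrix with |values| <= 1.
#' @param r_max firing rate (Hz) assigned to unit pixel magnitude;
#'   the training default is 125 Hz.
#' @return A \code{nrow x ncol x 2} array (Hz); plane 1 = ON, 2 = OFF.
#' @export
on_off_split <- function(patch, r_max = 125) {
  if (r_max <= 0) stop("r_max must be positive")
  patch <- unclass(as.matrix(patch))
  out <- array(0, c(nrow(patch), ncol(patch), 2),
               dimnames = list(NULL, NULL, c("on", "off")))
  out[, , 1] <- pmax(patch, 0) * r_max
  out[, , 2] <- pmax(-patch, 0) * r_max
  attr(out, "r_max") <- r_max
  out
}

#' Flatten an ON/OFF rate array into the LGN rate vector
#'
#' Column-major flattening; ON units first (indices 1..n), OFF units
#' second (n+1..2n). This fixed ordering is shared by the simulator and
#' by \code{\link{rf_from_weights}}.
#'
#' @param rates array from \code{\link{on_off_split}} or compatible.
#' @return Numeric vector of length \code{2 * prod(dim)[1:2]}, Hz.
#' @export
rates_to_vector <- function(rates) {
  stopifnot(length(dim(rates)) == 3, dim(rates)[3] == 2)
  c(as.vector(rates[, , 1]), as.vector(rates[, , 2]))
}

#' Sinusoidal grating as an ON/OFF rate map
#'
#' Renders cos(2 pi f (x cos(theta) + y sin(theta)) + phi) on a
#' \code{size} x \code{size} grid with coordinates relative to the
#' patch centre, rescales to unit peak amplitude, and passes the result
#' through \code{\link{on_off_split}}. Contrast is manipulated solely
#' through \code{r_max}.
#'
#' @param orientation grating angle theta in degrees.
#' @param phase spatial phase phi in radians, within [0, pi].
#' @param spatial_frequency cycles/pixel, within [0.05, 0.15] for the
#'   tuning protocol.
#' @param r_max peak firing rate (Hz); the tuning protocol uses 85.7 Hz
#'   and the contrast sweep spans 14.25 to 100 Hz.
#' @param size patch side length (default 12).
#' @return ON/OFF rate array as from \code{\link{on_off_split}}.
#' @export
make_grating <- function(orientation, phase = 0, spatial_frequency = 0.10,
                         r_max = 85.7, size = 12) {
  if (r_max <= 0) stop("r_max must be positive")
  if (spatial_frequency <= 0) stop("spatial_frequency must be positive")
  th <- orientation * pi / 180
  cc <- (seq_len(size) - (size + 1) / 2)  # centred pixel coordinates
  x <- matrix(cc, size, size, byrow = TRUE)
  y <- matrix(cc, size, size)
  g <- cos(2 * pi * spatial_frequency * (x * cos(th) + y * sin(th)) + phase)
  g <- g / max(abs(g))  # unit peak amplitude on the discrete grid
  on_off_split(g, r_max)
}

#' Gaussian noise patch for receptive-field mapping
#'
#' Draws a \code{size} x \code{size} image from Normal(mu, sigma),
#' clips negative values to zero, and interprets the result directly as
#' firing rates on the ON plane (the OFF plane is zero, since no pixel
#' is negative after clipping).
#'
#' @param size patch side (default 12).
#' @param mu,sigma noise mean and standard deviation in Hz
#'   (defaults 15 and 20).
#' @return ON/OFF rate array; attribute \code{image} holds the clipped
#'   noise image used as the stimulus for spike-triggered averaging.
#' @export
make_noise_patch <- function(size = 12, mu = 15, sigma = 20) {
  img <- matrix(rnorm(size * size, mu, sigma), size, size)
  img[img < 0] <- 0
  out <- array(0, c(size, size, 2), dimnames = list(NULL, NULL, c("on", "off")))
  out[, , 1] <- img
  attr(out, "image") <- img
  out
}
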