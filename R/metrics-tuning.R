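# Orientation tuning: tuning curves, bandwidth, diversity, gain.

#' Measure orientation tuning curves with sinusoidal gratings
#'
#' Presents gratings over a full 0-360 degree sweep in 8 degree steps,
#' crossed with spatial phases in [0, pi] and spatial frequencies in
#' [0.05, 0.15] cycles/pixel, each combination repeated \code{reps}
#' times for 125 ms with plasticity off. The per-condition response is
#' the mean spike count over repetitions; the per-orientation response
#' is the maximum over phases and frequencies. Responses are folded to
#' the orientation domain [0, 180).
#'
#' @param net a trained \code{v1_network}, or a function
#'   \code{f(rates_array) -> count vector} (e.g. an LNP surrogate) for
#'   fixture-based testing.
#' @param r_max peak input rate, Hz (contrast; default 85.7).
#' @param orientations grating angles in degrees (default the 8-degree
#'   grid over [0, 360)).
#' @param phases,freqs phase and spatial-frequency grids.
#' @param reps repetitions per condition (default 50).
#' @param record_currents also return the window-averaged excitatory
#'   and inhibitory input currents per condition (network input only).
#' @return List of class \code{tuning_result}: \code{orientation}
#'   (folded grid, degrees), \code{response} (n_neurons x n_orient mean
#'   counts per 125 ms), \code{preferred} (degrees), \code{contrast}
#'   (= r_max), and optionally \code{mean_ie}, \code{mean_ii},
#'   \code{mean_u}, plus the updated \code{net}.
#' @export
measure_tuning <- function(net, r_max = 85.7,
                           orientations = seq(0, 352, by = 8),
                           phases = seq(0, pi, length.out = 5),
                           freqs = seq(0.05, 0.15, length.out = 5),
                           reps = 50, record_currents = FALSE) {
  grid <- expand.grid(phase = phases, freq = freqs,
                      orientation = orientations)
  n_cond <- nrow(grid)
  size <- if (inherits(net, "v1_network")) net$config$patch_size else 12
  rates <- matrix(0, 2 * size^2, n_cond)
  for (k in seq_len(n_cond))
    rates[, k] <- rates_to_vector(make_grating(
      grid$orientation[k], grid$phase[k], grid$freq[k], r_max, size))

  if (inherits(net, "v1_network")) {
    all_rates <- rates[, rep(seq_len(n_cond), each = reps), drop = FALSE]
    r <- present_batch(net, all_rates, plastic = FALSE)
    rep_idx <- rep(seq_len(n_cond), each = reps)
    cnt <- t(apply(r$counts_e, 1, function(x) tapply(x, rep_idx, mean)))
    if (record_currents) {
      mie <- t(apply(r$mean_ie, 1, function(x) tapply(x, rep_idx, mean)))
      mii <- t(apply(r$mean_ii, 1, function(x) tapply(x, rep_idx, mean)))
      mu <- t(apply(r$mean_u, 1, function(x) tapply(x, rep_idx, mean)))
    }
    net <- r$net
  } else {
    stopifnot(is.function(net))
    cnt <- matrix(0, length(net(array(rates[, 1], c(size, size, 2)))), n_cond)
    for (k in seq_len(n_cond)) {
      acc <- 0
      for (rr in seq_len(reps))
        acc <- acc + net(array(rates[, k], c(size, size, 2)))
      cnt[, k] <- acc / reps
    }
  }

  # reduce: max over phase x frequency within each orientation
  ori_idx <- match(grid$orientation, orientations)
  resp_full <- t(apply(cnt, 1, function(x) tapply(x, ori_idx, max)))
  if (is.vector(resp_full)) resp_full <- matrix(resp_full, nrow = 1)

  # fold 0-360 sweep onto orientation domain [0, 180)
  folded <- orientations %% 180
  od <- sort(unique(folded))
  fold_idx <- match(folded, od)
  resp <- t(apply(resp_full, 1, function(x) tapply(x, fold_idx, max)))
  if (is.vector(resp)) resp <- matrix(resp, nrow = 1)

  out <- list(orientation = od, response = resp,
              preferred = od[apply(resp, 1, which.max)],
              contrast = r_max)
  if (inherits(net, "v1_network")) {
    out$net <- net
    if (record_currents) {
      red <- function(m) {
        mm <- t(apply(m, 1, function(x) tapply(x, ori_idx, mean)))
        t(apply(mm, 1, function(x) tapply(x, fold_idx, mean)))
      }
      out$mean_ie <- red(mie); out$mean_ii <- red(mii); out$mean_u <- red(mu)
    }
  }
  class(out) <- "tuning_result"
  out
}

#' Orientation bandwidth of a tuning curve
#'
#' Half-width of the tuning curve at 1/sqrt(2) (approximately 70.7%)
#' of its maximum, found by linear interpolation on each flank of the
#' peak on the circular orientation domain; the OBW is the mean of the
#' two half-widths. Curves whose flanks never cross the level (e.g.
#' flat curves or high-baseline curves) give NA.
#'
#' @param response response vector over the orientation grid.
#' @param orientation orientation grid in degrees over [0, 180).
#' @param period domain period (180 for orientation).
#' @return Bandwidth in degrees, or NA if undefined.
#' @export
orientation_bandwidth <- function(response, orientation, period = 180) {
  n <- length(response)
  if (n < 3 || max(response) <= 0) return(NA_real_)
  pk <- which.max(response)
  level <- response[pk] / sqrt(2)
  # walk outward from the peak on each side (circular indexing)
  half_width <- function(dir) {
    prev_r <- response[pk]
    prev_o <- 0
    for (s in seq_len(n - 1)) {
      i <- ((pk - 1 + dir * s) %% n) + 1
      o_rel <- (orientation[i] - orientation[pk]) * dir
      o_rel <- ((o_rel %% period) + period) %% period
      r <- response[i]
      if (r <= level) {
        frac <- (prev_r - level) / (prev_r - r)
        return(prev_o + frac * (o_rel - prev_o))
      }
      prev_r <- r
      prev_o <- o_rel
      if (o_rel >= period / 2) break
    }
    NA_real_
  }
  hw <- c(half_width(+1), half_width(-1))
  if (all(is.na(hw))) return(NA_real_)
  mean(hw, na.rm = TRUE)
}

#' Orientation bandwidths for all neurons of a tuning result
#'
#' @param tuning a \code{tuning_result} from \code{\link{measure_tuning}}.
#' @return Numeric vector of OBW values (degrees; NA where undefined).
#' @export
tuning_bandwidths <- function(tuning) {
  apply(tuning$response, 1, orientation_bandwidth,
        orientation = tuning$orientation)
}

#' Orientation diversity index
#'
#' Histogram P of preferred orientations over equal-width bins spanning
#' [0, 180), compared to the uniform distribution Q by Kullback-Leibler
#' divergence; ODI = exp(-D_KL(P || Q)). 1 indicates a uniform (maximally
#' diverse) distribution; all mass in one of K bins gives 1/K. Empty
#' bins contribute zero to the divergence.
#'
#' @param preferred preferred orientations in degrees.
#' @param n_bins number of bins (default 22, approximately 8 degrees
#'   wide).
#' @return Scalar in (0, 1].
#' @export
orientation_diversity_index <- function(preferred, n_bins = 22) {
  if (length(preferred) == 0) {
    warning("ODI undefined for empty input")
    return(NA_real_)
  }
  if (n_bins < 2) stop("n_bins must be at least 2")
  br <- seq(0, 180, length.out = n_bins + 1)
  h <- tabulate(findInterval(preferred %% 180, br,
                             rightmost.closed = TRUE), n_bins)
  P <- h / sum(h)
  Q <- 1 / n_bins
  dkl <- sum(P[P > 0] * log(P[P > 0] / Q))
  exp(-dkl)
}

#' Neuronal gain curves: spike count versus excitatory input current
#'
#' From a tuning measurement with recorded currents (gratings rotated
#' from the orthogonal to the preferred orientation of each neuron at
#' each contrast), pairs each neuron's spike count with its mean
#' excitatory input current, sorts ascending by current, and averages
#' within current bins to give the population gain curve per contrast.
#'
#' @param net a trained \code{v1_network}.
#' @param contrasts peak input rates, Hz (default c(14.25, 100), the
#'   contrast-sweep endpoints).
#' @param n_bins number of current bins.
#' @param ... passed to \code{\link{measure_tuning}} (e.g. \code{reps}).
#' @return List of class \code{gain_result}: per contrast a data.frame
#'   with bin-mean \code{I_exc} (pA) and \code{count}; plus the
#'   updated \code{net}.
#' @export
gain_curve <- function(net, contrasts = c(14.25, 100), n_bins = 20, ...) {
  stopifnot(inherits(net, "v1_network"))
  pooled <- list()
  for (ct in contrasts) {
    tr <- measure_tuning(net, r_max = ct, record_currents = TRUE, ...)
    net <- tr$net
    pooled[[as.character(ct)]] <-
      data.frame(I_exc = as.vector(tr$mean_ie),
                 count = as.vector(tr$response))
  }
  all_i <- unlist(lapply(pooled, `[[`, "I_exc"))
  br <- quantile(all_i, probs = seq(0, 1, length.out = n_bins + 1),
                 names = FALSE)
  br[1] <- -Inf; br[length(br)] <- Inf
  curves <- lapply(pooled, function(d) {
    bin <- findInterval(d$I_exc, br, rightmost.closed = TRUE)
    data.frame(
      I_exc = tapply(d$I_exc, factor(bin, levels = seq_len(n_bins)), mean),
      count = tapply(d$count, factor(bin, levels = seq_len(n_bins)), mean)
    )
  })
  structure(list(curves = curves, contrasts = contrasts, net = net),
            class = "gain_result")
}
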