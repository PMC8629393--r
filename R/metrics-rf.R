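# Receptive-field estimation and comparison.

#' Receptive field from feed-forward weights
#'
#' Reverts the ON/OFF mapping: subtracts the OFF synapses from the ON
#' synapses of the LGN-afferent weight vector and reshapes to the patch
#' grid.
#'
#' @param weights n_lgn x n_post LGN-afferent matrix (rows: ON units
#'   then OFF units, column-major pixel order).
#' @param neuron postsynaptic index; if \code{NULL}, all neurons.
#' @return A size x size matrix (one neuron) or a size x size x n array.
#' @export
rf_from_weights <- function(weights, neuron = NULL) {
  npre <- nrow(weights)
  half <- npre / 2
  size <- sqrt(half)
  if (size != round(size)) stop("weight rows do not form a square ON/OFF grid")
  one <- function(j)
    matrix(weights[seq_len(half), j] - weights[(half + 1):npre, j], size, size)
  if (!is.null(neuron)) return(one(neuron))
  out <- array(0, c(size, size, ncol(weights)))
  for (j in seq_len(ncol(weights))) out[, , j] <- one(j)
  out
}

#' Spike-triggered average
#'
#' STA = (1/N) * sum over spikes of the eliciting stimulus, where N is
#' the total spike count: the average of the presented stimuli weighted
#' by the per-stimulus spike counts.
#'
#' @param stimuli n_stimuli x n_pixels matrix of stimulus images (each
#'   row one flattened stimulus).
#' @param counts spike counts: vector of length n_stimuli (one neuron)
#'   or n_stimuli x n_neurons matrix.
#' @return Flattened STA vector (one neuron) or n_pixels x n_neurons
#'   matrix; neurons with zero total spikes yield NA columns with a
#'   warning.
#' @export
spike_triggered_average <- function(stimuli, counts) {
  stimuli <- as.matrix(stimuli)
  if (is.vector(counts)) {
    if (sum(counts) == 0) {
      warning("STA undefined: zero total spikes")
      return(rep(NA_real_, ncol(stimuli)))
    }
    return(as.vector(crossprod(stimuli, counts) / sum(counts)))
  }
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  out <- crossprod(stimuli, counts)
  out <- sweep(out, 2, pmax(tot, 1), "/")
  if (any(tot == 0)) {
    warning(sum(tot == 0), " neuron(s) with zero spikes: STA undefined (NA)")
    out[, tot == 0] <- NA_real_
  }
  out
}

#' Cosine similarity between receptive fields
#'
#' cos(phi) = <a, b> / (|a| |b|) of the flattened maps or feed-forward
#' weight vectors: +1 identical shape, 0 orthogonal, -1 polarity-
#' inverted.
#'
#' @param rf_a,rf_b numeric vectors, matrices, or weight columns.
#' @return Scalar in [-1, 1]; NA with a warning for a zero vector.
#' @export
rf_similarity <- function(rf_a, rf_b) {
  a <- as.vector(rf_a); b <- as.vector(rf_b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("similarity undefined for a zero vector")
    return(NA_real_)
  }
  sum(a * b) / (na * nb)
}

#' Pairwise cosine-similarity matrix of weight columns
#'
#' @param weights npre x npost matrix; similarity is computed between
#'   columns.
#' @return npost x npost symmetric matrix.
#' @export
rf_similarity_matrix <- function(weights) {
  nrm <- sqrt(colSums(weights^2))
  nrm[nrm == 0] <- NA_real_
  s <- crossprod(weights) / outer(nrm, nrm)
  s[s > 1] <- 1; s[s < -1] <- -1
  s
}

#' Map receptive fields of a trained network by spike-triggered average
#'
#' Presents Gaussian noise patches (Normal(15, 20) Hz, clipped at 0,
#' ON plane) for 125 ms each and computes each excitatory neuron's STA.
#'
#' @param net a trained \code{v1_network}.
#' @param n_stimuli number of noise patches.
#' @return List: \code{sta} (n_pixels x n_exc), \code{counts},
#'   \code{stimuli}, and the updated \code{net}.
#' @export
measure_sta <- function(net, n_stimuli = 5000) {
  size <- net$config$patch_size
  stim <- matrix(0, n_stimuli, size^2)
  rates <- matrix(0, net$config$n_lgn, n_stimuli)
  for (k in seq_len(n_stimuli)) {
    np <- make_noise_patch(size)
    stim[k, ] <- as.vector(attr(np, "image"))
    rates[, k] <- rates_to_vector(np)
  }
  r <- present_batch(net, rates, plastic = FALSE)
  list(sta = spike_triggered_average(stim, t(r$counts_e)),
       counts = r$counts_e, stimuli = stim, net = r$net)
}
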