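# Coding-efficiency metrics: E/I balance, sparseness, reconstruction,
# information, discriminability, correlation structure.

#' Population sparseness (Vinje-Gallant)
#'
#' S = (1 - (sum r_i / n)^2 / sum(r_i^2 / n)) / (1 - 1/n). One for a
#' one-hot response vector, zero for a uniform one.
#'
#' @param responses nonnegative per-neuron rates for one stimulus
#'   (length >= 2), or a matrix (neurons x stimuli) for which the
#'   per-stimulus sparseness values are returned.
#' @return Scalar in [0, 1], or a vector per stimulus; all-zero
#'   response vectors give NA with a warning.
#' @export
population_sparseness <- function(responses) {
  if (is.matrix(responses))
    return(apply(responses, 2, function(r)
      suppressWarnings(population_sparseness(r))))
  n <- length(responses)
  if (n < 2) stop("need at least 2 neurons")
  if (all(responses == 0)) {
    warning("sparseness undefined for an all-zero response")
    return(NA_real_)
  }
  (1 - (sum(responses) / n)^2 / (sum(responses^2) / n)) / (1 - 1 / n)
}

#' Time-averaged excitation/inhibition balance
#'
#' Presents randomly sampled natural-scene patches and records the
#' incoming excitatory and inhibitory currents of the excitatory
#' population, averaged over the 125 ms window and over repetitions.
#' Pairs are sorted by excitatory current and binned for the balance
#' curve; the summary ratio is mean(I_exc) / mean(I_inh).
#'
#' @param net a trained \code{v1_network}.
#' @param scenes list of \code{\link{whitened_scene}}s.
#' @param n_scenes number of patches (default 1000).
#' @param reps repetitions per patch (default 100).
#' @param n_bins bins for the balance curve.
#' @return List of class \code{ei_result}: \code{ratio} (Inf with
#'   \code{no_inhibition = TRUE} when inhibition is absent),
#'   \code{curve} (binned I_exc vs I_inh, pA), the raw per-(neuron,
#'   stimulus) currents, and the updated \code{net}.
#' @export
ei_ratio <- function(net, scenes, n_scenes = 1000, reps = 100, n_bins = 20) {
  stopifnot(inherits(net, "v1_network"))
  rates <- .sample_block(scenes, n_scenes, net$config)
  all_rates <- rates[, rep(seq_len(n_scenes), each = reps), drop = FALSE]
  r <- present_batch(net, all_rates, plastic = FALSE)
  idx <- rep(seq_len(n_scenes), each = reps)
  mie <- t(apply(r$mean_ie, 1, function(x) tapply(x, idx, mean)))
  mii <- t(apply(r$mean_ii, 1, function(x) tapply(x, idx, mean)))
  no_inh <- all(mii == 0)
  ie <- as.vector(mie); ii <- as.vector(mii)
  o <- order(ie)
  bin <- cut(seq_along(o), n_bins, labels = FALSE)
  curve <- data.frame(
    I_exc = tapply(ie[o], bin, mean),
    I_inh = tapply(ii[o], bin, mean)
  )
  structure(list(
    ratio = if (no_inh) Inf else mean(ie) / mean(ii),
    no_inhibition = no_inh, curve = curve,
    I_exc = mie, I_inh = mii, net = r$net
  ), class = "ei_result")
}

#' Root-mean-square error between z-normalized images
#'
#' Both images are normalized to zero mean and unit variance before
#' the pixelwise RMSE, so the error is invariant to affine rescaling
#' of the reconstruction.
#'
#' @param original,reconstruction numeric matrices of equal size.
#' @return Scalar RMSE; NA with a warning if an image is constant.
#' @export
ire <- function(original, reconstruction) {
  zn <- function(x) {
    s <- sd(as.vector(x))
    if (s == 0) return(NULL)
    (x - mean(x)) / s
  }
  a <- zn(original); b <- zn(reconstruction)
  if (is.null(a) || is.null(b)) {
    warning("IRE undefined for a constant image")
    return(NA_real_)
  }
  sqrt(mean((a - b)^2))
}

#' Linear reconstruction of a scene from population responses
#'
#' Tiles the image into overlapping patches (stride 3), obtains the
#' population response to each patch, reconstructs each patch as the
#' response-weighted sum of receptive fields, and averages overlapping
#' reconstructions.
#'
#' @param image numeric matrix (at least patch-sized).
#' @param respond function(patch_matrix) -> per-neuron response vector.
#' @param rfs n_pixels x n_neurons matrix of (flattened) receptive
#'   fields used as the linear decoder.
#' @param patch_size patch side (default 12).
#' @param stride tiling stride in pixels (default 3).
#' @return Reconstructed image matrix.
#' @export
reconstruct_scene <- function(image, respond, rfs, patch_size = 12,
                              stride = 3) {
  d <- dim(image)
  if (d[1] < patch_size || d[2] < patch_size)
    stop("image is smaller than the patch size")
  acc <- matrix(0, d[1], d[2])
  wgt <- matrix(0, d[1], d[2])
  rows <- unique(c(seq(1, d[1] - patch_size + 1, by = stride),
                   d[1] - patch_size + 1))
  cols <- unique(c(seq(1, d[2] - patch_size + 1, by = stride),
                   d[2] - patch_size + 1))
  for (i in rows) for (j in cols) {
    patch <- image[i:(i + patch_size - 1), j:(j + patch_size - 1)]
    resp <- respond(patch)
    rec <- matrix(rfs %*% resp, patch_size, patch_size)
    acc[i:(i + patch_size - 1), j:(j + patch_size - 1)] <-
      acc[i:(i + patch_size - 1), j:(j + patch_size - 1)] + rec
    wgt[i:(i + patch_size - 1), j:(j + patch_size - 1)] <-
      wgt[i:(i + patch_size - 1), j:(j + patch_size - 1)] + 1
  }
  acc / wgt
}

#' Image reconstruction error of a trained network
#'
#' Presents each overlapping 12x12 patch of a whitened scene
#' \code{reps} times (125 ms each, plasticity off), decodes the scene
#' linearly from the mean spike counts using the ON-minus-OFF
#' feed-forward receptive fields, and returns the RMSE between the
#' z-normalized original and reconstruction.
#'
#' @param net a trained \code{v1_network}.
#' @param scene a \code{\link{whitened_scene}} (normalized pixels are
#'   used as the original image).
#' @param reps presentations per patch (default 50).
#' @param stride tiling stride (default 3).
#' @param r_max input rate scaling (training default 125 Hz).
#' @return List: \code{ire}, \code{reconstruction}, \code{original},
#'   and the updated \code{net}.
#' @export
image_reconstruction_error <- function(net, scene, reps = 50, stride = 3,
                                       r_max = net$config$r_max) {
  stopifnot(inherits(net, "v1_network"), inherits(scene, "whitened_scene"))
  img <- scene$pixels / scene$norm
  ps <- net$config$patch_size
  W <- net$proj$lgn_e$W
  half <- nrow(W) / 2
  rfs <- W[seq_len(half), , drop = FALSE] - W[(half + 1):nrow(W), , drop = FALSE]
  net_env <- new.env()
  net_env$net <- net
  respond <- function(patch) {
    rates <- rates_to_vector(on_off_split(patch, r_max))
    r <- present_batch(net_env$net,
                       matrix(rates, ncol = 1)[, rep(1, reps), drop = FALSE],
                       plastic = FALSE)
    net_env$net <- r$net
    rowMeans(r$counts_e)
  }
  rec <- reconstruct_scene(img, respond, rfs, ps, stride)
  list(ire = ire(img, rec), reconstruction = rec, original = img,
       net = net_env$net)
}

#' Mutual information per spike from repeated stimulus presentations
#'
#' I(s, r) = H(r) - H(r | s) on 125 ms spike counts: the total response
#' entropy of the pooled count distribution minus the mean per-stimulus
#' (noise) entropy, divided by the mean spike count per bin.
#'
#' @param counts n_stimuli x n_reps matrix of spike counts for one
#'   neuron, or a 3-D array (stimuli x reps x neurons).
#' @return For one neuron a list with \code{mi} (bits), \code{H_r},
#'   \code{H_r_given_s}, \code{mean_count} and \code{bits_per_spike};
#'   for an array, a vector of bits/spike per neuron. Neurons with zero
#'   total spikes give NA with a warning.
#' @export
mutual_information_per_spike <- function(counts) {
  if (length(dim(counts)) == 3)
    return(apply(counts, 3, function(m)
      suppressWarnings(mutual_information_per_spike(m)$bits_per_spike)))
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 stimuli")
  entropy <- function(x) {
    p <- tabulate(x + 1L) / length(x)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  if (sum(counts) == 0) {
    warning("information undefined: zero total spikes")
    return(list(mi = NA_real_, H_r = NA_real_, H_r_given_s = NA_real_,
                mean_count = 0, bits_per_spike = NA_real_))
  }
  H_r <- entropy(as.vector(counts))
  H_rs <- mean(apply(counts, 1, entropy))
  mi <- H_r - H_rs
  mc <- mean(counts)
  list(mi = mi, H_r = H_r, H_r_given_s = H_rs, mean_count = mc,
       bits_per_spike = mi / mc)
}

#' Discriminability index d-prime of two response ensembles
#'
#' Projects every repetition of both stimuli onto the difference of
#' the ensemble means and computes
#' d' = (mu_a - mu_b) / (0.5 (sigma_a^2 + sigma_b^2)) of the projected
#' scalars. The denominator uses variances; set
#' \code{conventional = TRUE} for the standard-deviation form.
#'
#' @param responses_a,responses_b n_reps x n_neurons matrices.
#' @param conventional use sd instead of variance in the denominator.
#' @return Scalar d'; NA with a warning when both projected variances
#'   are zero.
#' @export
discriminability <- function(responses_a, responses_b,
                             conventional = FALSE) {
  a <- as.matrix(responses_a); b <- as.matrix(responses_b)
  d <- colMeans(a) - colMeans(b)
  pa <- as.vector(a %*% d); pb <- as.vector(b %*% d)
  va <- var(pa); vb <- var(pb)
  if (va == 0 && vb == 0) {
    if (mean(pa) == mean(pb)) return(0)  # identical deterministic codes
    warning("d' undefined: zero projected variance in both ensembles")
    return(NA_real_)
  }
  denom <- if (conventional) 0.5 * (sqrt(va) + sqrt(vb)) else 0.5 * (va + vb)
  (mean(pa) - mean(pb)) / denom
}

#' Response correlation as a function of receptive-field similarity
#'
#' Computes the Pearson correlation of per-stimulus responses for
#' every neuron pair, bins pairs by the cosine similarity of their
#' feed-forward weight vectors into equal-width bins spanning [-1, 1],
#' and returns the per-bin mean correlation plus the grand mean.
#'
#' @param responses n_neurons x n_stimuli matrix of spike counts.
#' @param weights npre x n_neurons feed-forward weight matrix (columns
#'   are compared for similarity).
#' @param n_bins number of similarity bins (default 30).
#' @return List of class \code{corr_sim_result}: \code{bin_center},
#'   \code{mean_correlation} (per bin; NA for empty bins),
#'   \code{n_pairs} per bin, \code{grand_mean}, and
#'   \code{n_excluded} (pairs dropped for constant-rate neurons).
#' @export
correlation_vs_similarity <- function(responses, weights, n_bins = 30) {
  stopifnot(nrow(responses) >= 2, ncol(responses) >= 2,
            ncol(weights) == nrow(responses))
  n <- nrow(responses)
  keep <- apply(responses, 1, sd) > 0
  cm <- suppressWarnings(cor(t(responses)))
  sm <- rf_similarity_matrix(weights)
  ut <- upper.tri(cm)
  pair_keep <- outer(keep, keep, "&")[ut]
  cors <- cm[ut][pair_keep]
  sims <- sm[ut][pair_keep]
  br <- seq(-1, 1, length.out = n_bins + 1)
  bin <- findInterval(sims, br, rightmost.closed = TRUE)
  f <- factor(bin, levels = seq_len(n_bins))
  structure(list(
    bin_center = (br[-1] + br[-length(br)]) / 2,
    mean_correlation = as.vector(tapply(cors, f, mean)),
    n_pairs = as.vector(table(f)),
    grand_mean = mean(cors),
    n_excluded = sum(!pair_keep)
  ), class = "corr_sim_result")
}

#' Information transmission of a trained network on natural patches
#'
#' Presents randomly sampled patches repeatedly (125 ms each,
#' plasticity off) and computes each excitatory neuron's mutual
#' information per spike between stimulus identity and spike count.
#'
#' @param net a trained \code{v1_network}.
#' @param scenes list of \code{\link{whitened_scene}}s.
#' @param n_stimuli ensemble size (default 500).
#' @param reps repetitions per stimulus (default 100).
#' @return List: \code{bits_per_spike} (per neuron), \code{counts}
#'   (stimuli x reps x neurons array), and the updated \code{net}.
#' @export
measure_information <- function(net, scenes, n_stimuli = 500, reps = 100) {
  stopifnot(inherits(net, "v1_network"))
  rates <- .sample_block(scenes, n_stimuli, net$config)
  r <- present_batch(net, rates[, rep(seq_len(n_stimuli), each = reps),
                                drop = FALSE], plastic = FALSE)
  nE <- nrow(r$counts_e)
  counts <- array(0, c(n_stimuli, reps, nE))
  for (j in seq_len(nE))
    counts[, , j] <- matrix(r$counts_e[j, ], reps, n_stimuli)[, , drop = TRUE] |> t()
  list(bits_per_spike = mutual_information_per_spike(counts),
       counts = counts, net = r$net)
}

#' Pairwise discriminability of natural-patch responses
#'
#' Presents each patch repeatedly and computes the discriminability
#' index d' for randomly chosen stimulus pairs from the population
#' response vectors.
#'
#' @param net a trained \code{v1_network}.
#' @param scenes list of \code{\link{whitened_scene}}s.
#' @param n_stimuli stimulus ensemble size (default 500).
#' @param reps repetitions per stimulus (default 100).
#' @param n_pairs number of random stimulus pairs to evaluate.
#' @return List: \code{d_prime} (per pair, absolute value),
#'   \code{mean_d_prime}, and the updated \code{net}.
#' @export
measure_discriminability <- function(net, scenes, n_stimuli = 500,
                                     reps = 100, n_pairs = 200) {
  stopifnot(inherits(net, "v1_network"))
  rates <- .sample_block(scenes, n_stimuli, net$config)
  r <- present_batch(net, rates[, rep(seq_len(n_stimuli), each = reps),
                                drop = FALSE], plastic = FALSE)
  resp <- function(s)  # reps x neurons matrix for stimulus s
    t(r$counts_e[, (s - 1) * reps + seq_len(reps), drop = FALSE])
  pairs <- matrix(0L, n_pairs, 2)
  for (k in seq_len(n_pairs))
    pairs[k, ] <- sample.int(n_stimuli, 2)
  dp <- vapply(seq_len(n_pairs), function(k)
    suppressWarnings(abs(discriminability(resp(pairs[k, 1]),
                                          resp(pairs[k, 2])))),
    numeric(1))
  list(d_prime = dp, mean_d_prime = mean(dp, na.rm = TRUE), net = r$net)
}
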