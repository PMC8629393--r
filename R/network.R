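# Network assembly, stimulus presentation and training.
#
# A v1_network holds the three populations (LGN 288 = 144 ON + 144 OFF;
# AdEx excitatory and inhibitory at a 4:1 ratio), the five projections
# (LGN->E, LGN->I, E->I, I->E, I->I; all-to-all, no inhibitory
# self-connections), all dynamical state, and the stimulus counter.
# Weight matrices are presynaptic x postsynaptic.

.VARIANTS <- c("EI2/1", "EI3/1", "noInh", "blockInh", "fix_fb_inh", "fix_ff_inh")

#' Network configuration
#'
#' @param variant one of "EI2/1", "EI3/1", "noInh", "blockInh",
#'   "fix_fb_inh", "fix_ff_inh". "EI2/1" and "EI3/1" differ only in the
#'   inhibitory-feedback target constant rho (0.4 vs 0.7); "noInh" has
#'   no inhibitory synapses and reduced excitatory learning rates;
#'   "blockInh" is a trained EI2/1 network with inhibitory transmission
#'   zeroed; the "fix_*" variants freeze specific projections at
#'   shuffled reference weights.
#' @param n_exc,n_inh population sizes (defaults 144 and 36; the 4:1
#'   excitatory:inhibitory ratio must be preserved).
#' @param patch_size side of the input patch; the LGN has
#'   2 * patch_size^2 units.
#' @param presentation_ms stimulus presentation time (default 125 ms).
#' @param r_max firing rate assigned to unit pixel magnitude during
#'   training (default 125 Hz).
#' @param n_stimuli default number of training stimuli (400000 at the
#'   full scale of the reference experiments).
#' @param equalize_every_s interval (simulated seconds) of ON/OFF norm
#'   equalization (default 20 s).
#' @param seed optional integer; stored for provenance (callers are
#'   expected to \code{set.seed} themselves for multi-network
#'   experiments).
#' @param adex optional \code{\link{adex_params}} override.
#' @param istdp_compression factor applied to the inhibitory-STDP
#'   learning rate eta. The inhibitory homeostat is calibrated for the
#'   reference 400,000-stimulus schedule; on a compressed desk-scale
#'   schedule its convergence must be sped up by the compression
#'   factor (e.g. 8 for a 50,000-stimulus run) so that the trained
#'   inhibitory state corresponds to the same point of development.
#' @param scale_synapses when the populations are scaled below the
#'   reference sizes (144 E / 36 I), rescale the recurrent synaptic
#'   bounds and init ranges by the population-size ratio so that the
#'   total recurrent current each neuron can receive is preserved
#'   (the 288 LGN afferents are never scaled). Default TRUE.
#' @return List of class \code{v1_config}.
#' @export
network_config <- function(variant = "EI2/1", n_exc = 144,
                           n_inh = round(n_exc / 4), patch_size = 12,
                           presentation_ms = 125, r_max = 125,
                           n_stimuli = 400000L, equalize_every_s = 20,
                           seed = NULL, adex = adex_params(),
                           istdp_compression = 1,
                           scale_synapses = TRUE) {
  variant <- match.arg(variant, .VARIANTS)
  if (n_inh * 4 != n_exc)
    stop("the 4:1 excitatory:inhibitory ratio must be preserved (got ",
         n_exc, ":", n_inh, ")")
  structure(list(
    variant = variant, n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
    n_lgn = as.integer(2 * patch_size^2), patch_size = as.integer(patch_size),
    dt = 1, presentation_ms = as.integer(presentation_ms), r_max = r_max,
    n_stimuli = as.integer(n_stimuli),
    equalize_every = as.integer(round(equalize_every_s * 1000 / presentation_ms)),
    seed = seed, adex = adex, istdp_compression = istdp_compression,
    syn_scale_e = if (scale_synapses) 144 / n_exc else 1,
    syn_scale_i = if (scale_synapses) 36 / n_inh else 1
  ), class = "v1_config")
}

#' Desk-scale network configuration
#'
#' The reduced study conditions used throughout the package's worked
#' examples and acceptance checks: 36 excitatory / 9 inhibitory
#' neurons (the 4:1 ratio preserved; recurrent synaptic bounds and
#' learning rates rescaled to keep total recurrent current), 50,000
#' training stimuli, and the inhibitory-STDP learning rate compressed
#' by the schedule ratio so the inhibitory state reaches a comparable
#' developmental point to a full 400,000-stimulus run.
#'
#' @param variant model variant.
#' @param n_stimuli training stimuli (default 50000).
#' @param n_exc excitatory population size (default 36).
#' @param ... passed to \code{\link{network_config}}.
#' @return A \code{v1_config}.
#' @export
desk_config <- function(variant = "EI2/1", n_stimuli = 50000L,
                        n_exc = 36L, ...) {
  network_config(variant, n_exc = n_exc, n_stimuli = n_stimuli,
                 istdp_compression = 400000 / n_stimuli, ...)
}

.init_pop_state <- function(n, adex) {
  list(u = rep(adex$E_L, n), vt = rep(adex$VT_rest, n), wad = numeric(n),
       z = numeric(n), ie = numeric(n), ii = numeric(n), clamp = numeric(n),
       ubp = rep(adex$E_L, n), ubm = rep(adex$E_L, n))
}

.shuffle_matrix <- function(w) {
  matrix(sample(as.vector(w)), nrow(w), ncol(w))
}

#' Assemble a network
#'
#' Creates the populations and the five all-to-all projections for the
#' requested variant. Excitatory weights are drawn uniformly from the
#' projection-specific init ranges; inhibitory weights start at zero.
#' For "blockInh" and the "fix_*" variants, \code{reference} must be a
#' trained "EI2/1" network: "blockInh" copies it and zeroes inhibitory
#' transmission; the "fix_*" variants start every projection from a
#' shuffled (entry-permuted) copy of the reference weights -- which
#' preserves each projection's weight-value multiset and hence the
#' average conveyed current -- except LGN->E, which is re-drawn from
#' its init distribution, and freeze the designated projections.
#'
#' @param config a \code{\link{network_config}}.
#' @param reference a trained \code{v1_network} (required for
#'   "blockInh" and "fix_*" variants).
#' @return Object of class \code{v1_network}.
#' @export
build_network <- function(config = network_config(), reference = NULL) {
  stopifnot(inherits(config, "v1_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  v <- config$variant
  if (v %in% c("blockInh", "fix_fb_inh", "fix_ff_inh") && is.null(reference))
    stop("variant '", v, "' requires a trained reference network")

  if (v == "blockInh") {
    net <- reference
    net$config$variant <- "blockInh"
    net$transmit_inh <- FALSE
    for (nm in names(net$proj)) net$proj[[nm]]$params$plastic <- FALSE
    net$state$ii_e <- numeric(net$config$n_exc)
    net$state$ii_i <- numeric(net$config$n_inh)
    return(net)
  }

  has_inh <- v != "noInh"
  adex <- config$adex
  nE <- config$n_exc; nI <- config$n_inh; nL <- config$n_lgn

  draw <- function(pp, npre, npost)
    matrix(runif(npre * npost, pp$w_init[1], pp$w_init[2]), npre, npost)

  # preserve total recurrent current under population scaling: weight
  # bounds, init ranges and learning rates dilate together, so the
  # scaled projection traverses the same current range on the same
  # simulated-time schedule as the reference-size one
  rescale <- function(pp, fac) {
    if (fac == 1) return(pp)
    pp$w_max <- pp$w_max * fac
    if (!is.null(pp$w_init)) pp$w_init <- pp$w_init * fac
    if (!is.null(pp$eta)) pp$eta <- pp$eta * fac
    if (!is.null(pp$A_ltp)) {
      pp$A_ltp <- pp$A_ltp * fac
      pp$A_ltd <- pp$A_ltd * fac
    }
    pp
  }

  proj <- list()
  pp_le <- clopath_params("lgn_e", v)
  proj$lgn_e <- list(W = draw(pp_le, nL, nE), rule = "clopath", params = pp_le)
  if (has_inh) {
    pp_li <- clopath_params("lgn_i", v)
    pp_ei <- rescale(clopath_params("e_i", v), config$syn_scale_e)
    pp_ie <- rescale(istdp_params("i_e", v), config$syn_scale_i)
    pp_ii <- rescale(istdp_params("i_i", v), config$syn_scale_i)
    pp_ie$eta <- pp_ie$eta * config$istdp_compression
    pp_ii$eta <- pp_ii$eta * config$istdp_compression
    proj$lgn_i <- list(W = draw(pp_li, nL, nI), rule = "clopath", params = pp_li)
    proj$e_i <- list(W = draw(pp_ei, nE, nI), rule = "clopath", params = pp_ei)
    proj$i_e <- list(W = matrix(0, nI, nE), rule = "istdp", params = pp_ie)
    W_ii <- matrix(0, nI, nI)
    proj$i_i <- list(W = W_ii, rule = "istdp", params = pp_ii)
  }

  if (v %in% c("fix_fb_inh", "fix_ff_inh")) {
    if (!identical(dim(reference$proj$lgn_e$W), dim(proj$lgn_e$W)))
      stop("reference network has incompatible dimensions")
    for (nm in c("lgn_i", "e_i", "i_e", "i_i"))
      proj[[nm]]$W <- .shuffle_matrix(reference$proj[[nm]]$W)
    # LGN->E is drawn anew from a normal distribution matched to the
    # reference's trained weight moments, so the fresh feed-forward
    # drive is commensurate with the frozen inhibition from the start
    rw <- reference$proj$lgn_e$W
    proj$lgn_e$W <- matrix(
      pmin(pmax(rnorm(nL * nE, mean(rw), sd(rw)), pp_le$w_min), pp_le$w_max),
      nL, nE)
    if (v == "fix_fb_inh") {
      proj$i_e$params$plastic <- FALSE
    } else {
      proj$lgn_i$params$plastic <- FALSE
      proj$e_i$params$plastic <- FALSE
    }
    diag(proj$i_i$W) <- 0
  }

  state <- list()
  se <- .init_pop_state(nE, adex)
  names(se) <- paste0(names(se), "_e")
  state <- c(state, se)
  state$ubb_lgn_e <- numeric(nE)
  state$x_lgn <- numeric(nL)
  state$x_e15 <- numeric(nE)
  state$x_e10 <- numeric(nE)
  state$px_lgn <- integer(nL)
  state$px_e <- integer(nE)
  if (has_inh) {
    si <- .init_pop_state(nI, adex)
    names(si) <- paste0(names(si), "_i")
    state <- c(state, si)
    state$ubb_lgn_i <- numeric(nI)
    state$ubb_e_i <- numeric(nI)
    state$x_i10 <- numeric(nI)
    state$px_i <- integer(nI)
  } else {
    state$px_i <- integer(1)
  }

  structure(list(
    config = config, proj = proj, state = state,
    has_inh = has_inh, transmit_inh = has_inh, stim_count = 0L
  ), class = "v1_network")
}

#' @export
print.v1_network <- function(x, ...) {
  cat("V1 layer-4 network (variant ", x$config$variant, ")\n", sep = "")
  cat("  LGN ", x$config$n_lgn, " | E ", x$config$n_exc,
      " | I ", if (x$has_inh) x$config$n_inh else 0, "\n", sep = "")
  cat("  stimuli seen: ", x$stim_count, "\n", sep = "")
  invisible(x)
}

# flat parameter list consumed by the compiled core
.sim_pars <- function(net, plastic_override = NULL) {
  cfg <- net$config
  pl <- function(p) {
    p$plastic <- isTRUE(p$plastic) &&
      (is.null(plastic_override) || plastic_override)
    p
  }
  pars <- list(
    adex = cfg$adex, dt = cfg$dt, n_lgn = cfg$n_lgn, n_exc = cfg$n_exc,
    n_inh = if (net$has_inh) cfg$n_inh else 0L,
    has_inh = net$has_inh, transmit_inh = net$transmit_inh,
    equalize_every = cfg$equalize_every, stim_count = net$stim_count,
    ubb_subthreshold = isTRUE(net$proj$lgn_e$params$ubb_subthreshold),
    theta_plus = net$proj$lgn_e$params$theta_plus,
    theta_minus = net$proj$lgn_e$params$theta_minus,
    tau_ubb = net$proj$lgn_e$params$tau_ubb,
    tau_x = net$proj$lgn_e$params$tau_x,
    tau_istdp = 10, tau_plus = net$proj$lgn_e$params$tau_plus,
    tau_minus = net$proj$lgn_e$params$tau_minus,
    lgn_e = pl(net$proj$lgn_e$params)
  )
  if (net$has_inh) {
    pars$lgn_i <- pl(net$proj$lgn_i$params)
    pars$e_i <- pl(net$proj$e_i$params)
    pars$i_e <- pl(net$proj$i_e$params)
    pars$i_i <- pl(net$proj$i_i$params)
  }
  pars
}

.sim_weights <- function(net) {
  w <- list(lgn_e = net$proj$lgn_e$W)
  if (net$has_inh) {
    w$lgn_i <- net$proj$lgn_i$W
    w$e_i <- net$proj$e_i$W
    w$i_e <- net$proj$i_e$W
    w$i_i <- net$proj$i_i$W
  }
  w
}

.absorb_result <- function(net, res) {
  net$state <- res$state
  net$proj$lgn_e$W <- res$weights$lgn_e
  if (net$has_inh) {
    net$proj$lgn_i$W <- res$weights$lgn_i
    net$proj$e_i$W <- res$weights$e_i
    net$proj$i_e$W <- res$weights$i_e
    net$proj$i_i$W <- res$weights$i_i
  }
  net$stim_count <- res$stim_count
  net
}

#' Run a batch of stimulus presentations
#'
#' Presents the columns of \code{rates} in order, each for
#' \code{duration} ms, through the compiled clock-driven core. State
#' persists across stimuli (no resets, no blank intervals).
#'
#' @param net a \code{v1_network}.
#' @param rates n_lgn x n_stimuli matrix of LGN rates (Hz), or a single
#'   ON/OFF rate array (one stimulus).
#' @param duration per-stimulus presentation time, ms.
#' @param plastic apply the learning rules (traces always evolve).
#' @param record_detail record per-step spikes, membrane potential and
#'   currents of the excitatory population (memory-heavy; for short
#'   windows).
#' @return List: updated \code{net}, \code{counts_e}/\code{counts_i}
#'   (spike counts per neuron x stimulus), \code{mean_ie}/\code{mean_ii}
#'   (window-averaged synaptic currents, pA), \code{mean_u} (mV), and
#'   when requested the detailed traces.
#' @export
present_batch <- function(net, rates, duration = net$config$presentation_ms,
                          plastic = FALSE, record_detail = FALSE) {
  stopifnot(inherits(net, "v1_network"))
  if (length(dim(rates)) == 3) rates <- rates_to_vector(rates)
  if (is.vector(rates)) rates <- matrix(rates, ncol = 1)
  if (nrow(rates) != net$config$n_lgn)
    stop("rates must have ", net$config$n_lgn, " rows")
  if (duration %% net$config$dt != 0)
    stop("duration must be a multiple of dt")
  res <- .cpp_sim_batch(net$state, .sim_weights(net), .sim_pars(net),
                        rates, as.integer(duration), plastic, record_detail)
  out <- list(net = .absorb_result(net, res),
              counts_e = res$counts_e, counts_i = res$counts_i,
              mean_ie = res$mean_ie, mean_ii = res$mean_ii,
              mean_u = res$mean_u)
  if (record_detail) {
    out$spikes_e <- res$spikes_e
    out$spikes_i <- res$spikes_i
    out$u_trace <- res$u_trace
    out$ie_trace <- res$ie_trace
    out$ii_trace <- res$ii_trace
  }
  out
}

#' Present a single stimulus
#'
#' Convenience wrapper around \code{\link{present_batch}} for one
#' stimulus with detailed recording; returns the spike record as an
#' event table.
#'
#' @inheritParams present_batch
#' @param record observables to return; spike events are always
#'   recorded.
#' @return List with \code{net}, \code{spikes} (data.frame: population,
#'   neuron, time_ms), \code{counts_e}, and the per-step traces
#'   \code{u}, \code{I_exc}, \code{I_inh} (excitatory population).
#' @export
present_stimulus <- function(net, rates, duration = net$config$presentation_ms,
                             plastic = FALSE,
                             record = c("spikes", "currents", "voltage")) {
  r <- present_batch(net, rates, duration, plastic, record_detail = TRUE)
  ev_e <- which(r$spikes_e == 1, arr.ind = TRUE)
  spikes <- data.frame(population = rep("E", nrow(ev_e)),
                       neuron = ev_e[, 1], time_ms = ev_e[, 2])
  if (net$has_inh && length(r$spikes_i)) {
    ev_i <- which(r$spikes_i == 1, arr.ind = TRUE)
    spikes <- rbind(spikes, data.frame(population = rep("I", nrow(ev_i)),
                                       neuron = ev_i[, 1], time_ms = ev_i[, 2]))
  }
  spikes <- spikes[order(spikes$time_ms, spikes$population, spikes$neuron), ]
  rownames(spikes) <- NULL
  list(net = r$net, spikes = spikes, counts_e = r$counts_e,
       u = r$u_trace, I_exc = r$ie_trace, I_inh = r$ii_trace)
}

#' Zero inhibitory transmission in a trained network
#'
#' Returns a copy of the network with inhibitory currents disabled and
#' all plasticity off (the "blockInh" manipulation). Feed-forward
#' weights are shared with the input network by construction.
#'
#' @param net a trained \code{v1_network}.
#' @return Modified copy.
#' @export
block_inhibition <- function(net) {
  stopifnot(inherits(net, "v1_network"))
  net$config$variant <- "blockInh"
  net$transmit_inh <- FALSE
  for (nm in names(net$proj)) net$proj[[nm]]$params$plastic <- FALSE
  net$state$ii_e <- numeric(net$config$n_exc)
  if (net$has_inh) net$state$ii_i <- numeric(net$config$n_inh)
  net
}

#' Train a network on patches from whitened scenes
#'
#' Runs \code{n_stimuli} presentations (125 ms each) with plasticity
#' on. Each stimulus is a randomly sampled, randomly flipped 12x12
#' patch from a randomly chosen scene, converted to ON/OFF rates with
#' the training \code{r_max}. The ON/OFF norm equalization runs every
#' 20 s of simulated time. The training log records, per block, the
#' mean absolute LGN->E weight change, the fraction of LGN->E weights
#' at the upper bound, and (when a probe set is supplied) the mean
#' pairwise response correlation of the excitatory population on the
#' held-out probes.
#'
#' @param net a \code{v1_network}.
#' @param scenes list of \code{\link{whitened_scene}} objects.
#' @param n_stimuli number of training presentations.
#' @param block_size stimuli per compiled batch / log row (default 1000).
#' @param probe_rates optional n_lgn x n_probe matrix of probe stimuli
#'   for the response-correlation log (presented with plasticity off).
#' @param probe_every probe interval in blocks (default 5).
#' @param checkpoint_every optional interval in stimuli (rounded to
#'   blocks) at which full checkpoints are written.
#' @param checkpoint_dir directory for checkpoints.
#' @param verbose print block-level progress with simulated-time stamps.
#' @return List: \code{net} (trained) and \code{log} (data.frame).
#' @export
train <- function(net, scenes, n_stimuli = net$config$n_stimuli,
                  block_size = 1000L, probe_rates = NULL, probe_every = 5L,
                  checkpoint_every = NULL, checkpoint_dir = tempdir(),
                  verbose = FALSE) {
  stopifnot(inherits(net, "v1_network"))
  if (inherits(scenes, "whitened_scene")) scenes <- list(scenes)
  if (n_stimuli == 0)
    return(list(net = net, log = data.frame()))
  n_blocks <- ceiling(n_stimuli / block_size)
  ckpt_blocks <- if (!is.null(checkpoint_every))
    max(1L, round(checkpoint_every / block_size)) else NA_integer_
  log <- vector("list", n_blocks)
  done <- 0L
  for (b in seq_len(n_blocks)) {
    nb <- min(block_size, n_stimuli - done)
    rates <- .sample_block(scenes, nb, net$config)
    w_before <- net$proj$lgn_e$W
    r <- present_batch(net, rates, plastic = TRUE)
    net <- r$net
    done <- done + nb
    pct_max <- mean(net$proj$lgn_e$W >=
                      net$proj$lgn_e$params$w_max - 1e-9)
    if (pct_max > 0.99)
      stop("runaway weights: >99% of LGN->E weights at the upper bound")
    corr <- NA_real_
    if (!is.null(probe_rates) && (b %% probe_every == 0 || b == n_blocks)) {
      pr <- present_batch(net, probe_rates, plastic = FALSE)
      net <- pr$net
      corr <- mean_pairwise_correlation(pr$counts_e)
    }
    log[[b]] <- data.frame(
      block = b, stimuli = done,
      sim_time_s = done * net$config$presentation_ms / 1000,
      mean_abs_dw = mean(abs(net$proj$lgn_e$W - w_before)),
      frac_at_max = pct_max, mean_corr = corr
    )
    if (verbose)
      message(sprintf("[%8.1f s simulated] block %d/%d  |dW|=%.3e  corr=%s",
                      done * net$config$presentation_ms / 1000, b, n_blocks,
                      log[[b]]$mean_abs_dw,
                      ifelse(is.na(corr), "-", sprintf("%.3f", corr))))
    if (!is.na(ckpt_blocks) && b %% ckpt_blocks == 0)
      save_checkpoint(net, file.path(checkpoint_dir,
                                     sprintf("checkpoint_%07d.rds", done)))
  }
  list(net = net, log = do.call(rbind, log))
}

# sample a block of training stimuli as an LGN rate matrix
.sample_block <- function(scenes, n, cfg) {
  rates <- matrix(0, cfg$n_lgn, n)
  ns <- length(scenes)
  for (k in seq_len(n)) {
    sc <- scenes[[if (ns == 1) 1L else 1L + floor(runif(1) * ns)]]
    patch <- sample_patch(sc, size = cfg$patch_size)
    rates[, k] <- rates_to_vector(on_off_split(patch, cfg$r_max))
  }
  rates
}

#' Mean pairwise response correlation
#'
#' Pearson correlation of per-stimulus response vectors for every
#' neuron pair, averaged; neurons with constant responses are excluded.
#'
#' @param counts n_neurons x n_stimuli matrix of spike counts.
#' @return Scalar (NA if fewer than two non-constant neurons).
#' @export
mean_pairwise_correlation <- function(counts) {
  keep <- apply(counts, 1, sd) > 0
  if (sum(keep) < 2) return(NA_real_)
  cm <- cor(t(counts[keep, , drop = FALSE]))
  mean(cm[upper.tri(cm)])
}

#' Save / load a network checkpoint
#'
#' Checkpoints contain the full network (weights, state, configuration,
#' stimulus counter) and the R random-number-generator state, so that
#' restore-and-continue is bit-identical to an uninterrupted run.
#'
#' @param net a \code{v1_network}.
#' @param path file path (.rds).
#' @return \code{save_checkpoint}: the path, invisibly;
#'   \code{load_checkpoint}: the restored network (the RNG state is
#'   restored as a side effect).
#' @export
save_checkpoint <- function(net, path) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(net = net, rng = rng, format = 1L), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!is.null(x$rng))
    assign(".Random.seed", x$rng, envir = globalenv())
  x$net
}
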