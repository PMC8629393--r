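# Learning rules: voltage-based triplet STDP (excitatory synapses) and
# symmetric homeostatic iSTDP (inhibitory synapses), plus ON/OFF norm
# equalization. Weight matrices are presynaptic x postsynaptic.

#' Low-pass voltage trace update
#'
#' Forward-Euler update of tau * dv/dt = -v + u.
#'
#' @param v trace vector (mV).
#' @param u current membrane potential vector (mV).
#' @param tau time constant, ms.
#' @param dt step, ms.
#' @return Updated trace.
#' @export
update_voltage_trace <- function(v, u, tau, dt = 1) {
  v + dt / tau * (u - v)
}

#' Slow homeostatic depolarization trace update
#'
#' Forward-Euler update of tau_ubb * d(ubb)/dt = ((u - E_L)_+)^2 - ubb.
#' The membrane potential includes the 29-mV spike plateau, so the
#' trace rises both with sustained subthreshold depolarization and
#' with firing rate, making the LTD scale a fast brake on activity
#' surges.
#'
#' @param ubb trace vector (mV^2).
#' @param u membrane potential vector (mV).
#' @param E_L resting potential (mV).
#' @param tau time constant (ms, default 750).
#' @param dt step, ms.
#' @return Updated trace.
#' @export
update_ubb_trace <- function(ubb, u, E_L = -70.6, tau = 750, dt = 1) {
  ubb + dt / tau * (pmax(u - E_L, 0)^2 - ubb)
}

#' One step of the voltage-based triplet STDP rule
#'
#' For each synapse i -> j:
#' \deqn{dw = A_{LTP} \bar{x}_i (u_j-\theta_+)_+ (\bar{u}^+_j-\theta_-)_+
#'   - A_{LTD} (\bar{\bar{u}}_j/u_{ref}) X_i (\bar{u}^-_j-\theta_-)_+}
#' integrated over dt and clipped to [w_min, w_max]. The voltage traces
#' are assumed already updated to the current step; \code{u_bar_bar} is
#' the pre-update slow trace.
#'
#' @param weights npre x npost matrix.
#' @param x_bar presynaptic spike traces (length npre).
#' @param pre_spikes 0/1 indicator vector (length npre).
#' @param u_post postsynaptic membrane potentials (length npost), mV.
#' @param u_bar_plus,u_bar_minus postsynaptic voltage traces, mV.
#' @param u_bar_bar slow squared-depolarization trace, mV^2.
#' @param params a \code{\link{clopath_params}} list.
#' @param dt step, ms.
#' @return Updated, clipped weight matrix.
#' @export
clopath_update <- function(weights, x_bar, pre_spikes, u_post,
                           u_bar_plus, u_bar_minus, u_bar_bar,
                           params, dt = 1) {
  if (params$u_ref <= 0) stop("u_ref must be positive")
  # x_scale normalizes the unit-jump presynaptic trace to the
  # per-spike contribution dt/tau_x the learning rates are calibrated for
  ltp_gate <- params$A_ltp * params$x_scale *
    pmax(u_post - params$theta_plus, 0) *
    pmax(u_bar_plus - params$theta_minus, 0) * dt
  ltd_gate <- params$A_ltd * params$ltd_scale * (u_bar_bar / params$u_ref) *
    pmax(u_bar_minus - params$theta_minus, 0) * dt
  # LTP first (clip at the upper bound), then LTD on presynaptic spike
  # rows (clip at the lower bound) -- the same sequence as the compiled
  # core, so saturating weights behave identically
  w <- weights + outer(x_bar, ltp_gate)
  w[w > params$w_max] <- params$w_max
  w <- w - outer(as.numeric(pre_spikes), ltd_gate)
  w[w < params$w_min] <- params$w_min
  w
}

#' One step of the symmetric homeostatic inhibitory STDP rule
#'
#' On each presynaptic spike, w += eta * (x_post - rho); on each
#' postsynaptic spike, w += eta * x_pre. Near-coincident pre/post
#' spiking potentiates regardless of order; isolated presynaptic spikes
#' depress. Weights are clipped to [w_min, w_max] after the update.
#'
#' @param weights npre x npost matrix.
#' @param x_pre,x_post pre-/postsynaptic spike traces (tau = 10 ms,
#'   unit jump), already updated to the current step.
#' @param pre_spikes,post_spikes 0/1 indicator vectors.
#' @param params an \code{\link{istdp_params}} list.
#' @param skip_diagonal exclude self-connections (for the recurrent
#'   inhibitory projection).
#' @return Updated, clipped weight matrix.
#' @export
istdp_update <- function(weights, x_pre, x_post, pre_spikes, post_spikes,
                         params, skip_diagonal = FALSE) {
  clip <- function(w) {
    w[w < params$w_min] <- params$w_min
    w[w > params$w_max] <- params$w_max
    w
  }
  dw_pre <- outer(as.numeric(pre_spikes), params$eta * (x_post - params$rho))
  if (skip_diagonal) diag(dw_pre) <- 0
  w <- clip(weights + dw_pre)
  dw_post <- outer(params$eta * x_pre, as.numeric(post_spikes))
  if (skip_diagonal) diag(dw_post) <- 0
  clip(w + dw_post)
}

#' Equalize ON and OFF weight norms per postsynaptic neuron
#'
#' For an LGN-afferent matrix (rows: 144 ON units then 144 OFF units),
#' rescales each postsynaptic neuron's OFF weights so their Euclidean
#' norm equals the ON norm; ON weights are unchanged. Applied every
#' 20 s of simulated training time to remove ON/OFF drift.
#'
#' @param weights npre x npost matrix with an even number of rows; the
#'   first half are ON weights.
#' @return Rescaled matrix.
#' @export
equalize_on_off <- function(weights) {
  npre <- nrow(weights)
  if (npre %% 2 != 0) stop("weight matrix must have an even number of rows")
  half <- npre / 2
  on_n <- sqrt(colSums(weights[seq_len(half), , drop = FALSE]^2))
  off_n <- sqrt(colSums(weights[(half + 1):npre, , drop = FALSE]^2))
  scale <- ifelse(off_n > 0 & on_n > 0, on_n / off_n, NA_real_)
  if (anyNA(scale)) {
    bad <- sum(is.na(scale) & on_n > 0)
    if (bad > 0)
      warning(bad, " neuron(s) with zero OFF norm and nonzero ON norm; skipped")
    scale[is.na(scale)] <- 1
  }
  weights[(half + 1):npre, ] <-
    sweep(weights[(half + 1):npre, , drop = FALSE], 2, scale, "*")
  weights
}
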