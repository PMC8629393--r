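# Adaptive exponential integrate-and-fire population dynamics (R surface;
# the training loop runs the same update compiled).

#' Initialize AdEx population state at rest
#'
#' @param n number of neurons.
#' @param params an \code{\link{adex_params}} list.
#' @return List of state vectors: membrane potential \code{u} (mV),
#'   adaptive threshold \code{vt} (mV), adaptation current \code{wad}
#'   (pA), afterpotential \code{z} (pA), synaptic currents \code{ie},
#'   \code{ii} (pA), and \code{clamp} (ms remaining in the post-spike
#'   plateau).
#' @export
adex_init <- function(n, params = adex_params()) {
  list(
    u = rep(params$E_L, n), vt = rep(params$VT_rest, n),
    wad = numeric(n), z = numeric(n),
    ie = numeric(n), ii = numeric(n), clamp = numeric(n)
  )
}

#' Advance an AdEx population by one time step
#'
#' Synaptic currents decay by the Euler factor (1 - dt/tau) and are
#' incremented by the summed afferent weights of last-step spikes,
#' scaled by C/tau_syn so that a weight-w event approximates a w-mV
#' voltage pulse. The membrane potential is integrated by forward
#' Euler; the adaptive threshold, afterpotential and adaptation current
#' evolve alongside. On threshold crossing (u > V_T) the membrane is
#' clamped at 29 mV for 2 ms and then reset to E_L; V_T jumps to
#' VT_max, z to I_sp, and the adaptation current is incremented by b.
#'
#' @param state list from \code{\link{adex_init}}.
#' @param params an \code{\link{adex_params}} list.
#' @param exc_input summed presynaptic weight of excitatory afferents
#'   that spiked in the previous step (vector or scalar).
#' @param inh_input same for inhibitory afferents (enters with negative
#'   sign).
#' @param I_ext additional injected current, pA (for protocols such as
#'   f-I curves; default 0).
#' @param dt time step, ms (default 1).
#' @return List with \code{spiked} (logical vector) and \code{state}.
#' @export
adex_step <- function(state, params = adex_params(), exc_input = 0,
                      inh_input = 0, I_ext = 0, dt = 1) {
  if (!all(vapply(state, function(v) all(is.finite(v)), logical(1))))
    stop("non-finite AdEx state: u = ", paste(signif(state$u, 4), collapse = ", "))
  n <- length(state$u)
  p <- params
  # synaptic currents from last-step afferent spikes (pulse normalization)
  state$ie <- state$ie * (1 - dt / p$tau_Iexc) +
    exc_input * p$syn_gain * p$C / p$tau_Iexc
  state$ii <- state$ii * (1 - dt / p$tau_Iinh) +
    inh_input * p$syn_gain * p$C / p$tau_Iinh

  state$vt <- p$VT_rest + (state$vt - p$VT_rest) * exp(-dt / p$tau_VT)
  state$z <- state$z * exp(-dt / p$tau_z)
  state$wad <- state$wad + dt / p$tau_wad * (p$a * (state$u - p$E_L) - state$wad)

  spiked <- logical(n)
  clamped <- state$clamp > 0
  if (any(clamped)) {
    state$clamp[clamped] <- state$clamp[clamped] - dt
    done <- clamped & state$clamp <= 0
    state$u[done] <- p$E_L
  }
  free <- !clamped
  if (any(free)) {
    ex <- pmin((state$u[free] - state$vt[free]) / p$Delta_T, 20)
    du <- dt / p$C * (
      -p$g_L * (state$u[free] - p$E_L) + p$g_L * p$Delta_T * exp(ex) -
        state$wad[free] + state$z[free] + state$ie[free] - state$ii[free] +
        (if (length(I_ext) == 1) I_ext else I_ext[free])
    )
    u_new <- state$u[free] + du
    fired <- u_new > state$vt[free]
    u_new[fired] <- p$u_spike
    state$u[free] <- u_new
    idx <- which(free)[fired]
    spiked[idx] <- TRUE
    state$clamp[idx] <- p$clamp_ms
    state$vt[idx] <- p$VT_max
    state$z[idx] <- p$I_sp
    state$wad[idx] <- state$wad[idx] + p$b
  }
  list(spiked = spiked, state = state)
}
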