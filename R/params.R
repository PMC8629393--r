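#' Adaptive exponential integrate-and-fire neuron parameters
#'
#' Default values are the standard parameter set for the voltage-STDP
#' cortical neuron: C = 281 pF, g_L = 30 nS, E_L = -70.6 mV, Delta_T =
#' 2 mV, resting threshold -50.4 mV, threshold time constant 50 ms,
#' afterpotential reset 400 pA (tau 40 ms), adaptation a = 4 nS,
#' b = 0.805 pA (tau 144 ms). Synaptic currents are current-based with
#' tau_Iexc = 1 ms and tau_Iinh = 10 ms; each presynaptic spike through
#' weight w delivers total charge w*C, i.e. approximates a w-mV voltage
#' pulse. After a spike the membrane is clamped at 29 mV for 2 ms, then
#' reset to E_L.
#'
#' @param VT_max spike-threshold reset value after a spike (mV). The
#'   threshold decays from this value back to \code{VT_rest} with
#'   \code{tau_VT}. Default -30.4 mV; with a reset far above the
#'   reachable voltage range the post-spike threshold never re-enters it
#'   on a useful time scale and sustained firing is impossible.
#' @param syn_gain peak membrane depolarization (mV) delivered by one
#'   presynaptic spike through a synapse of unit weight: the synaptic
#'   current increment is \code{syn_gain * w * C / tau_syn} pA. This
#'   sets the overall coupling scale of the current-based
#'   approximation of pulse input. The default (0.7) is calibrated so
#'   that the network reproduces the three dynamical regimes of the
#'   plasticity model: a quiet, slowly potentiating developing state,
#'   a trained state at the homeostatic depolarization set point, and
#'   a saturated all-weights-high state in which depression dominates
#'   (i.e. saturation is self-correcting rather than absorbing).
#' @param ... overrides for any other parameter listed above.
#' @return A named list of class \code{adex_params}.
#' @export
adex_params <- function(VT_max = -30.4, syn_gain = 0.7, ...) {
  p <- list(
    C = 281, g_L = 30, E_L = -70.6, Delta_T = 2,
    VT_rest = -50.4, VT_max = VT_max, tau_VT = 50,
    tau_z = 40, tau_wad = 144, I_sp = 400, a = 4, b = 0.805,
    tau_Iexc = 1, tau_Iinh = 10, u_spike = 29, clamp_ms = 2L,
    syn_gain = syn_gain
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown adex parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  taus <- c("tau_VT", "tau_z", "tau_wad", "tau_Iexc", "tau_Iinh")
  if (any(unlist(p[taus]) <= 0)) stop("time constants must be positive")
  structure(p, class = "adex_params")
}

#' Voltage-based triplet STDP parameters for one excitatory projection
#'
#' Per-projection learning rates, homeostatic reference and weight
#' bounds for the three excitatory projections (LGN to E, LGN to I,
#' E to I). Shared constants: theta_plus = -45.3 mV, theta_minus =
#' -70.6 mV, tau_plus = 7 ms, tau_minus = 10 ms, presynaptic trace
#' tau_x = 15 ms, slow homeostatic trace tau_ubb = 750 ms.
#'
#' The \code{noInh} variant uses reduced LGN-to-E learning rates
#' (7.2e-5 / 5.6e-5) compensating the higher firing rates in the
#' absence of inhibition.
#'
#' @param projection one of "lgn_e", "lgn_i", "e_i".
#' @param variant model variant name (affects lgn_e rates for "noInh").
#' @param ... overrides.
#' @return A named list of class \code{clopath_params}.
#' @export
clopath_params <- function(projection = c("lgn_e", "lgn_i", "e_i"),
                           variant = "EI2/1", ...) {
  projection <- match.arg(projection)
  base <- switch(projection,
    lgn_e = list(A_ltp = 1.35e-4, A_ltd = 1.05e-4, u_ref = 60,
                 w_min = 0, w_max = 5.0, w_init = c(0.015, 2.0)),
    lgn_i = list(A_ltp = 5.4e-5, A_ltd = 4.2e-5, u_ref = 55,
                 w_min = 0, w_max = 3.0, w_init = c(0.0175, 2.15)),
    e_i   = list(A_ltp = 1.2e-5, A_ltd = 1.4e-5, u_ref = 55,
                 w_min = 0, w_max = 1.0, w_init = c(0.0175, 0.25))
  )
  if (projection == "lgn_e" && identical(variant, "noInh")) {
    base$A_ltp <- 7.2e-5
    base$A_ltd <- 5.6e-5
  }
  p <- c(base, list(
    theta_plus = -45.3, theta_minus = -70.6,
    tau_plus = 7, tau_minus = 10, tau_x = 15, tau_ubb = 750,
    x_scale = 1 / 15, ltd_scale = 2.8, ubb_subthreshold = FALSE,
    plastic = TRUE
  ))
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown clopath parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  if (p$u_ref <= 0) stop("u_ref must be positive")
  if (p$A_ltp < 0 || p$A_ltd < 0) stop("learning rates must be nonnegative")
  structure(p, class = "clopath_params")
}

#' Symmetric homeostatic inhibitory STDP parameters
#'
#' Learning rate eta = 1e-5, pre/post spike-trace time constant 10 ms,
#' weights initialized at 0 and bounded in [0, w_max] (0.7 for I-to-E,
#' 0.5 for I-to-I). The target constant rho controls the postsynaptic
#' rate the rule converges to: rho = 0.4 for I-to-E in the EI2/1
#' variant, 0.7 in EI3/1; rho = 0.6 for I-to-I in both.
#'
#' @param projection one of "i_e", "i_i".
#' @param variant model variant name (affects rho for "i_e").
#' @param ... overrides.
#' @return A named list of class \code{istdp_params}.
#' @export
istdp_params <- function(projection = c("i_e", "i_i"),
                         variant = "EI2/1", ...) {
  projection <- match.arg(projection)
  rho <- if (projection == "i_e") {
    if (identical(variant, "EI3/1")) 0.7 else 0.4
  } else 0.6
  p <- list(
    eta = 1e-5, rho = rho, tau_pre = 10, tau_post = 10,
    w_min = 0, w_max = if (projection == "i_e") 0.7 else 0.5,
    plastic = TRUE
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown istdp parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  structure(p, class = "istdp_params")
}
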