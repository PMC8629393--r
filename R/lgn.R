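# Poisson LGN front end: rate maps -> spike indicators + presynaptic traces.

#' Initialize LGN population state
#'
#' @param n number of units (default 288 = 144 ON + 144 OFF).
#' @return List with \code{x_trace} (presynaptic spike traces, unitless)
#'   and \code{X} (spike indicators of the last step).
#' @export
lgn_init <- function(n = 288) {
  list(x_trace = numeric(n), X = integer(n))
}

#' Advance the LGN Poisson population by one time step
#'
#' Each unit spikes with probability rate * dt (Poisson thinning at
#' 1 ms resolution; probabilities above 1 are clipped with a warning).
#' On a spike the presynaptic trace jumps by 1; otherwise it decays
#' exponentially with tau_x = 15 ms. One uniform draw is consumed per
#' unit per step, in unit order, so results are reproducible under a
#' fixed seed and identical to the compiled network core.
#'
#' @param state list from \code{\link{lgn_init}}.
#' @param rates nonnegative rate vector (Hz), one per unit, or an
#'   ON/OFF rate array (flattened via \code{\link{rates_to_vector}}).
#' @param dt time step in ms (default 1).
#' @param tau_x spike-trace time constant, ms.
#' @return List with \code{spikes} (0/1 integer vector) and
#'   \code{state} (updated).
#' @export
lgn_step <- function(state, rates, dt = 1, tau_x = 15) {
  if (length(dim(rates)) == 3) rates <- rates_to_vector(rates)
  if (any(rates < 0)) stop("rates must be nonnegative")
  p <- rates * dt / 1000
  if (any(p > 1)) {
    warning("rate * dt exceeds 1; spike probability clipped")
    p <- pmin(p, 1)
  }
  X <- as.integer(runif(length(p)) < p)
  state$x_trace <- state$x_trace * exp(-dt / tau_x) + X
  state$X <- X
  list(spikes = X, state = state)
}

#' Exponential spike-trace update (unit jump convention)
#'
#' The exact solution of a first-order trace driven by unit-area
#' impulses: decay by exp(-dt/tau), then add 1 per spike.
#'
#' @param x trace vector.
#' @param spikes 0/1 indicator vector.
#' @param tau time constant, ms.
#' @param dt step, ms.
#' @return Updated trace vector.
#' @export
update_spike_trace <- function(x, spikes, tau, dt = 1) {
  x * exp(-dt / tau) + spikes
}
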