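# Independent oracles: fine-timestep AdEx integrator, scalar plasticity
# reference, and an R-composed network loop that must match the
# compiled core bit for bit.

# Fine-step forward-Euler integration of the AdEx equations, written
# directly from the model definition (independent of adex_step).
# Returns the first-spike latency (ms) from rest under constant
# injected current.
adex_latency_oracle <- function(I_ext, p = adex_params(), dt = 0.01,
                                t_max = 500) {
  u <- p$E_L; vt <- p$VT_rest; wad <- 0; z <- 0
  steps <- ceiling(t_max / dt)
  for (k in seq_len(steps)) {
    vt <- p$VT_rest + (vt - p$VT_rest) * exp(-dt / p$tau_VT)
    z <- z * exp(-dt / p$tau_z)
    wad <- wad + dt / p$tau_wad * (p$a * (u - p$E_L) - wad)
    ex <- min((u - vt) / p$Delta_T, 20)
    u <- u + dt / p$C * (-p$g_L * (u - p$E_L) +
                           p$g_L * p$Delta_T * exp(ex) - wad + z + I_ext)
    if (u > vt) return(k * dt)
  }
  NA_real_
}

# Scalar step-by-step reference of the voltage-STDP weight change for a
# single synapse driven by prescribed pre-spike times and a prescribed
# postsynaptic voltage sequence. Every quantity is tracked with plain
# scalar arithmetic.
clopath_scalar_oracle <- function(pre_spikes, u_seq, pp, dt = 1,
                                  w0 = 1, E_L = -70.6) {
  w <- w0; xbar <- 0; ubp <- E_L; ubm <- E_L; ubb <- 0
  n <- length(u_seq)
  for (t in seq_len(n)) {
    u <- u_seq[t]
    xbar <- xbar * exp(-dt / pp$tau_x) + pre_spikes[t]
    ubp <- ubp + dt / pp$tau_plus * (u - ubp)
    ubm <- ubm + dt / pp$tau_minus * (u - ubm)
    ltp <- pp$A_ltp * pp$x_scale * xbar *
      max(u - pp$theta_plus, 0) * max(ubp - pp$theta_minus, 0) * dt
    w <- min(w + ltp, pp$w_max)
    if (pre_spikes[t] == 1) {
      ltd <- pp$A_ltd * pp$ltd_scale * (ubb / pp$u_ref) *
        max(ubm - pp$theta_minus, 0) * dt
      w <- max(w - ltd, pp$w_min)
    }
    ubb <- ubb + dt / pp$tau_ubb * (max(u - E_L, 0)^2 - ubb)
  }
  w
}

# Pre-before-post pairing protocol driven through the AdEx neuron:
# returns the postsynaptic voltage sequence and pre-spike train so the
# same history can feed both the package rule and the scalar oracle.
pairing_protocol <- function(n_pairs = 20, pair_hz = 20, delta_ms = 10,
                             p = adex_params()) {
  period <- round(1000 / pair_hz)
  n <- n_pairs * period + 50
  pre <- integer(n)
  force_at <- integer(n)
  for (k in seq_len(n_pairs)) {
    t0 <- (k - 1) * period + 10
    pre[t0] <- 1L
    force_at[t0 + delta_ms] <- 1L
  }
  st <- adex_init(1, p)
  u_seq <- numeric(n)
  for (t in seq_len(n)) {
    r <- adex_step(st, p, I_ext = if (force_at[t]) 5e4 else 0)
    st <- r$state
    u_seq[t] <- st$u
  }
  list(pre = pre, u = u_seq)
}

# Toy homeostatic circuit: one AdEx neuron with constant excitatory
# drive and one plastic inhibitory afferent firing Poisson at rate_hz.
# Returns the firing rate over the final fifth of the run and the
# final weight.
istdp_toy_circuit <- function(rho, rate_hz = 200, I_drive = 900,
                              eta = 0.01, w_max = 1000, sim_ms = 150000,
                              p = adex_params()) {
  pp <- istdp_params("i_e", rho = rho, eta = eta, w_max = w_max)
  st <- adex_init(1, p)
  w <- 0; x_pre <- 0; x_post <- 0
  spikes <- integer(sim_ms)
  pre_prev <- 0L
  for (t in seq_len(sim_ms)) {
    pre <- as.integer(runif(1) < rate_hz / 1000)
    r <- adex_step(st, p, exc_input = 0, inh_input = w * pre_prev,
                   I_ext = I_drive)
    st <- r$state
    post <- as.integer(r$spiked)
    x_pre <- update_spike_trace(x_pre, pre, pp$tau_pre)
    x_post <- update_spike_trace(x_post, post, pp$tau_post)
    w <- istdp_update(matrix(w, 1, 1), x_pre, x_post, pre, post, pp)[1, 1]
    spikes[t] <- post
    pre_prev <- pre
  }
  tail_idx <- seq(round(0.6 * sim_ms), sim_ms)
  list(rate = 1000 * mean(spikes[tail_idx]), w = w)
}

# R-composed network loop built from the exported step functions; must
# reproduce the compiled core exactly (same RNG consumption order).
r_network_loop <- function(net, rates_mat, duration) {
  cfg <- net$config; adex <- cfg$adex
  st <- net$state
  W <- lapply(net$proj, function(p) p$W)
  pp <- lapply(net$proj, function(p) p$params)
  counts_e <- matrix(0, cfg$n_exc, ncol(rates_mat))
  eS <- list(u = st$u_e, vt = st$vt_e, wad = st$wad_e, z = st$z_e,
             ie = st$ie_e, ii = st$ii_e, clamp = st$clamp_e)
  iS <- list(u = st$u_i, vt = st$vt_i, wad = st$wad_i, z = st$z_i,
             ie = st$ie_i, ii = st$ii_i, clamp = st$clamp_i)
  ubp_e <- st$ubp_e; ubm_e <- st$ubm_e; ubb_lgn_e <- st$ubb_lgn_e
  ubp_i <- st$ubp_i; ubm_i <- st$ubm_i
  ubb_lgn_i <- st$ubb_lgn_i; ubb_e_i <- st$ubb_e_i
  x_e15 <- st$x_e15; x_e10 <- st$x_e10; x_i10 <- st$x_i10
  lgn <- list(x_trace = st$x_lgn, X = st$px_lgn)
  pxL <- st$px_lgn; pxE <- st$px_e; pxI <- st$px_i
  stim_count <- net$stim_count
  for (s in seq_len(ncol(rates_mat))) {
    for (t in seq_len(duration)) {
      l <- lgn_step(lgn, rates_mat[, s])
      lgn <- l$state; XL <- l$spikes
      ae <- adex_step(eS, adex, as.vector(crossprod(W$lgn_e, pxL)),
                      as.vector(crossprod(W$i_e, pxI)))
      eS <- ae$state; XE <- as.integer(ae$spiked)
      ai <- adex_step(iS, adex,
                      as.vector(crossprod(W$lgn_i, pxL)) +
                        as.vector(crossprod(W$e_i, pxE)),
                      as.vector(crossprod(W$i_i, pxI)))
      iS <- ai$state; XI <- as.integer(ai$spiked)
      x_e15 <- update_spike_trace(x_e15, XE, 15)
      x_e10 <- update_spike_trace(x_e10, XE, 10)
      x_i10 <- update_spike_trace(x_i10, XI, 10)
      ubp_e <- update_voltage_trace(ubp_e, eS$u, 7)
      ubm_e <- update_voltage_trace(ubm_e, eS$u, 10)
      ubp_i <- update_voltage_trace(ubp_i, iS$u, 7)
      ubm_i <- update_voltage_trace(ubm_i, iS$u, 10)
      W$lgn_e <- clopath_update(W$lgn_e, lgn$x_trace, XL, eS$u, ubp_e,
                                ubm_e, ubb_lgn_e, pp$lgn_e)
      W$lgn_i <- clopath_update(W$lgn_i, lgn$x_trace, XL, iS$u, ubp_i,
                                ubm_i, ubb_lgn_i, pp$lgn_i)
      W$e_i <- clopath_update(W$e_i, x_e15, XE, iS$u, ubp_i, ubm_i,
                              ubb_e_i, pp$e_i)
      W$i_e <- istdp_update(W$i_e, x_i10, x_e10, XI, XE, pp$i_e)
      W$i_i <- istdp_update(W$i_i, x_i10, x_i10, XI, XI, pp$i_i,
                            skip_diagonal = TRUE)
      ubb_lgn_e <- update_ubb_trace(ubb_lgn_e, eS$u)
      ubb_lgn_i <- update_ubb_trace(ubb_lgn_i, iS$u)
      ubb_e_i <- update_ubb_trace(ubb_e_i, iS$u)
      counts_e[, s] <- counts_e[, s] + XE
      pxL <- XL; pxE <- XE; pxI <- XI
    }
    stim_count <- stim_count + 1
    if (stim_count %% cfg$equalize_every == 0) {
      W$lgn_e <- equalize_on_off(W$lgn_e)
      W$lgn_i <- equalize_on_off(W$lgn_i)
    }
  }
  list(W = W, counts_e = counts_e)
}

# Independent scalar simulation of the same toy circuit, written with
# inline arithmetic (no package step functions): the oracle for the
# rho-determined convergence rate, which includes the (negative)
# correlation between inhibitory input spikes and postsynaptic firing
# that the naive independence fixed point rho/(2*tau) ignores.
istdp_toy_oracle <- function(rho, rate_hz = 200, I_drive = 900,
                             eta = 0.01, w_max = 1000, sim_ms = 150000,
                             p = adex_params()) {
  u <- p$E_L; vt <- p$VT_rest; wad <- 0; z <- 0; ii <- 0; clampt <- 0
  w <- 0; xp <- 0; xq <- 0
  pre_prev <- 0L
  nsp <- 0L; t0 <- round(0.6 * sim_ms)
  kin <- p$syn_gain * p$C / p$tau_Iinh
  for (t in seq_len(sim_ms)) {
    pre <- as.integer(runif(1) < rate_hz / 1000)
    ii <- ii * (1 - 1 / p$tau_Iinh) + w * pre_prev * kin
    vt <- p$VT_rest + (vt - p$VT_rest) * exp(-1 / p$tau_VT)
    z <- z * exp(-1 / p$tau_z)
    wad <- wad + (p$a * (u - p$E_L) - wad) / p$tau_wad
    post <- 0L
    if (clampt > 0) {
      clampt <- clampt - 1
      if (clampt <= 0) u <- p$E_L
    } else {
      ex <- min((u - vt) / p$Delta_T, 20)
      u <- u + (-p$g_L * (u - p$E_L) + p$g_L * p$Delta_T * exp(ex) -
                  wad + z - ii + I_drive) / p$C
      if (u > vt) {
        post <- 1L; u <- p$u_spike; clampt <- p$clamp_ms
        vt <- p$VT_max; z <- p$I_sp; wad <- wad + p$b
      }
    }
    xp <- xp * exp(-1 / 10) + pre
    xq <- xq * exp(-1 / 10) + post
    if (pre == 1L) w <- min(max(w + eta * (xq - rho), 0), w_max)
    if (post == 1L) w <- min(max(w + eta * xp, 0), w_max)
    if (t > t0) nsp <- nsp + post
    pre_prev <- pre
  }
  1000 * nsp / (sim_ms - t0)
}
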