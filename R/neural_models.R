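# Linearized two-population neural mass and neural field models used to
# interpret GPLA outputs: phase lags across frequency, spatial phase
# gradients, and rank-1 coupling predictions.

#' Two-population neural mass parameters
#'
#' Membrane dynamics `tau dV/dt = -V + sum(nu * s) + eta` for an excitatory
#' (E) and an inhibitory (I) population, with population rates linearized at
#' the operating point (unit gain absorbed into the synaptic strengths
#' `nu`). Synapses are instantaneous except for an optional alpha kernel
#' `(t/tau_s) exp(-t/tau_s)` and pure delay on the I-I connection, the
#' lagged recurrent inhibition responsible for interneuron-network (ING)
#' resonance.
#'
#' @param tau_e,tau_i membrane time constants (s).
#' @param nu_ee,nu_ei,nu_ie,nu_ii synaptic strengths (E<-E, I<-E, E<-I, I<-I
#'   in the direction "target <- source"; all given as positive magnitudes).
#' @param tau_s alpha-synapse time constant for the I-I connection (s), or
#'   `NULL` for an instantaneous synapse.
#' @param delay_ii pure I-I transmission delay (s).
#' @param ffi feedforward-inhibition weight: fraction of the exogenous drive
#'   also delivered to the I population.
#' @param lfp_proxy which current dominates the simulated LFP: `"exogenous"`
#'   input, recurrent `"epsp"`, or `"ipsp"`.
#' @return a `mass_params` list.
#' @export
mass_params <- function(tau_e = 0.02, tau_i = 0.02, nu_ee = 0, nu_ei = 1,
                        nu_ie = 1, nu_ii = 0, tau_s = NULL, delay_ii = 0,
                        ffi = 0,
                        lfp_proxy = c("exogenous", "epsp", "ipsp")) {
  stopifnot(tau_e > 0, tau_i > 0)
  structure(list(tau_e = tau_e, tau_i = tau_i, nu_ee = nu_ee, nu_ei = nu_ei,
                 nu_ie = nu_ie, nu_ii = nu_ii, tau_s = tau_s,
                 delay_ii = delay_ii, ffi = ffi,
                 lfp_proxy = match.arg(lfp_proxy)),
            class = "mass_params")
}

#' @rdname mass_params
#' @param ... overrides passed to [mass_params()].
#' @export
mass2d_params <- function(...) {
  mass_params(tau_s = NULL, nu_ii = 0, ...)
}

#' @rdname mass_params
#' @export
massalpha_params <- function(nu_ii = 8, tau_s = 0.006,
                             lfp_proxy = "ipsp", ...) {
  mass_params(nu_ii = nu_ii, tau_s = tau_s, lfp_proxy = lfp_proxy, ...)
}

# Augmented linear state matrix (V_E, V_I [, alpha synapse states]) for the
# stability check. Delays are not representable here; callers warn.
mass_state_matrix <- function(p) {
  if (is.null(p$tau_s)) {
    rbind(
      c((-1 + p$nu_ee) / p$tau_e, -p$nu_ie / p$tau_e, 0, 0),
      c(p$nu_ei / p$tau_i, (-1 - p$nu_ii) / p$tau_i, 0, 0),
      c(0, 0, -1, 0), c(0, 0, 0, -1)
    )
  } else {
    rbind(
      c((-1 + p$nu_ee) / p$tau_e, -p$nu_ie / p$tau_e, 0, 0),
      c(p$nu_ei / p$tau_i, -1 / p$tau_i, 0, -p$nu_ii / p$tau_i),
      c(0, 1 / p$tau_s, -1 / p$tau_s, 0),
      c(0, 0, 1 / p$tau_s, -1 / p$tau_s)
    )
  }
}

#' Phase response of the linearized mass model across frequency
#'
#' Solves the two-population linear frequency response to a unit oscillatory
#' exogenous drive and returns the phases of the E and I rate responses
#' relative to the chosen LFP proxy, plus the E-I phase difference, all
#' unwrapped along the frequency grid. An unstable linearization (a pole in
#' the right half plane) is refused.
#'
#' @param params a [mass_params()] object.
#' @param freqs frequency grid (Hz).
#' @return data.frame with columns `freq`, `phase_e`, `phase_i`,
#'   `phase_diff_ei` (radians) and the complex responses `h_e`, `h_i`,
#'   `h_lfp`.
#' @export
mass_phase_curves <- function(params, freqs) {
  stopifnot(inherits(params, "mass_params"), all(freqs >= 0))
  if (params$delay_ii == 0) {
    ev <- eigen(mass_state_matrix(params), only.values = TRUE)$values
    if (max(Re(ev)) >= 0)
      stop("unstable linearization: pole with Re = ",
           signif(max(Re(ev)), 3), " >= 0; reduce the synaptic gains")
  } else {
    warning("stability not verified for a delayed I-I synapse")
  }
  w <- 2 * pi * freqs
  h_ii <- if (is.null(params$tau_s)) rep(1 + 0i, length(w)) else
    1 / (1 + 1i * w * params$tau_s)^2
  h_ii <- h_ii * exp(-1i * w * params$delay_ii)
  a11 <- (1 + 1i * w * params$tau_e) - params$nu_ee
  a12 <- params$nu_ie + 0i
  a21 <- -params$nu_ei + 0i
  a22 <- (1 + 1i * w * params$tau_i) + params$nu_ii * h_ii
  det <- a11 * a22 - a12 * a21
  h_e <- (a22 - a12 * params$ffi) / det
  h_i <- (a11 * params$ffi - a21) / det
  h_lfp <- switch(params$lfp_proxy,
    exogenous = rep(1 + 0i, length(w)),
    epsp = params$nu_ee * h_e,
    ipsp = params$nu_ie * h_ii * h_i
  )
  if (all(Mod(h_lfp) < 1e-300))
    stop("LFP proxy '", params$lfp_proxy, "' is identically zero for these ",
         "parameters (no such synaptic current in the model)")
  data.frame(
    freq = freqs,
    phase_e = signal::unwrap(Arg(h_e / h_lfp)),
    phase_i = signal::unwrap(Arg(h_i / h_lfp)),
    phase_diff_ei = signal::unwrap(Arg(h_e / h_i)),
    h_e = h_e, h_i = h_i, h_lfp = h_lfp
  )
}

#' Two-population neural field parameters (2D grid)
#'
#' Extends the mass model with an exponentially decaying horizontal E-E
#' connectivity of spatial scale `r0` on a square electrode-like grid, plus
#' sigmoid rate functions `lambda = Q / (1 + exp(-chi (V - v_th)))`. The
#' four named presets span weak to strong recurrent inhibition by scaling
#' the inhibitory excitability `chi_i` (with the corresponding sigmoid
#' thresholds), all other parameters held fixed.
#'
#' @param preset `"weak"`, `"lower_med"`, `"upper_med"` or `"strong"`.
#' @param tau_e,tau_i membrane time constants (s).
#' @param nu_ee,nu_ei,nu_ie,nu_ii synaptic strength magnitudes.
#' @param chi_e,chi_i excitability (sigmoid slope) of each population.
#' @param v_th_e,v_th_i sigmoid thresholds.
#' @param q_e,q_i maximum rates (Hz).
#' @param r0 horizontal excitatory connectivity scale (um).
#' @param dx grid spacing (um).
#' @param extent grid side length (um).
#' @param input_sigma spatial STD of the Gaussian exogenous input (um).
#' @param syn_gain overall synaptic efficacy multiplying every connection.
#'   Together with the excitabilities it sets the dimensionless loop gains
#'   attained at the operating point; the default places the
#'   strong-inhibition preset in an underdamped (beta-range resonant) regime
#'   while the weak preset stays overdamped, the regimes the presets are
#'   meant to contrast.
#' @param input_tau correlation time (s) of the Ornstein-Uhlenbeck exogenous
#'   drive; a short value gives an approximately flat input spectrum over
#'   the analysis bands while concentrating power where the rate response
#'   is estimable.
#' @param tau_s first-order synaptic time constant (s) of the recurrent
#'   inhibitory loop (E->I and I->E post-synaptic currents are low-passed
#'   rates); horizontal E-E transmission and the exogenous drive are treated
#'   as fast (unfiltered).
#' @return a `field_params` list.
#' @export
field_params <- function(preset = c("weak", "lower_med", "upper_med",
                                    "strong"),
                         tau_e = 0.02, tau_i = 0.02, nu_ee = 0.2,
                         nu_ei = 0.2, nu_ie = 1, nu_ii = 0, chi_e = 1,
                         chi_i = NULL, v_th_e = 0, v_th_i = NULL,
                         q_e = 20, q_i = 20, r0 = 440, dx = 800,
                         extent = 12000, input_sigma = 1400,
                         syn_gain = 2.8, input_tau = 0.016, tau_s = 0.003) {
  preset <- match.arg(preset)
  chi_i <- chi_i %||% switch(preset, weak = 0.1, lower_med = 0.33,
                             upper_med = 1, strong = 3.33)
  v_th_i <- v_th_i %||% switch(preset, weak = 0, lower_med = 1,
                               upper_med = 5, strong = 5)
  structure(list(preset = preset, tau_e = tau_e, tau_i = tau_i,
                 nu_ee = nu_ee, nu_ei = nu_ei, nu_ie = nu_ie, nu_ii = nu_ii,
                 chi_e = chi_e, chi_i = chi_i, v_th_e = v_th_e,
                 v_th_i = v_th_i, q_e = q_e, q_i = q_i, r0 = r0, dx = dx,
                 extent = extent, input_sigma = input_sigma,
                 syn_gain = syn_gain, input_tau = input_tau, tau_s = tau_s),
            class = "field_params")
}

# Effective linearized couplings at the mid-sigmoid operating point: the
# normalized synaptic drive has slope chi per unit membrane potential and
# every connection carries the shared efficacy syn_gain.
field_effective_nu <- function(p) {
  g <- p$syn_gain
  list(ee = g * p$nu_ee * p$chi_e,
       ei_ie = (g * p$nu_ei * p$chi_e) * (g * p$nu_ie * p$chi_i),
       ii = g * p$nu_ii * p$chi_i)
}

#' Spatial damping coefficient a(f) of the linearized neural field
#'
#' Low-frequency closed form for the complex spatial decay rate of the
#' field's response kernel:
#' `a^2 = (1/r0^2) [1 + nu_EI nu_IE - nu_EE - i 2 pi tau f (2 nu_EI nu_IE - nu_EE)]`
#' with the effective (excitability-scaled) couplings; this is the
#' low-frequency limit in which the synaptic lag `tau_s` is negligible. The
#' principal square root (`Re[a] > 0`, a decaying kernel) is returned. The sign of `Im[a]`
#' separates propagation away from the input site (`Im[a] > 0`, weak
#' recurrent inhibition) from phase convergence toward it (`Im[a] < 0`,
#' strong recurrent inhibition, `2 nu_EI nu_IE >> nu_EE`).
#'
#' @param params a [field_params()] object.
#' @param f frequency (Hz), scalar or vector.
#' @return complex `a(f)` in 1/um.
#' @export
field_kernel_coeff <- function(params, f) {
  stopifnot(inherits(params, "field_params"))
  nu <- field_effective_nu(params)
  re0 <- 1 + nu$ei_ie - nu$ee
  if (re0 <= 0)
    stop("unstable field linearization: 1 + nu_EI*nu_IE - nu_EE = ",
         signif(re0, 3), " <= 0")
  tau <- params$tau_e
  a2 <- (re0 - 1i * 2 * pi * tau * f * (2 * nu$ei_ie - nu$ee)) / params$r0^2
  sqrt(a2)
}

#' Complex spatial response kernel k(x) = exp(-|x| a)
#'
#' The modulus decays with distance at rate `Re[a]`; the phase gradient is
#' `-Im[a]` per unit distance, so the sign of `Im[a]` sets whether the
#' location of strongest input leads (`Im[a] > 0`) or lags (`Im[a] < 0`)
#' its surround.
#'
#' @param a complex coefficient from [field_kernel_coeff()] (1/um).
#' @param x distances (um).
#' @return complex kernel values.
#' @export
spatial_kernel <- function(a, x) exp(-abs(x) * a)

field_grid <- function(params) {
  n_side <- round(params$extent / params$dx)
  g <- (seq_len(n_side) - (n_side + 1) / 2) * params$dx
  coords <- as.matrix(expand.grid(x = g, y = g))
  D <- as.matrix(stats::dist(coords))
  list(coords = coords, dist = D, n = nrow(coords), n_side = n_side)
}

#' Simulate the two-population neural field on a 2D electrode grid
#'
#' Integrates the sigmoid-rate field equations by forward Euler:
#' membrane potentials of local E and I populations at every grid node,
#' horizontal E-E coupling `exp(-|x|/r0)` (row-normalized), local inhibition,
#' and a spatially Gaussian, temporally white, synchronous exogenous drive
#' to the E population. Both populations receive a tonic depolarization
#' placing them at their sigmoid mid-slope, so the linearization around the
#' simulated operating point has the effective couplings used by
#' [field_kernel_coeff()]. One excitatory unit per node fires as an
#' inhomogeneous Poisson process from the local E rate; the LFP proxy at a
#' node is the total horizontal E-E EPSP (default) or the local IPSP.
#'
#' @param params a [field_params()] object.
#' @param duration simulated time (s).
#' @param dt Euler step (s); must satisfy `dt <= tau/20`.
#' @param fs_out output sampling rate (Hz) for LFP, rates and spikes.
#' @param input_sd stationary standard deviation of the Ornstein-Uhlenbeck
#'   exogenous drive (same units as V) at the input center.
#' @return list with `lfp_epsp` and `lfp_ipsp` ([raw_lfp()], one trial,
#'   channels = grid nodes), `spikes` ([spike_trains()]), `rate_e` (nodes x
#'   time matrix, Hz), `coords` (um), `fs` and `params`.
#' @export
simulate_field_2d <- function(params, duration = 60, dt = 2.5e-4,
                              fs_out = 125, input_sd = 1) {
  stopifnot(inherits(params, "field_params"))
  tau_min <- min(params$tau_e, params$tau_i)
  if (dt > tau_min / 20 || dt > params$tau_s / 8)
    stop("time step dt = ", dt, " s too coarse; need dt <= tau/20 = ",
         tau_min / 20, " s and dt <= tau_s/8 = ", params$tau_s / 8, " s")
  g <- field_grid(params)
  K <- exp(-g$dist / params$r0)
  K <- K / rowSums(K)
  center <- colMeans(g$coords)
  rho2 <- rowSums(sweep(g$coords, 2L, center)^2)
  n_x <- exp(-rho2 / (2 * params$input_sigma^2))
  decim <- round(1 / (fs_out * dt))
  if (abs(decim * fs_out * dt - 1) > 1e-9)
    stop("1/(fs_out * dt) must be an integer number of steps")
  n_out <- round(duration * fs_out)
  n_steps <- n_out * decim
  V_e <- rep(params$v_th_e, g$n)
  V_i <- rep(params$v_th_i, g$n)
  syn_e <- numeric(g$n)          # synaptically filtered E and I outputs
  syn_i <- numeric(g$n)
  sig <- function(x) 1 / (1 + exp(-x))
  gn <- params$syn_gain
  lfp_e <- matrix(0, g$n, n_out)
  lfp_i <- matrix(0, g$n, n_out)
  rate_e <- matrix(0, g$n, n_out)
  # Ornstein-Uhlenbeck drive with stationary SD input_sd
  rho <- exp(-dt / params$input_tau)
  innov <- stats::rnorm(n_steps, sd = input_sd * sqrt(1 - rho^2))
  eps <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  for (s in seq_len(n_steps)) {
    s_e <- sig(params$chi_e * (V_e - params$v_th_e))
    u_e <- 4 * s_e - 2
    u_i <- 4 * sig(params$chi_i * (V_i - params$v_th_i)) - 2
    epsp <- gn * params$nu_ee * drop(K %*% u_e)
    ipsp <- -gn * params$nu_ie * syn_i
    lam <- params$q_e * s_e
    V_e <- V_e + dt / params$tau_e *
      (-(V_e - params$v_th_e) + epsp + ipsp + n_x * eps[s])
    V_i <- V_i + dt / params$tau_i *
      (-(V_i - params$v_th_i) + gn * (params$nu_ei * syn_e -
                                      params$nu_ii * syn_i))
    syn_e <- syn_e + dt / params$tau_s * (u_e - syn_e)
    syn_i <- syn_i + dt / params$tau_s * (u_i - syn_i)
    b <- (s - 1L) %/% decim + 1L
    lfp_e[, b] <- lfp_e[, b] + epsp / decim
    lfp_i[, b] <- lfp_i[, b] + ipsp / decim
    rate_e[, b] <- rate_e[, b] + lam / decim
  }
  times <- lapply(seq_len(g$n), function(m) {
    k_t <- stats::rpois(n_out, rate_e[m, ] / fs_out)
    list(rep(seq_len(n_out), k_t))
  })
  spikes <- spike_trains(times, n_out, fs_out)
  list(lfp_epsp = raw_lfp(lfp_e, fs_out, coords = g$coords),
       lfp_ipsp = raw_lfp(lfp_i, fs_out, coords = g$coords),
       spikes = spikes, rate_e = rate_e, coords = g$coords, fs = fs_out,
       params = params)
}

#' Rank-1 coupling prediction of the linearized neural field
#'
#' Solves the linearized field response to a separable exogenous drive
#' `eta(x, f) = n(x) eps(f)` at one frequency, giving the spatial profiles
#' `psi_E`, `psi_I` (rate responses) and `psi_L` (LFP proxy response). The
#' predicted coupling matrix is the rank-1 outer product
#' `psi_L psi_E^H`, directly comparable (up to global phase and scale) to
#' the GPLA LFP and spike vectors estimated from a simulation.
#'
#' @param params a [field_params()] object.
#' @param f frequency (Hz).
#' @param lfp_proxy `"epsp"` or `"ipsp"`.
#' @param input_profile optional custom `n(x)` over grid nodes; default is
#'   the Gaussian profile used by [simulate_field_2d()].
#' @return list with complex vectors `psi_e`, `psi_i`, `psi_l`, the
#'   predicted `coupling` matrix, and `coords`.
#' @export
model_rank1_prediction <- function(params, f, lfp_proxy = c("epsp", "ipsp"),
                                   input_profile = NULL) {
  stopifnot(inherits(params, "field_params"))
  lfp_proxy <- match.arg(lfp_proxy)
  g <- field_grid(params)
  K <- exp(-g$dist / params$r0)
  K <- K / rowSums(K)
  if (is.null(input_profile)) {
    center <- colMeans(g$coords)
    rho2 <- rowSums(sweep(g$coords, 2L, center)^2)
    input_profile <- exp(-rho2 / (2 * params$input_sigma^2))
  }
  w <- 2 * pi * f
  gn <- params$syn_gain
  hs <- 1 / (1 + 1i * w * params$tau_s)
  d_i <- 1 + 1i * w * params$tau_i + gn * params$nu_ii * params$chi_i * hs
  gain_i <- (gn * params$nu_ie * params$chi_i * hs) *
    (gn * params$nu_ei * params$chi_e * hs) / d_i
  A <- diag(1 + 1i * w * params$tau_e + gain_i, g$n) -
    gn * params$nu_ee * params$chi_e * K
  v_e <- solve(A, input_profile + 0i)
  v_i <- (gn * params$nu_ei * params$chi_e * hs) / d_i * v_e
  psi_e <- params$chi_e * v_e
  psi_i <- params$chi_i * v_i
  psi_l <- switch(lfp_proxy,
    epsp = gn * params$nu_ee * params$chi_e * drop(K %*% v_e),
    ipsp = -gn * params$nu_ie * params$chi_i * v_i
  )
  list(psi_e = psi_e, psi_i = psi_i, psi_l = psi_l,
       coupling = psi_l %*% t(Conj(psi_e)), coords = g$coords)
}
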