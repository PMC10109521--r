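# Synthetic benchmark generators: oscillation-mixture LFPs and
# phase-locked Poisson spike trains. All randomness uses R's global RNG, so
# callers control reproducibility with set.seed().

#' Oscillatory component specification
#'
#' @param freq oscillation frequency (Hz).
#' @param amplitude peak amplitude.
#' @param phase phase offset (radians).
#' @param envelope `"constant"` or `"transient"` (a Tukey-tapered burst in
#'   the middle of the trial).
#' @param transient_frac fraction of the trial occupied by a transient
#'   envelope.
#' @param taper Tukey taper fraction of the transient window.
#' @return an `oscillation_spec` list.
#' @export
oscillation <- function(freq, amplitude = 1, phase = 0,
                        envelope = c("constant", "transient"),
                        transient_frac = 0.5, taper = 0.5) {
  envelope <- match.arg(envelope)
  stopifnot(freq > 0, amplitude >= 0)
  structure(list(freq = freq, amplitude = amplitude, phase = phase,
                 envelope = envelope, transient_frac = transient_frac,
                 taper = taper),
            class = "oscillation_spec")
}

tukey_window <- function(n, taper = 0.5) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  r <- taper / 2
  lo <- t < r
  hi <- t > 1 - r
  w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1 + r) / r)))
  w
}

# Unit-amplitude complex phasor (envelope * exp(i(2 pi f t + phase))) of one
# oscillation spec, at sample times of one trial.
osc_phasor <- function(spec, fs, n_samples) {
  t <- (seq_len(n_samples) - 1L) / fs
  env <- if (spec$envelope == "constant") {
    rep(1, n_samples)
  } else {
    inside <- round(n_samples * c((1 - spec$transient_frac) / 2,
                                  (1 + spec$transient_frac) / 2))
    e <- numeric(n_samples)
    idx <- max(1L, inside[1L]):min(n_samples, inside[2L])
    e[idx] <- tukey_window(length(idx), spec$taper)
    e
  }
  env * exp(1i * (2 * pi * spec$freq * t + spec$phase))
}

#' Generate a multichannel LFP as a mixture of oscillations plus noise
#'
#' Each channel is a weighted sum of the real parts of the oscillatory
#' components plus channel-independent additive Gaussian white noise. The
#' unit-amplitude complex phasors of the components are attached as
#' attribute `"phasors"` (one `n_osc x T` matrix per trial) for use by
#' [gen_locked_spikes()].
#'
#' @param oscillations list of [oscillation()] specs.
#' @param mixing numeric `n_channels x n_osc` weight matrix.
#' @param fs sampling rate (Hz).
#' @param duration trial duration (s).
#' @param n_trials number of trials.
#' @param noise_sd standard deviation of the additive white noise.
#' @return a [raw_lfp()] with attribute `"phasors"`.
#' @export
gen_lfp <- function(oscillations, mixing, fs, duration, n_trials = 1L,
                    noise_sd = 0) {
  if (inherits(oscillations, "oscillation_spec"))
    oscillations <- list(oscillations)
  mixing <- as.matrix(mixing)
  stopifnot(ncol(mixing) == length(oscillations))
  n_samples <- round(duration * fs)
  phasors <- vector("list", n_trials)
  trials <- vector("list", n_trials)
  amps <- vapply(oscillations, `[[`, numeric(1L), "amplitude")
  for (k in seq_len(n_trials)) {
    Z <- t(vapply(oscillations, function(s) osc_phasor(s, fs, n_samples),
                  complex(n_samples)))
    Z <- matrix(Z, nrow = length(oscillations))
    comp <- Re(Z) * amps
    tr <- mixing %*% comp
    if (noise_sd > 0)
      tr <- tr + matrix(stats::rnorm(length(tr), sd = noise_sd), nrow(tr))
    trials[[k]] <- tr
    phasors[[k]] <- Z
  }
  out <- raw_lfp(trials, fs)
  attr(out, "phasors") <- phasors
  out
}

#' Generate phase-locked inhomogeneous Poisson spike trains
#'
#' Each unit fires as an inhomogeneous Poisson process with rate
#' `lambda(t) = rate * (1 + kappa * Re(z(t) exp(-i phi0)))`, clipped at 0,
#' where `z(t)` is the unit-amplitude phasor of the oscillation the unit is
#' assigned to. `kappa = 0` gives a homogeneous Poisson train; `kappa = 1`
#' drives the rate to zero at the anti-preferred phase ("perfect" coupling).
#' For a constant envelope the exact pairwise coupling against the
#' oscillation's own phasor is `PLV = (kappa / 2) exp(i phi0)`.
#'
#' Spike counts are drawn per LFP sample (Poisson with mean `lambda(t)/fs`),
#' so spike times are directly sample indices; a sample may carry more than
#' one spike.
#'
#' @param phasors list per trial of `n_osc x T` complex phasor matrices, or
#'   a [gen_lfp()] output carrying them as attribute.
#' @param n_units number of units.
#' @param rate baseline firing rate (Hz).
#' @param kappa coupling strength in `[0, 1]`, scalar or per unit.
#' @param phi0 preferred locking phase (radians), scalar or per unit.
#' @param assignment per-unit oscillation index (0 = uncoupled), recycled.
#' @param fs sampling rate (Hz).
#' @return a [spike_trains()] object.
#' @export
gen_locked_spikes <- function(phasors, n_units, rate, kappa, phi0 = 0,
                              assignment = 1L, fs) {
  if (inherits(phasors, "raw_lfp")) {
    fs <- phasors$fs
    phasors <- attr(phasors, "phasors")
  }
  stopifnot(is.list(phasors), all(kappa >= 0), all(kappa <= 1))
  kappa <- rep_len(kappa, n_units)
  phi0 <- rep_len(phi0, n_units)
  assignment <- rep_len(as.integer(assignment), n_units)
  n_trials <- length(phasors)
  lens <- vapply(phasors, ncol, 1L)
  times <- lapply(seq_len(n_units), function(m) {
    lapply(seq_len(n_trials), function(k) {
      lam <- if (assignment[m] == 0L || kappa[m] == 0) {
        rep(rate, lens[k])
      } else {
        z <- phasors[[k]][assignment[m], ]
        pmax(0, rate * (1 + kappa[m] * Re(z * exp(-1i * phi0[m]))))
      }
      k_t <- stats::rpois(lens[k], lam / fs)
      rep(seq_len(lens[k]), k_t)
    })
  })
  spike_trains(times, lens, fs)
}

#' Canonical single-channel coupling scenarios
#'
#' Generates a single-channel transient LFP oscillation together with 18 (by
#' default) spike trains whose locking pattern illustrates the
#' interpretation of the spike vector: all units locked at one phase
#' (`"global_sync"`, at the oscillation trough), preferred phases spread
#' evenly over 180 degrees (`"wave"`, sequential discharge), three phase
#' clusters (`"three_clusters"`), or no coupling at all (`"uncoupled"`).
#'
#' @param kind scenario name.
#' @param n_units number of spike trains.
#' @param n_trials,duration,fs trial layout.
#' @param f0 oscillation frequency (Hz).
#' @param kappa coupling strength for the coupled scenarios.
#' @param rate baseline firing rate (Hz).
#' @param noise_sd LFP additive noise.
#' @return list with `lfp` ([raw_lfp()]), `spikes` ([spike_trains()]),
#'   `phi0` (per-unit locking phases), `band` (suggested analysis band) and
#'   `kind`.
#' @export
gen_scenario <- function(kind = c("global_sync", "wave", "three_clusters",
                                  "uncoupled"),
                         n_units = 18L, n_trials = 40L, duration = 4,
                         fs = 125, f0 = 5, kappa = 1, rate = 10,
                         noise_sd = 0.02) {
  kind <- match.arg(kind)
  phi0 <- switch(kind,
    global_sync = rep(pi, n_units),
    wave = seq(0, pi, length.out = n_units),
    three_clusters = rep(c(-2 * pi / 3, 0, 2 * pi / 3),
                         length.out = n_units),
    uncoupled = rep(0, n_units)
  )
  if (kind == "uncoupled") kappa <- 0
  lfp <- gen_lfp(oscillation(f0, envelope = "transient"),
                 mixing = matrix(1, 1L, 1L), fs = fs, duration = duration,
                 n_trials = n_trials, noise_sd = noise_sd)
  spikes <- gen_locked_spikes(lfp, n_units = n_units, rate = rate,
                              kappa = kappa, phi0 = phi0, assignment = 1L,
                              fs = fs)
  list(lfp = lfp, spikes = spikes, phi0 = phi0,
       band = c(max(0.5, f0 - 2), f0 + 2), kind = kind)
}

#' Multi-assembly benchmark: cell populations locked to distinct rhythms
#'
#' Simulates `n_pops` non-overlapping cell assemblies, each phase-locked to
#' its own oscillatory LFP component with frequencies spread over a narrow
#' range (11-15.5 Hz by default). The LFP mixes all components across
#' channels with Gaussian weights plus white noise; coupled units are
#' partitioned evenly among assemblies and the remaining units fire
#' homogeneously. The noiseless coupling matrix has rank `n_pops`.
#'
#' @param n_pops number of assemblies (1-10 in the benchmark).
#' @param n_units,n_channels matrix dimensions of the benchmark.
#' @param freq_range assembly frequency range (Hz).
#' @param strength coupling strength kappa in `[0, 1]` (0 = none).
#' @param coupled_fraction fraction of units assigned to assemblies.
#' @param rate baseline firing rate (Hz).
#' @param duration total recording length (s), split into `n_trials` trials.
#' @param n_trials number of trials.
#' @param fs sampling rate (Hz).
#' @param noise_sd LFP white-noise standard deviation. The default keeps the
#'   oscillatory components dominant within the analysis band (per-channel
#'   oscillation power is ~0.5 on average), so the retained whitened rank
#'   stays close to the number of rhythms; broadband-noise-dominated LFP
#'   raises the effective rank and with it the detection threshold.
#' @return list with `lfp`, `spikes`, `band` (suggested analysis band) and
#'   `truth` (assignment, frequencies, locking phases, rank, and the exact
#'   per-unit `PLV = strength/2 * exp(i phi0)`).
#' @export
gen_multipop <- function(n_pops = 1L, n_units = 100L, n_channels = 100L,
                         freq_range = c(11, 15.5), strength = 0.5,
                         coupled_fraction = 1, rate = 20, duration = 60,
                         n_trials = 3L, fs = 125, noise_sd = 0.1) {
  stopifnot(n_pops >= 1L, strength >= 0, strength <= 1)
  freqs <- if (n_pops == 1L) mean(freq_range) else
    seq(freq_range[1L], freq_range[2L], length.out = n_pops)
  phase0 <- stats::runif(n_pops, 0, 2 * pi)
  oscs <- lapply(seq_len(n_pops), function(p)
    oscillation(freqs[p], amplitude = 1, phase = phase0[p]))
  mixing <- matrix(stats::rnorm(n_channels * n_pops), n_channels) /
    sqrt(n_pops)
  lfp <- gen_lfp(oscs, mixing, fs = fs, duration = duration / n_trials,
                 n_trials = n_trials, noise_sd = noise_sd)
  n_coupled <- round(coupled_fraction * n_units)
  assignment <- c(rep_len(seq_len(n_pops), n_coupled),
                  rep(0L, n_units - n_coupled))
  phi0_pop <- stats::runif(n_pops, -pi, pi)
  phi0 <- ifelse(assignment > 0, phi0_pop[pmax(assignment, 1L)], 0)
  kappa <- ifelse(assignment > 0, strength, 0)
  spikes <- gen_locked_spikes(lfp, n_units = n_units, rate = rate,
                              kappa = kappa, phi0 = phi0,
                              assignment = assignment, fs = fs)
  truth <- list(assignment = assignment, freqs = freqs, phi0 = phi0_pop,
                rank = if (strength > 0) n_pops else 0L,
                plv = ifelse(assignment > 0,
                             strength / 2 * exp(1i * phi0), 0))
  list(lfp = lfp, spikes = spikes,
       band = c(freq_range[1L] - 1.5, freq_range[2L] + 1.5), truth = truth)
}

#' Signal-to-noise ratio of a complex coupling estimate
#'
#' Ratio of the ground-truth coupling strength to the estimation error:
#' `SNR = |truth| / |estimated - truth|`. An exact estimate yields the cap
#' value with attribute `capped = TRUE`.
#'
#' @param estimated,truth complex scalars (or equal-length vectors).
#' @param cap ceiling for a zero estimation error.
#' @return numeric SNR(s), possibly with attribute `capped`.
#' @export
snr_of_estimate <- function(estimated, truth, cap = 1e12) {
  err <- Mod(estimated - truth)
  out <- ifelse(err == 0, cap, Mod(truth) / pmax(err, Mod(truth) / cap))
  if (any(err == 0)) attr(out, "capped") <- TRUE
  out
}
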