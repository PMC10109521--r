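# Benchmark drivers replicating the synthetic validation studies: type-I
# error of the analytical test, recovery of the number of coupled
# populations, detection sensitivity versus coupling strength, and the
# comparison of gPLV against univariate detection. All use the global RNG;
# seed with set.seed() for reproducibility.

#' Type-I error of the analytical test on uncoupled data
#'
#' Repeatedly simulates a mixed-oscillation multichannel LFP together with
#' homogeneous Poisson spike trains (zero coupling), runs the whitened
#' mode-"c" GPLA chain and the Marchenko-Pastur threshold test, and reports
#' the fraction of runs declared significant.
#'
#' @param n_runs number of independent simulated datasets.
#' @param n_units,n_channels benchmark dimensions.
#' @param n_osc number of oscillatory LFP components.
#' @param duration,rate recording length (s) and firing rate (Hz) per run.
#' @param progress print a dot every 10 runs.
#' @return list with `rate` (percent of runs significant) and the logical
#'   `decisions` vector.
#' @export
benchmark_type1 <- function(n_runs = 200, n_units = 100, n_channels = 100,
                            n_osc = 3, duration = 20, rate = 25,
                            progress = FALSE) {
  decisions <- vapply(seq_len(n_runs), function(i) {
    d <- gen_multipop(n_pops = n_osc, n_units = n_units,
                      n_channels = n_channels, strength = 0,
                      duration = duration, n_trials = 1L, rate = rate)
    fit <- gpla(d$lfp, d$spikes, band = d$band, mode = "c", whiten = TRUE)
    if (progress && i %% 10 == 0) cat(".")
    analytic_test(fit$coupling)$significant
  }, logical(1L))
  if (progress) cat("\n")
  list(rate = 100 * mean(decisions), decisions = decisions)
}

#' Recovery of the number of coupled populations
#'
#' For each assembly count, simulates non-overlapping cell assemblies locked
#' to distinct rhythms, estimates the population count as the number of
#' squared singular values above the Marchenko-Pastur threshold, and
#' returns the mean-squared error against the true count.
#'
#' @param n_pops vector of true assembly counts.
#' @param runs_per_setting simulated datasets per count.
#' @param strength coupling strength kappa.
#' @param duration,n_trials,rate simulation layout per run. A single
#'   continuous epoch is used by default: with many rhythms of comparable
#'   power the covariance eigenvalues are nearly degenerate, and the
#'   per-trial whitening bases of repeated short trials then rotate within
#'   the oscillation subspace from trial to trial, which can split one
#'   assembly's coupling across components.
#' @param progress print a dot per setting.
#' @return list with `mse`, and a data.frame `estimates` of (n_pops, run,
#'   estimate).
#' @export
benchmark_population_count <- function(n_pops = 1:10, runs_per_setting = 20,
                                       strength = 0.5, duration = 60,
                                       n_trials = 1L, rate = 20,
                                       progress = FALSE) {
  rows <- list()
  for (np in n_pops) {
    est <- vapply(seq_len(runs_per_setting), function(i) {
      d <- gen_multipop(n_pops = np, strength = strength,
                        duration = duration, n_trials = n_trials,
                        rate = rate)
      fit <- gpla(d$lfp, d$spikes, band = d$band, mode = "c", whiten = TRUE)
      analytic_test(fit$coupling)$n_significant
    }, integer(1L))
    rows[[length(rows) + 1L]] <- data.frame(
      n_pops = np, run = seq_len(runs_per_setting), estimate = est)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  estimates <- do.call(rbind, rows)
  list(mse = mean((estimates$estimate - estimates$n_pops)^2),
       estimates = estimates)
}

#' Detection sensitivity of the analytical test versus coupling strength
#'
#' Sweeps the coupling strength in the 100-unit / 100-channel benchmark with
#' two fifths of the units coupled (two assemblies), and reports the
#' smallest strength at which the majority of replicates is declared
#' significant.
#'
#' @param strengths strength grid (including 0 as a negative control).
#' @param reps replicates per strength.
#' @param duration,n_trials,rate simulation layout per run.
#' @param progress print a dot per strength level.
#' @return list with `min_detected` (smallest majority-detected strength; 1
#'   if none) and a data.frame `detections` of per-strength detection
#'   fractions.
#' @export
benchmark_sensitivity <- function(strengths = c(0, 0.025, 0.05, 0.1, 0.2),
                                  reps = 20, duration = 240, n_trials = 3L,
                                  rate = 20, progress = FALSE) {
  frac <- vapply(strengths, function(s) {
    hits <- vapply(seq_len(reps), function(i) {
      d <- gen_multipop(n_pops = 2L, strength = s, coupled_fraction = 0.4,
                        duration = duration, n_trials = n_trials,
                        rate = rate)
      fit <- gpla(d$lfp, d$spikes, band = d$band, mode = "c", whiten = TRUE)
      analytic_test(fit$coupling)$significant
    }, logical(1L))
    if (progress) cat(".")
    mean(hits)
  }, numeric(1L))
  if (progress) cat("\n")
  detected <- strengths[strengths > 0 & frac > 0.5]
  list(min_detected = if (length(detected)) min(detected) else 1,
       detections = data.frame(strength = strengths, fraction = frac))
}

#' Detection-rate comparison: gPLV versus univariate PLV and pooled PLV
#'
#' Repeats a small single-channel simulation with a handful of weakly locked
#' units at heterogeneous preferred phases, and assesses each coupling
#' measure's detection rate with the same interval-jitter surrogate test:
#' per-unit |PLV|, the pooled-spike-train |PLV| (pPLV), and the gPLV of the
#' 1 x n_units coupling matrix. Heterogeneous phases penalize pooling but
#' not the gPLV, which aggregates locking power across units.
#'
#' @param n_reps number of simulated experiments.
#' @param n_units units per experiment.
#' @param kappa coupling strength (weak, near the detection limit).
#' @param n_surrogates jitter surrogates per test (p resolution 1/(n+1)).
#' @param n_trials,duration,f0,rate simulation layout.
#' @param level significance level.
#' @param progress print a dot every 50 repetitions.
#' @return list of detection rates in percent: `gplv`, `pplv`, `plv`
#'   (vector, one per unit).
#' @export
benchmark_detection_comparison <- function(n_reps = 500, n_units = 3,
                                           kappa = 0.4, n_surrogates = 19,
                                           n_trials = 15, duration = 4,
                                           f0 = 5, rate = 10, level = 0.05,
                                           progress = FALSE) {
  phis <- rep(c(0, 2 * pi / 3, -2 * pi / 3), length.out = n_units)
  fs <- 125
  measures <- function(spikes, an) {
    plv <- vapply(seq_len(n_units), function(m)
      pairwise_plv(spikes, an, unit = m), complex(1L))
    n <- spike_counts(spikes)
    c(Mod(plv), Mod(sum(n * plv)) / sum(n), sqrt(sum(Mod(plv)^2)))
  }
  hits <- matrix(0L, n_reps, n_units + 2L)
  for (r in seq_len(n_reps)) {
    lfp <- gen_lfp(oscillation(f0, envelope = "transient"),
                   matrix(1, 1, 1), fs = fs, duration = duration,
                   n_trials = n_trials, noise_sd = 0.02)
    spikes <- gen_locked_spikes(lfp, n_units = n_units, rate = rate,
                                kappa = kappa, phi0 = phis, fs = fs)
    an <- bandpass_analytic(lfp, c(f0 - 2, f0 + 2))
    obs <- measures(spikes, an)
    exceed <- rep(0L, n_units + 2L)
    for (s in seq_len(n_surrogates)) {
      surr <- measures(interval_jitter(spikes, 1 / f0), an)
      exceed <- exceed + (surr >= obs)
    }
    hits[r, ] <- (1 + exceed) / (1 + n_surrogates) <= level
    if (progress && r %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  rates <- 100 * colMeans(hits)
  list(plv = rates[seq_len(n_units)], pplv = rates[n_units + 1L],
       gplv = rates[n_units + 2L])
}
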