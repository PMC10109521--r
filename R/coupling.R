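# Spike containers and the spike-field coupling matrix.

#' Multi-unit, multi-trial spike train container
#'
#' Spike times are stored as 1-based sample indices into the LFP time axis,
#' following the convention that a spike "reads out" the analytic signal at
#' its sample. Use [spikes_from_seconds()] to convert continuous times.
#'
#' @param times list (one element per unit) of lists (one element per trial)
#'   of sorted integer sample indices.
#' @param trial_samples integer scalar or vector: number of samples per trial.
#' @param fs sampling rate in Hz (shared with the LFP).
#' @param units optional unit labels.
#' @return an object of class `spike_trains`.
#' @export
spike_trains <- function(times, trial_samples, fs, units = NULL) {
  stopifnot(is.list(times), length(times) >= 1L)
  n_trials <- length(times[[1L]])
  if (length(trial_samples) == 1L)
    trial_samples <- rep(as.integer(trial_samples), n_trials)
  trial_samples <- as.integer(trial_samples)
  stopifnot(length(trial_samples) == n_trials, all(trial_samples >= 1L))
  times <- lapply(times, function(per_trial) {
    if (length(per_trial) != n_trials)
      stop("all units must have the same number of trials")
    lapply(seq_len(n_trials), function(k) {
      idx <- as.integer(per_trial[[k]])
      if (length(idx) && (min(idx) < 1L || max(idx) > trial_samples[k]))
        stop("spike sample index outside [1, trial length] in trial ", k)
      sort(idx)
    })
  })
  counts <- t(vapply(times, function(per_trial)
    vapply(per_trial, length, 1L), integer(n_trials)))
  counts <- matrix(counts, nrow = length(times))
  if (is.null(units)) units <- paste0("u", seq_along(times))
  structure(
    list(times = times, trial_samples = trial_samples, fs = fs,
         units = units, counts = counts, n_trials = n_trials),
    class = "spike_trains"
  )
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf(
    "<spike_trains> %d unit(s), %d trial(s), %d spikes total (median %g/unit)\n",
    length(x$times), x$n_trials, sum(x$counts),
    stats::median(rowSums(x$counts))
  ))
  invisible(x)
}

#' Total spike count per unit
#' @param spikes a [spike_trains()] object.
#' @return integer vector, one entry per unit.
#' @export
spike_counts <- function(spikes) {
  stopifnot(inherits(spikes, "spike_trains"))
  as.integer(rowSums(spikes$counts))
}

#' Convert continuous spike times (seconds) to sample indices
#'
#' Times are rounded to the nearest sample, with exact half-sample ties
#' resolved toward the earlier sample. Time 0 maps to sample 1.
#'
#' @param times_s list per unit of lists per trial of spike times in seconds.
#' @param fs sampling rate (Hz).
#' @param trial_samples samples per trial (scalar or vector).
#' @param units optional labels.
#' @return a [spike_trains()] object.
#' @export
spikes_from_seconds <- function(times_s, fs, trial_samples, units = NULL) {
  conv <- function(t) {
    x <- t * fs
    i0 <- floor(x)
    i0 + (x - i0 > 0.5) + 1L
  }
  times <- lapply(times_s, function(per_trial) lapply(per_trial, conv))
  spike_trains(times, trial_samples, fs, units)
}

# Phasor (unit-modulus) version of an analytic trial matrix, guarding zeros.
phasor_matrix <- function(L) {
  m <- Mod(L)
  m[m == 0] <- 1
  L / m
}

#' Pairwise phase locking value of one unit against one LFP channel
#'
#' Mean over all spikes, pooled across trials, of the unit-modulus LFP
#' phasors at the spike samples: `PLV = (1/N_tot) sum_j exp(i phi(t_j))`.
#'
#' @param spikes a [spike_trains()] object.
#' @param lfp an `analytic_lfp` with the same trial structure.
#' @param unit unit index.
#' @param channel LFP channel index.
#' @return a single complex number; `NA_complex_` (with attribute
#'   `n_spikes = 0`) when the unit has no spikes, since 0 would wrongly mean
#'   "no locking" rather than "no data".
#' @export
pairwise_plv <- function(spikes, lfp, unit = 1L, channel = 1L) {
  pairwise_stat(spikes, lfp, unit, channel, mode = "plv")
}

#' Pairwise amplitude-weighted coupling statistic c
#'
#' Sum over all spikes of the analytic-signal values at the spike samples,
#' scaled by `1/sqrt(N_tot)`: `c = (1/sqrt(N_tot)) sum_j L(t_j)`. Unlike the
#' PLV it keeps the oscillation amplitude and uses the square-root count
#' normalization that gives unit-variance entries under the null when the
#' LFP is whitened (the form required by the analytical significance test).
#'
#' @inheritParams pairwise_plv
#' @return a single complex number, or flagged `NA` for a spikeless unit.
#' @export
pairwise_c <- function(spikes, lfp, unit = 1L, channel = 1L) {
  pairwise_stat(spikes, lfp, unit, channel, mode = "c")
}

pairwise_stat <- function(spikes, lfp, unit, channel, mode) {
  stopifnot(inherits(spikes, "spike_trains"), inherits(lfp, "analytic_lfp"))
  if (spikes$n_trials != length(lfp$trials))
    stop("spikes and LFP have different trial counts")
  n_tot <- 0L
  acc <- 0 + 0i
  for (k in seq_len(spikes$n_trials)) {
    idx <- spikes$times[[unit]][[k]]
    if (!length(idx)) next
    v <- lfp$trials[[k]][channel, idx]
    if (mode == "plv") v <- exp(1i * Arg(v))
    acc <- acc + sum(v)
    n_tot <- n_tot + length(idx)
  }
  if (n_tot == 0L) {
    out <- NA_complex_
    attr(out, "n_spikes") <- 0L
    return(out)
  }
  if (mode == "plv") acc / n_tot else acc / sqrt(n_tot)
}

#' Assemble the spike-field coupling matrix
#'
#' Builds the complex channels x units matrix of pairwise coupling
#' statistics, pooling spikes over trials. In `mode = "plv"` each entry is a
#' phase locking value (modulus bounded by 1, invariant to LFP amplitude);
#' in `mode = "c"` each entry is the amplitude-weighted statistic normalized
#' by the square root of the spike count, which is the form whose singular
#' spectrum follows the Marchenko-Pastur law under the null after whitening.
#'
#' @param spikes a [spike_trains()] object.
#' @param lfp an `analytic_lfp` (whitened or not).
#' @param mode `"plv"` or `"c"`.
#' @param min_spikes units with fewer total spikes are excluded (default 50).
#' @return an object of class `coupling_matrix` with the complex `values`
#'   matrix, the retained `units` and their `unit_counts`, plus the
#'   normalization metadata (`mode`, `whitened`, `band`).
#' @export
build_coupling_matrix <- function(spikes, lfp, mode = c("plv", "c"),
                                  min_spikes = 50L) {
  mode <- match.arg(mode)
  stopifnot(inherits(spikes, "spike_trains"), inherits(lfp, "analytic_lfp"))
  if (spikes$n_trials != length(lfp$trials))
    stop("spikes and LFP have different trial counts")
  lens <- vapply(lfp$trials, ncol, 1L)
  if (!all(spikes$trial_samples == lens))
    stop("spike trial lengths do not match LFP trial lengths")
  n_tot <- spike_counts(spikes)
  keep <- which(n_tot >= min_spikes)
  if (!length(keep))
    stop("no units retained: all ", length(n_tot), " unit(s) have fewer than ",
         min_spikes, " spikes (counts: ", paste(n_tot, collapse = ", "), ")")
  n_u <- length(keep)
  n_c <- nrow(lfp$trials[[1L]])
  acc_re <- matrix(0, n_c, n_u)
  acc_im <- matrix(0, n_c, n_u)
  for (k in seq_len(spikes$n_trials)) {
    ii <- integer(0); jj <- integer(0)
    for (j in seq_len(n_u)) {
      idx <- spikes$times[[keep[j]]][[k]]
      if (length(idx)) {
        ii <- c(ii, idx)
        jj <- c(jj, rep.int(j, length(idx)))
      }
    }
    if (!length(ii)) next
    S <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(lens[k], n_u))
    L <- lfp$trials[[k]]
    if (mode == "plv") L <- phasor_matrix(L)
    acc_re <- acc_re + as.matrix(Re(L) %*% S)
    acc_im <- acc_im + as.matrix(Im(L) %*% S)
  }
  vals <- matrix(complex(real = acc_re, imaginary = acc_im), n_c, n_u)
  scale <- if (mode == "plv") n_tot[keep] else sqrt(n_tot[keep])
  vals <- sweep(vals, 2L, scale, "/")
  structure(
    list(values = vals, mode = mode, whitened = isTRUE(lfp$whitened),
         band = lfp$band, unit_counts = n_tot[keep],
         units = spikes$units[keep], excluded = spikes$units[-keep],
         channel_ids = lfp$channel_ids),
    class = "coupling_matrix"
  )
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf(
    "<coupling_matrix> %d channels x %d units, mode = %s%s, band %g-%g Hz\n",
    nrow(x$values), ncol(x$values), x$mode,
    if (x$whitened) " (whitened LFP)" else "", x$band[1L], x$band[2L]
  ))
  if (length(x$excluded))
    cat("  excluded units (below spike-count threshold):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
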