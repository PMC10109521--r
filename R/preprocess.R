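# LFP preprocessing: band-limited analytic signals and reduced-rank whitening.

#' Multi-trial raw LFP container
#'
#' Bundles per-trial multichannel LFP matrices with their sampling rate and
#' optional channel metadata. All trials must share the channel count and
#' contain only finite values.
#'
#' @param trials a matrix (channels x time) or list of such matrices, one per
#'   trial. All trials must have the same number of channels.
#' @param fs sampling rate in Hz.
#' @param channel_ids optional character/integer vector of channel labels.
#' @param coords optional numeric matrix (channels x 1 or channels x 2) of
#'   electrode positions in micrometers.
#' @return an object of class `raw_lfp`.
#' @export
raw_lfp <- function(trials, fs, channel_ids = NULL, coords = NULL) {
  if (is.matrix(trials)) trials <- list(trials)
  stopifnot(is.list(trials), length(trials) >= 1L, is.numeric(fs), fs > 0)
  n_c <- nrow(trials[[1L]])
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    if (!is.matrix(tr) || !is.numeric(tr))
      stop("trial ", k, " is not a numeric matrix")
    if (nrow(tr) != n_c)
      stop("trial ", k, " has ", nrow(tr), " channels; expected ", n_c)
    if (ncol(tr) < 2L) stop("trial ", k, " has fewer than 2 samples")
    if (!all(is.finite(tr))) stop("trial ", k, " contains non-finite values")
  }
  if (is.null(channel_ids)) channel_ids <- seq_len(n_c)
  structure(
    list(trials = trials, fs = fs, channel_ids = channel_ids, coords = coords),
    class = "raw_lfp"
  )
}

#' @export
print.raw_lfp <- function(x, ...) {
  cat(sprintf(
    "<raw_lfp> %d channels, %d trial(s), %s samples/trial @ %g Hz\n",
    nrow(x$trials[[1L]]), length(x$trials),
    paste(unique(vapply(x$trials, ncol, 1L)), collapse = "/"), x$fs
  ))
  invisible(x)
}

new_analytic_lfp <- function(trials, fs, band, channel_ids = NULL,
                             whitened = FALSE) {
  structure(
    list(trials = trials, fs = fs, band = band,
         channel_ids = channel_ids %||% seq_len(nrow(trials[[1L]])),
         whitened = whitened),
    class = "analytic_lfp"
  )
}

#' @export
print.analytic_lfp <- function(x, ...) {
  cat(sprintf(
    "<analytic_lfp> %d channels, %d trial(s) @ %g Hz, band %g-%g Hz%s\n",
    nrow(x$trials[[1L]]), length(x$trials), x$fs, x$band[1L], x$band[2L],
    if (isTRUE(x$whitened)) " (whitened)" else ""
  ))
  invisible(x)
}

#' Band-limited analytic signal of a multichannel LFP
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass filter to
#' every channel of every trial and converts the filtered signal to its
#' complex analytic representation via the Hilbert transform. The modulus of
#' the output is the instantaneous oscillation amplitude and its argument the
#' instantaneous phase.
#'
#' @param raw a [raw_lfp()] object.
#' @param band numeric length-2 vector `c(f_lo, f_hi)` in Hz with
#'   `0 < f_lo < f_hi < fs/2`.
#' @param order Butterworth filter order applied in each direction
#'   (default 4).
#' @return an object of class `analytic_lfp` with complex trial matrices of
#'   the same dimensions as the input.
#' @export
bandpass_analytic <- function(raw, band, order = 4L) {
  stopifnot(inherits(raw, "raw_lfp"))
  band <- as.numeric(band)
  if (length(band) != 2L || !all(is.finite(band)))
    stop("band must be c(f_lo, f_hi)")
  if (!(band[1L] > 0 && band[1L] < band[2L] && band[2L] < raw$fs / 2))
    stop(sprintf("band [%g, %g] Hz invalid for fs = %g Hz (need 0 < f_lo < f_hi < fs/2)",
                 band[1L], band[2L], raw$fs))
  bf <- signal::butter(order, band * 2 / raw$fs, type = "pass")
  # filtfilt needs the trial to comfortably exceed the filter's edge padding
  min_len <- 6L * (length(bf$a) - 1L) + 1L
  trials <- lapply(raw$trials, function(tr) {
    if (ncol(tr) < min_len)
      stop("trial too short (", ncol(tr), " samples) for the filter transient (need >= ",
           min_len, ")")
    out <- matrix(0i, nrow(tr), ncol(tr))
    for (ch in seq_len(nrow(tr))) {
      y <- signal::filtfilt(bf, tr[ch, ])
      out[ch, ] <- analytic_signal(y)
    }
    out
  })
  new_analytic_lfp(trials, raw$fs, band, raw$channel_ids)
}

#' Fit a reduced-rank whitening model to analytic LFP
#'
#' Determines the number of principal components `n_c_eff` needed to explain
#' at least `variance_threshold` of the total variance of the all-trial
#' concatenated LFP covariance, then stores, for every trial, the truncated
#' eigendecomposition of that trial's covariance. Applying the model
#' ([apply_whitening()]) decorrelates the channels and normalizes each
#' retained component to unit variance, which is the preprocessing required
#' by the analytical (random-matrix) significance test.
#'
#' @param lfp an `analytic_lfp` object (not already whitened).
#' @param variance_threshold fraction of total variance the retained
#'   components must explain (default 0.99).
#' @return an object of class `whitening_model` with elements `n_c_eff`,
#'   `eigenvalues` (global spectrum), `trial_ops` (per-trial truncated
#'   eigenpairs) and `unwhitening` (filled by [fit_unwhitening()]).
#' @export
fit_whitening <- function(lfp, variance_threshold = 0.99) {
  stopifnot(inherits(lfp, "analytic_lfp"))
  if (isTRUE(lfp$whitened)) stop("LFP is already whitened")
  stopifnot(variance_threshold > 0, variance_threshold <= 1)
  L <- do.call(cbind, lfp$trials)
  C <- cov_analytic(L)
  tot <- sum(Re(diag(C)))
  if (tot <= .Machine$double.eps)
    stop("degenerate input: total LFP variance is zero")
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  n_c_eff <- which(cumsum(vals) / sum(vals) >= variance_threshold)[1L]
  trial_ops <- lapply(lfp$trials, function(tr) {
    ek <- eigen(cov_analytic(tr), symmetric = TRUE)
    idx <- seq_len(n_c_eff)
    lam <- ek$values[idx]
    if (any(lam <= 1e-12 * max(ek$values)))
      stop("trial covariance is rank deficient below the retained rank; ",
           "lower variance_threshold or check the input")
    X <- ek$vectors[, idx, drop = FALSE]
    X <- apply(X, 2L, fix_vector_phase)
    list(values = lam, vectors = matrix(X, ncol = n_c_eff))
  })
  structure(
    list(n_c_eff = n_c_eff, variance_threshold = variance_threshold,
         eigenvalues = vals, trial_ops = trial_ops, unwhitening = NULL,
         n_c = nrow(L), band = lfp$band, fs = lfp$fs),
    class = "whitening_model"
  )
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf(
    "<whitening_model> n_c_eff = %d of %d channels (>= %.3g of variance), %d trial(s)\n",
    x$n_c_eff, x$n_c, x$variance_threshold, length(x$trial_ops)
  ))
  invisible(x)
}

#' Apply a reduced-rank whitening model
#'
#' Projects each trial onto the retained eigenvectors of its own covariance
#' and rescales by the inverse square root of the eigenvalues, so that each
#' whitened trial has (numerically exact) identity covariance on the
#' retained components.
#'
#' @param lfp the `analytic_lfp` the model was fitted on (or compatible data).
#' @param model a [fit_whitening()] result.
#' @return an `analytic_lfp` with `n_c_eff` rows per trial and
#'   `whitened = TRUE`.
#' @export
apply_whitening <- function(lfp, model) {
  stopifnot(inherits(lfp, "analytic_lfp"), inherits(model, "whitening_model"))
  if (length(lfp$trials) != length(model$trial_ops))
    stop("trial count mismatch between data and whitening model")
  if (nrow(lfp$trials[[1L]]) != model$n_c)
    stop("channel count mismatch between data and whitening model")
  trials <- vector("list", length(lfp$trials))
  for (k in seq_along(lfp$trials)) {
    op <- model$trial_ops[[k]]
    trials[[k]] <- (ct(op$vectors) / sqrt(op$values)) %*% lfp$trials[[k]]
  }
  new_analytic_lfp(trials, lfp$fs, lfp$band,
                   channel_ids = paste0("w", seq_len(model$n_c_eff)),
                   whitened = TRUE)
}

#' Estimate the unwhitening operator by least squares
#'
#' Fits the complex linear map `W^-1` that best reconstructs the original
#' channel-space LFP from its whitened representation, over all concatenated
#' trials. Used to map the whitened-space LFP singular vector back to
#' electrode space.
#'
#' @param whitened whitened `analytic_lfp` (n_c_eff rows).
#' @param original the matching original `analytic_lfp` (n_c rows).
#' @return complex matrix `n_c x n_c_eff`.
#' @export
fit_unwhitening <- function(whitened, original) {
  stopifnot(inherits(whitened, "analytic_lfp"), inherits(original, "analytic_lfp"))
  Lw <- do.call(cbind, whitened$trials)
  L <- do.call(cbind, original$trials)
  if (ncol(Lw) != ncol(L))
    stop("concatenated trial lengths differ between whitened and original LFP")
  G <- Lw %*% ct(Lw)
  (L %*% ct(Lw)) %*% solve(G)
}

#' Trim filter edge artifacts from analytic LFP (and matching spikes)
#'
#' Discards a margin at both ends of every trial, by default three cycles of
#' the band's lower edge, to avoid Hilbert/filter edge effects entering the
#' coupling estimates. Spike indices are shifted accordingly and spikes
#' falling in the margins are dropped.
#'
#' @param lfp an `analytic_lfp`.
#' @param spikes optional [spike_trains()] sharing the trial structure.
#' @param cycles margin length in cycles of the band lower edge (default 3).
#' @return the trimmed `analytic_lfp`, or `list(lfp, spikes)` when spikes
#'   are supplied.
#' @export
trim_edges <- function(lfp, spikes = NULL, cycles = 3) {
  stopifnot(inherits(lfp, "analytic_lfp"))
  m <- ceiling(cycles * lfp$fs / lfp$band[1L])
  lens <- vapply(lfp$trials, ncol, 1L)
  if (any(lens <= 2L * m + 2L))
    stop("trials too short to trim a ", m, "-sample edge margin")
  trials <- lapply(lfp$trials, function(tr) tr[, (m + 1L):(ncol(tr) - m), drop = FALSE])
  out_lfp <- new_analytic_lfp(trials, lfp$fs, lfp$band, lfp$channel_ids,
                              lfp$whitened)
  if (is.null(spikes)) return(out_lfp)
  stopifnot(inherits(spikes, "spike_trains"))
  new_times <- lapply(spikes$times, function(per_trial) {
    lapply(seq_along(per_trial), function(k) {
      idx <- per_trial[[k]]
      idx <- idx[idx > m & idx <= lens[k] - m] - m
      idx
    })
  })
  out_sp <- spike_trains(new_times, trial_samples = lens - 2L * m,
                         fs = spikes$fs, units = spikes$units)
  list(lfp = out_lfp, spikes = out_sp)
}
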