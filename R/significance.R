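# Significance assessment of the gPLV: spike-jitter surrogates and the
# analytical Marchenko-Pastur (random matrix theory) test.

#' Simple interval jitter surrogate
#'
#' Partitions each trial's time axis into contiguous windows (anchored at
#' the trial start; the last, possibly partial, window is kept) and redraws
#' every spike uniformly within its window, independently per spike. The
#' per-window, per-unit spike counts are preserved exactly, so rate
#' modulations slower than the window survive while locking to oscillations
#' faster than the window is destroyed. The recommended window is one cycle
#' of the analysis band's center frequency.
#'
#' @param spikes a [spike_trains()] object.
#' @param window_s jitter window in seconds (> 0).
#' @return a jittered `spike_trains` object.
#' @export
interval_jitter <- function(spikes, window_s) {
  jitter_windows(spikes, window_s, grouped = FALSE)
}

#' Group-preserved jitter surrogate
#'
#' Like [interval_jitter()], but draws a single uniform circular shift per
#' window, applied jointly to the spikes of all units, so the relative spike
#' timing across units within a window is preserved (modulo the window)
#' while the alignment to the LFP is destroyed.
#'
#' @inheritParams interval_jitter
#' @return a jittered `spike_trains` object.
#' @export
group_preserved_jitter <- function(spikes, window_s) {
  jitter_windows(spikes, window_s, grouped = TRUE)
}

jitter_windows <- function(spikes, window_s, grouped) {
  stopifnot(inherits(spikes, "spike_trains"), window_s > 0)
  w <- max(1L, as.integer(round(window_s * spikes$fs)))
  n_units <- length(spikes$times)
  lens <- spikes$trial_samples
  if (any(w >= lens))
    warning("jitter window (", w, " samples) covers a whole trial; ",
            "surrogates reduce to a single window")
  new_times <- lapply(spikes$times, function(per_trial) per_trial)
  for (k in seq_len(spikes$n_trials)) {
    T_k <- lens[k]
    n_win <- ceiling(T_k / w)
    win_len <- pmin(w, T_k - (seq_len(n_win) - 1L) * w)
    shifts <- if (grouped) {
      vapply(win_len, function(l) sample.int(l, 1L) - 1L, 1L)
    } else NULL
    for (m in seq_len(n_units)) {
      idx <- spikes$times[[m]][[k]]
      if (!length(idx)) next
      wid <- (idx - 1L) %/% w          # 0-based window id
      start <- wid * w                 # 0-based window start
      len <- win_len[wid + 1L]
      new_idx <- if (grouped) {
        start + ((idx - 1L - start + shifts[wid + 1L]) %% len) + 1L
      } else {
        start + floor(stats::runif(length(idx)) * len) + 1L
      }
      new_times[[m]][[k]] <- sort(as.integer(new_idx))
    }
  }
  spike_trains(new_times, lens, spikes$fs, spikes$units)
}

#' Surrogate-based significance test of the gPLV
#'
#' Builds an empirical null distribution of the gPLV by recomputing GPLA on
#' jittered spike trains and returns the add-one p-value
#' `p = (1 + #{gPLV_surr >= gPLV_obs}) / (1 + n_surrogates)` (never exactly
#' zero).
#'
#' @param spikes a [spike_trains()] object.
#' @param lfp an `analytic_lfp` (already band-limited; whitened or not).
#' @param n_surrogates number of surrogate datasets (>= 19).
#' @param jitter `"interval"` or `"group"` surrogate scheme.
#' @param window_s jitter window in seconds; default one cycle of the band
#'   center frequency.
#' @param mode coupling statistic passed to [build_coupling_matrix()].
#' @param min_spikes unit inclusion threshold.
#' @param seed optional integer seed, recorded in the report.
#' @return an object of class `significance_report`.
#' @export
surrogate_test <- function(spikes, lfp, n_surrogates = 100L,
                           jitter = c("interval", "group"), window_s = NULL,
                           mode = "plv", min_spikes = 1L, seed = NULL) {
  jitter <- match.arg(jitter)
  stopifnot(n_surrogates >= 19L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(window_s)) window_s <- 2 / sum(lfp$band)
  observed <- gpla_decompose(
    build_coupling_matrix(spikes, lfp, mode = mode, min_spikes = min_spikes)
  )$gplv
  jfun <- if (jitter == "interval") interval_jitter else group_preserved_jitter
  surr <- vapply(seq_len(n_surrogates), function(i) {
    sp <- jfun(spikes, window_s)
    gpla_decompose(
      build_coupling_matrix(sp, lfp, mode = mode, min_spikes = min_spikes)
    )$gplv
  }, numeric(1L))
  p <- (1 + sum(surr >= observed)) / (1 + n_surrogates)
  structure(
    list(method = paste0("surrogate_", jitter), p_value = p,
         significant = p <= 0.05, gplv_observed = observed,
         surrogates = surr, n_surrogates = n_surrogates,
         jitter_window = window_s, seed = seed),
    class = "significance_report"
  )
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("<significance_report> method = %s\n", x$method))
  if (!is.null(x$p_value) && !is.na(x$p_value))
    cat(sprintf("  p = %.4g (%d surrogates, window %.4g s)\n",
                x$p_value, x$n_surrogates %||% NA, x$jitter_window %||% NA))
  if (!is.null(x$statistic))
    cat(sprintf("  largest eigenvalue of S = %.4g vs threshold %.4g -> %s\n",
                x$statistic, x$threshold,
                if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Marchenko-Pastur law and detection threshold
#'
#' For an `n_c_eff x n_u` coupling matrix with iid unit-variance entries,
#' the eigenvalues of `S = (1/n_u) C C^H` follow the Marchenko-Pastur law
#' with aspect ratio `alpha = n_c_eff / n_u`, supported on
#' `[(1 - sqrt(alpha))^2, (1 + sqrt(alpha))^2]`. The upper edge is the
#' detection threshold `theta_DET` for the largest eigenvalue.
#'
#' @param n_c_eff number of (retained, whitened) LFP components.
#' @param n_u number of spiking units.
#' @return an object of class `mp_law` with `alpha`, support `a`, `b`, and
#'   `threshold`.
#' @export
mp_threshold <- function(n_c_eff, n_u) {
  stopifnot(n_c_eff >= 1, n_u >= 1)
  alpha <- n_c_eff / n_u
  structure(
    list(alpha = alpha, a = (1 - sqrt(alpha))^2, b = (1 + sqrt(alpha))^2,
         threshold = (1 + sqrt(alpha))^2, n_c_eff = n_c_eff, n_u = n_u),
    class = "mp_law"
  )
}

#' @export
print.mp_law <- function(x, ...) {
  cat(sprintf(
    "<mp_law> alpha = %.4g, support [%.4g, %.4g], theta_DET = %.4g\n",
    x$alpha, x$a, x$b, x$threshold
  ))
  invisible(x)
}

#' Marchenko-Pastur density
#'
#' `f(x) = sqrt((b - x)(x - a)) / (2 pi alpha x)` on `[a, b]`, zero outside.
#' For `alpha <= 1` the density integrates to 1; for `alpha > 1` the law has
#' an additional point mass `1 - 1/alpha` at zero (not represented here).
#'
#' @param x evaluation points.
#' @param alpha aspect ratio (> 0).
#' @return density values.
#' @export
mp_density <- function(x, alpha) {
  stopifnot(alpha > 0)
  a <- (1 - sqrt(alpha))^2
  b <- (1 + sqrt(alpha))^2
  out <- numeric(length(x))
  inside <- x > a & x < b
  xi <- x[inside]
  out[inside] <- sqrt((b - xi) * (xi - a)) / (2 * pi * alpha * xi)
  out
}

#' Marchenko-Pastur cumulative distribution (continuous part)
#'
#' Numerical quadrature of [mp_density()]; used for spectrum goodness-of-fit
#' checks.
#'
#' @param q quantiles.
#' @param alpha aspect ratio.
#' @return cumulative probabilities.
#' @export
mp_cdf <- function(q, alpha) {
  a <- (1 - sqrt(alpha))^2
  b <- (1 + sqrt(alpha))^2
  grid <- seq(a, b, length.out = 4096L)
  dens <- mp_density(grid, alpha)
  step <- grid[2L] - grid[1L]
  cdf <- c(0, cumsum((dens[-1L] + dens[-length(dens)]) / 2) * step)
  cdf <- cdf / cdf[length(cdf)]
  vapply(q, function(x) {
    if (x <= a) 0 else if (x >= b) 1 else stats::approx(grid, cdf, x)$y
  }, numeric(1L))
}

#' Analytical (random matrix theory) significance test
#'
#' Under the null of no spike-field coupling, after LFP whitening and with
#' the `1/sqrt(N)` entry normalization (mode `"c"`), the squared singular
#' values of the coupling matrix, scaled as `S = (1/n_u) C C^H`, follow the
#' Marchenko-Pastur law with ratio `alpha_eff = n_c_eff / n_u`. Coupling is
#' declared significant when the largest eigenvalue exceeds the upper edge
#' `theta_DET = (1 + sqrt(alpha_eff))^2`, i.e. when
#' `gPLV > sqrt(n_u * theta_DET)`. Each squared singular value is tested
#' against the same threshold; the number of significant components
#' (counted in descending order, stopping at the first non-significant one)
#' estimates the number of distinct coupled populations.
#'
#' @param C a [build_coupling_matrix()] result with `mode = "c"` computed on
#'   whitened LFP (the conditions of the underlying theorem); anything else
#'   is refused.
#' @return a `significance_report` with the decision, the eigenvalue
#'   statistic, the threshold, per-component significance and
#'   `n_significant`.
#' @export
analytic_test <- function(C) {
  stopifnot(inherits(C, "coupling_matrix"))
  if (C$mode != "c" || !isTRUE(C$whitened))
    stop("the analytical test requires mode = 'c' on whitened LFP; got mode = '",
         C$mode, "', whitened = ", C$whitened,
         ". Use surrogate_test() instead.")
  d <- svd(C$values, nu = 0L, nv = 0L)$d
  n_u <- ncol(C$values)
  law <- mp_threshold(nrow(C$values), n_u)
  ell <- d^2 / n_u
  sig_each <- ell > law$threshold
  n_sig <- if (any(!sig_each)) which(!sig_each)[1L] - 1L else length(sig_each)
  structure(
    list(method = "analytic", significant = sig_each[1L],
         statistic = ell[1L], threshold = law$threshold,
         eigenvalues = ell, component_significant = sig_each,
         n_significant = n_sig, law = law,
         gplv_observed = d[1L], p_value = NA_real_),
    class = "significance_report"
  )
}

#' Count significant singular values of a GPLA result
#'
#' Applies the Marchenko-Pastur threshold to each squared singular value (in
#' descending order, stopping at the first non-significant one). The count
#' estimates the number of neuronal populations coupled to distinct rhythms.
#'
#' @param result a `gpla_result` from mode `"c"` on whitened LFP.
#' @return integer count.
#' @export
count_significant <- function(result) {
  stopifnot(inherits(result, "gpla_result"))
  if (result$mode != "c" || !isTRUE(result$whitened))
    stop("significant-component counting requires mode 'c' on whitened LFP")
  law <- mp_threshold(result$n_c, result$n_s)
  ell <- result$spectrum^2 / result$n_s
  sig <- ell > law$threshold
  if (any(!sig)) which(!sig)[1L] - 1L else length(sig)
}
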