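# SVD of the coupling matrix, the gPLV, phase conventions and circular
# summaries of the resulting vectors.

#' Singular value decomposition of a coupling matrix
#'
#' Computes the full SVD `C = U D V^H`. The largest singular value is the
#' generalized phase locking value (gPLV); the associated left/right
#' singular vectors are the LFP vector (per-channel complex weights) and the
#' spike vector (per-unit complex weights). The result is "raw": the global
#' phase of the vector pair is still arbitrary until [apply_conventions()]
#' is applied.
#'
#' @param C a [build_coupling_matrix()] result.
#' @return an object of class `gpla_result` with elements `gplv`, `spectrum`
#'   (all singular values, descending), `lfp_vector`, `spike_vector`
#'   (unit-norm), and bookkeeping (`mode`, `whitened`, `n_c`, `n_s`,
#'   `unit_counts`, `band`).
#' @export
gpla_decompose <- function(C) {
  stopifnot(inherits(C, "coupling_matrix"))
  if (!all(is.finite(Re(C$values)) & is.finite(Im(C$values))))
    stop("coupling matrix contains non-finite entries; exclude spikeless units upstream")
  sv <- svd(C$values)
  structure(
    list(gplv = sv$d[1L], spectrum = sv$d,
         lfp_vector = sv$u[, 1L], spike_vector = sv$v[, 1L],
         phi_d = NA_real_, complex_gplv = NA_complex_,
         mode = C$mode, whitened = C$whitened,
         n_c = nrow(C$values), n_s = ncol(C$values),
         unit_counts = C$unit_counts, units = C$units,
         channel_ids = C$channel_ids, band = C$band,
         conventions = list(rotated = FALSE, unwhitened = FALSE,
                            rescaled = FALSE, rotation_skipped = FALSE),
         n_significant = NA_integer_),
    class = "gpla_result"
  )
}

#' @export
print.gpla_result <- function(x, ...) {
  cat(sprintf("<gpla_result> gPLV = %.4g (%d channels x %d units, mode %s%s)\n",
              x$gplv, x$n_c, x$n_s, x$mode,
              if (x$whitened) ", whitened" else ""))
  if (!is.na(x$phi_d))
    cat(sprintf("  overall spike-LFP phase shift Phi_d = %.3f rad\n", x$phi_d))
  if (!is.na(x$n_significant))
    cat(sprintf("  significant singular values: %d\n", x$n_significant))
  invisible(x)
}

#' Apply the phase convention and post-processing to a GPLA result
#'
#' The SVD leaves a free global phase: both vectors can be rotated by the
#' same unit complex number without changing the factorization. The adopted
#' convention rotates both vectors by minus the phase of the mean LFP-vector
#' coefficient, so the mean LFP phase becomes zero and the mean spike-vector
#' phase reads as the overall spike-LFP shift `Phi_d = phi_LFP - phi_spike`.
#' Optionally, the LFP vector is mapped back to electrode space with the
#' unwhitening operator, and the spike vector is divided entrywise by the
#' square root of the per-unit spike counts (undoing the `1/sqrt(N)` entry
#' normalization of mode `"c"`) and renormalized to unit norm.
#'
#' `Phi_d` and the complex gPLV are computed from the convention-rotated
#' singular vectors, before unwhitening or rescaling.
#'
#' @param result a [gpla_decompose()] result.
#' @param unwhitening optional `n_c x n_c_eff` operator from
#'   [fit_unwhitening()].
#' @param counts optional per-unit total spike counts (defaults to the
#'   counts stored in the coupling matrix when `rescale = TRUE`).
#' @param rescale divide the spike vector by `sqrt(counts)` and renormalize.
#' @return the updated `gpla_result` with `phi_d`, `complex_gplv` and
#'   convention flags filled in.
#' @export
apply_conventions <- function(result, unwhitening = NULL, counts = NULL,
                              rescale = !is.null(counts)) {
  stopifnot(inherits(result, "gpla_result"))
  u <- result$lfp_vector
  v <- result$spike_vector
  su <- sum(u)
  sv_ <- sum(v)
  if (Mod(su) < 1e-12 * sqrt(length(u))) {
    warning("mean LFP-vector coefficient is ~0; phase rotation skipped")
    result$conventions$rotation_skipped <- TRUE
    phi_lfp <- NA_real_
  } else {
    phi_lfp <- Arg(su)
    u <- u * exp(-1i * phi_lfp)
    v <- v * exp(-1i * phi_lfp)
    result$conventions$rotated <- TRUE
  }
  phi_spike <- if (Mod(sv_) > 0) Arg(sv_) else NA_real_
  result$phi_d <- wrap_angle(phi_lfp - phi_spike)
  result$complex_gplv <- result$gplv * exp(-1i * result$phi_d)
  if (!is.null(unwhitening)) {
    if (ncol(unwhitening) != length(u))
      stop("unwhitening operator has ", ncol(unwhitening),
           " columns; LFP vector has length ", length(u))
    u <- drop(unwhitening %*% u)
    result$conventions$unwhitened <- TRUE
  }
  if (rescale) {
    counts <- counts %||% result$unit_counts
    if (length(counts) != length(v))
      stop("counts length does not match the spike vector")
    v <- v / sqrt(counts)
    v <- v / sqrt(sum(Mod(v)^2))
    result$conventions$rescaled <- TRUE
  }
  result$lfp_vector <- u
  result$spike_vector <- v
  result
}

#' Size-normalized gPLV
#'
#' Divides the gPLV by its maximum attainable value `sqrt(n_c * n_s)`
#' (reached when every pairwise PLV has modulus 1), giving a value in
#' `[0, 1]` comparable across recordings of different dimensions. Only
#' meaningful in `"plv"` mode, where entries are bounded by 1.
#'
#' @param result a `gpla_result`.
#' @return scalar in `[0, 1]`.
#' @export
normalize_gplv <- function(result) {
  stopifnot(inherits(result, "gpla_result"))
  if (result$mode != "plv")
    stop("size normalization requires mode 'plv' (entries of mode 'c' are unbounded)")
  result$gplv / sqrt(result$n_c * result$n_s)
}

#' Regression of singular-vector phase on modulus
#'
#' Unwraps the phases of a complex coefficient vector about their circular
#' mean and regresses them on the moduli by ordinary least squares, with an
#' F-test of zero slope. A negative, significant slope (phase decreasing
#' with modulus) is the signature of strong recurrent inhibition in the
#' spatial neural-field interpretation of the spike vector.
#'
#' @param v complex vector (at least 3 coefficients).
#' @return list with `slope` (rad per unit modulus), `intercept`, `p_value`,
#'   `n`, and `degenerate` flag (all moduli equal: slope undefined).
#' @export
phase_modulus_regression <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 3L) stop("need at least 3 coefficients")
  mods <- Mod(v)
  if (stats::sd(mods) < 1e-12 * max(mods, 1e-300)) {
    return(list(slope = NA_real_, intercept = NA_real_, p_value = NA_real_,
                n = n, degenerate = TRUE))
  }
  mu <- circ_mean(Arg(v))
  phases <- wrap_angle(Arg(v) - mu) + mu
  fit <- stats::lm(phases ~ mods)
  fs <- summary(fit)$fstatistic
  p <- stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_value = unname(p), n = n, degenerate = FALSE)
}

#' Maximum-likelihood von Mises fit to a sample of phases
#'
#' Returns the circular mean `mu` and concentration `kappa`, the latter via
#' the standard series approximations to the inverse of the ratio of Bessel
#' functions `A(kappa) = I1/I0`.
#'
#' @param phases numeric vector of angles (radians), length >= 2.
#' @param kappa_max cap on the concentration for (near-)degenerate samples.
#' @return list with `mu`, `kappa`, `rbar` (mean resultant length), `n`, and
#'   `uniform` flag set when the resultant is numerically zero.
#' @export
fit_phase_distribution <- function(phases, kappa_max = 1e4) {
  phases <- phases[is.finite(phases)]
  n <- length(phases)
  if (n < 2L) stop("need at least 2 phases")
  z <- mean(exp(1i * phases))
  rbar <- Mod(z)
  mu <- Arg(z)
  if (rbar < 1e-10) {
    return(list(mu = NA_real_, kappa = 0, rbar = rbar, n = n, uniform = TRUE))
  }
  kappa <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  list(mu = mu, kappa = min(kappa, kappa_max), rbar = rbar, n = n,
       uniform = FALSE)
}

#' Run the full GPLA chain on in-memory data
#'
#' Convenience driver used throughout the package: band-pass + analytic
#' signal, edge trimming, optional reduced-rank whitening, coupling matrix,
#' SVD and phase conventions (with unwhitening and spike-count rescaling
#' when whitening/mode "c" are active).
#'
#' @param raw a [raw_lfp()] object.
#' @param spikes a [spike_trains()] object (sample indices at the LFP rate).
#' @param band analysis band `c(f_lo, f_hi)` in Hz.
#' @param mode `"plv"` or `"c"` pairwise statistic.
#' @param whiten apply reduced-rank whitening (required by the analytical
#'   significance test; `mode` should then be `"c"`).
#' @param variance_threshold retained-variance fraction for whitening.
#' @param edge_margin_cycles trimmed margin in cycles of `band[1]`.
#' @param min_spikes unit inclusion threshold (total spikes).
#' @return list with `result` (a `gpla_result`), `coupling`
#'   (`coupling_matrix`), and (when whitening) `whitening` and `unwhitening`.
#' @export
gpla <- function(raw, spikes, band, mode = if (whiten) "c" else "plv",
                 whiten = FALSE, variance_threshold = 0.99,
                 edge_margin_cycles = 3, min_spikes = 50L) {
  an <- bandpass_analytic(raw, band)
  tr <- trim_edges(an, spikes, cycles = edge_margin_cycles)
  an <- tr$lfp; sp <- tr$spikes
  wm <- NULL; unw <- NULL
  use <- an
  if (whiten) {
    wm <- fit_whitening(an, variance_threshold)
    use <- apply_whitening(an, wm)
    unw <- fit_unwhitening(use, an)
  }
  C <- build_coupling_matrix(sp, use, mode = mode, min_spikes = min_spikes)
  res <- gpla_decompose(C)
  res <- apply_conventions(res, unwhitening = unw,
                           counts = if (mode == "c") C$unit_counts else NULL,
                           rescale = mode == "c")
  list(result = res, coupling = C, whitening = wm, unwhitening = unw)
}
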