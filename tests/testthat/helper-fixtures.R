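# Shared fixture builders for the test suite. Everything is generated in
# code; no files are read.

# A hand-built analytic LFP whose trials are arbitrary complex matrices,
# bypassing the filter (for exact-value tests of the coupling statistics).
make_analytic <- function(trials, fs = 100, band = c(8, 12),
                          whitened = FALSE) {
  if (is.matrix(trials)) trials <- list(trials)
  gpla:::new_analytic_lfp(trials, fs, band, whitened = whitened)
}

# A coupling_matrix object around a given complex matrix.
make_coupling <- function(values, mode = "c", whitened = TRUE,
                          unit_counts = rep(100L, ncol(values))) {
  structure(
    list(values = values, mode = mode, whitened = whitened,
         band = c(8, 12), unit_counts = unit_counts,
         units = paste0("u", seq_len(ncol(values))), excluded = character(),
         channel_ids = seq_len(nrow(values))),
    class = "coupling_matrix"
  )
}

# Spike trains at explicit sample indices, one trial by default.
make_spikes <- function(idx_per_unit, trial_samples, fs = 100) {
  spike_trains(lapply(idx_per_unit, function(i) list(as.integer(i))),
               trial_samples, fs)
}

# iid complex standard normal matrix (variance 1 per entry).
crandn <- function(n, m) {
  matrix(complex(real = rnorm(n * m, sd = sqrt(0.5)),
                 imaginary = rnorm(n * m, sd = sqrt(0.5))), n, m)
}

# von Mises sampler (Best & Fisher rejection scheme), used as an
# independent oracle for the circular fit.
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (u[2] < c_ * (2 - c_) || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
    }
  }
  gpla:::wrap_angle(out)
}

# Area under the ROC curve via the rank-sum statistic.
auc_ranksum <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
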