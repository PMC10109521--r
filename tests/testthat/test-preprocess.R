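# Band-limited analytic signal and reduced-rank whitening.

test_that("analytic signal of an in-band tone has unit modulus and the right phase velocity", {
  fs <- 250
  t <- (0:(4 * fs - 1)) / fs
  x <- cos(2 * pi * 20 * t)
  raw <- raw_lfp(matrix(x, 1), fs)
  an <- bandpass_analytic(raw, c(15, 25))
  core <- an$trials[[1]][1, 200:(length(t) - 200)]
  expect_lt(sd(Mod(core)) / mean(Mod(core)), 0.01)  # constant modulus
  expect_equal(mean(Mod(core)), 1, tolerance = 0.02)
  dphi <- diff(Arg(core))
  dphi <- dphi[abs(dphi) < pi]
  expect_equal(median(dphi), 2 * pi * 20 / fs, tolerance = 1e-3)
})

test_that("all-zero input maps to all-zero analytic output", {
  raw <- raw_lfp(matrix(0, 2, 500), 100)
  an <- bandpass_analytic(raw, c(8, 12))
  expect_equal(max(Mod(an$trials[[1]])), 0)
})

test_that("band validation and short trials are refused", {
  raw <- raw_lfp(matrix(rnorm(200), 1), 100)
  expect_error(bandpass_analytic(raw, c(10, 60)), "invalid")
  expect_error(bandpass_analytic(raw, c(-1, 10)), "invalid")
  short <- raw_lfp(matrix(rnorm(10), 1), 100)
  expect_error(bandpass_analytic(short, c(8, 12)), "too short")
})

test_that("two-tone input keeps only the in-band tone, matching an FFT-mask oracle", {
  fs <- 250
  n <- 8 * fs
  t <- (0:(n - 1)) / fs
  x <- 1.5 * cos(2 * pi * 20 * t + 0.3) + 3 * cos(2 * pi * 70 * t)
  an <- bandpass_analytic(raw_lfp(matrix(x, 1), fs), c(15, 25))
  # FFT band-mask oracle: zero everything outside the band, double positive
  # frequencies
  X <- fft(x)
  freq <- (0:(n - 1)) * fs / n
  keep <- freq >= 15 & freq <= 25
  h <- ifelse(keep, 2, 0)
  oracle <- fft(X * h, inverse = TRUE) / n
  core <- 500:(n - 500)
  expect_equal(mean(Mod(an$trials[[1]][1, core])), 1.5, tolerance = 0.02)
  expect_lt(max(Mod(an$trials[[1]][1, core] - oracle[core])), 0.05)
})

test_that("whitening rank selection follows the variance threshold", {
  fs <- 250
  set.seed(1)
  base <- cos(2 * pi * 20 * (0:(4 * fs - 1)) / fs)
  # identical signal on all channels -> rank 1
  raw <- raw_lfp(rbind(base, base, base, base), fs)
  an <- bandpass_analytic(raw, c(15, 25))
  expect_equal(fit_whitening(an)$n_c_eff, 1L)
  # independent equal-power signals -> all components needed at 0.99.
  # Oracle: count of eigenvalues of the brute-force covariance needed.
  n_c <- 4
  Z <- lapply(1:n_c, function(i)
    gpla:::analytic_signal(as.numeric(arima.sim(list(), 1000))))
  an2 <- make_analytic(do.call(rbind, Z))
  wm2 <- fit_whitening(an2, 0.99)
  L <- an2$trials[[1]]
  ev <- eigen((L %*% Conj(t(L))) / ncol(L), symmetric = TRUE)$values
  oracle_rank <- which(cumsum(ev) / sum(ev) >= 0.99)[1]
  expect_equal(wm2$n_c_eff, oracle_rank)
  expect_equal(wm2$n_c_eff, n_c)
  expect_equal(wm2$eigenvalues, ev, tolerance = 1e-8)
})

test_that("whitened trials have identity covariance on retained components", {
  set.seed(2)
  trials <- list(crandn(5, 400) * sqrt(c(4, 2, 1, .5, .2)),
                 crandn(5, 400) * sqrt(c(4, 2, 1, .5, .2)))
  an <- make_analytic(trials)
  wm <- fit_whitening(an, variance_threshold = 1)
  wh <- apply_whitening(an, wm)
  for (k in 1:2) {
    C <- gpla:::cov_analytic(wh$trials[[k]])
    expect_equal(Re(diag(C)), rep(1, wm$n_c_eff), tolerance = 1e-8)
    expect_lt(max(Mod(C - diag(wm$n_c_eff))), 1e-6)
  }
  # whitening already-whitened data changes covariance by < tolerance
  wh_as_plain <- make_analytic(wh$trials)
  wm2 <- fit_whitening(wh_as_plain, variance_threshold = 1)
  wh2 <- apply_whitening(wh_as_plain, wm2)
  expect_lt(max(Mod(gpla:::cov_analytic(wh2$trials[[1]]) -
                    gpla:::cov_analytic(wh$trials[[1]]))), 1e-6)
})

test_that("rank-1 input whitens to a single component carrying the shared signal", {
  z <- gpla:::analytic_signal(cos(2 * pi * 10 * (0:999) / 100))
  an <- make_analytic(rbind(2 * z, -1 * z, 0.5 * z))
  wm <- fit_whitening(an, 0.99)
  expect_equal(wm$n_c_eff, 1L)
  wh <- apply_whitening(an, wm)
  cc <- abs(sum(Conj(wh$trials[[1]][1, ]) * z)) /
    sqrt(sum(Mod(wh$trials[[1]][1, ])^2) * sum(Mod(z)^2))
  expect_equal(cc, 1, tolerance = 1e-8)
})

test_that("unwhitening round-trips full-rank data and predicts zero from zero", {
  set.seed(3)
  an <- make_analytic(crandn(4, 300))
  wm <- fit_whitening(an, variance_threshold = 1)
  wh <- apply_whitening(an, wm)
  W_inv <- fit_unwhitening(wh, an)
  rec <- W_inv %*% wh$trials[[1]]
  expect_lt(max(Mod(rec - an$trials[[1]])) / max(Mod(an$trials[[1]])), 1e-8)
  expect_equal(max(Mod(W_inv %*% matrix(0i, wm$n_c_eff, 5))), 0)
})

test_that("truncated reconstruction residual equals the discarded-component energy", {
  set.seed(4)
  L <- crandn(5, 500) * sqrt(c(8, 4, 2, 0.05, 0.02))
  an <- make_analytic(L)
  wm <- fit_whitening(an, 0.95)
  expect_lt(wm$n_c_eff, 5L)
  wh <- apply_whitening(an, wm)
  W_inv <- fit_unwhitening(wh, an)
  resid <- sum(Mod(an$trials[[1]] - W_inv %*% wh$trials[[1]])^2)
  # oracle: energy outside the retained eigenspace of the trial covariance
  ek <- eigen(gpla:::cov_analytic(L), symmetric = TRUE)
  discarded <- sum(ek$values[(wm$n_c_eff + 1):5]) * ncol(L)
  expect_equal(resid, discarded, tolerance = 1e-6)
})

test_that("degenerate all-zero input is refused by fit_whitening", {
  an <- make_analytic(matrix(0i, 3, 100))
  expect_error(fit_whitening(an), "degenerate")
})

test_that("edge trimming shifts spikes consistently", {
  fs <- 100
  raw <- raw_lfp(matrix(rnorm(fs * 10), 1), fs)
  an <- bandpass_analytic(raw, c(8, 12))
  m <- ceiling(3 * fs / 8)
  sp <- make_spikes(list(c(5L, m + 50L, 900L)), fs * 10, fs)
  tr <- trim_edges(an, sp)
  expect_equal(ncol(tr$lfp$trials[[1]]), fs * 10 - 2 * m)
  expect_equal(tr$spikes$times[[1]][[1]], c(50L, 900L - m))
})
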