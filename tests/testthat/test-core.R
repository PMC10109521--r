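# SVD core: gPLV extraction, conventions, and circular utilities.

test_that("exact rank-1 matrices are recovered up to a global phase", {
  set.seed(11)
  a <- crandn(6, 1); a <- a / sqrt(sum(Mod(a)^2))
  b <- crandn(4, 1); b <- b / sqrt(sum(Mod(b)^2))
  d <- 3.7
  res <- gpla_decompose(make_coupling(d * a %*% Conj(t(b))))
  expect_equal(res$gplv, d, tolerance = 1e-10)
  expect_equal(Mod(sum(Conj(res$lfp_vector) * a)), 1, tolerance = 1e-10)
  expect_equal(Mod(sum(Conj(res$spike_vector) * b)), 1, tolerance = 1e-10)
  expect_lt(res$spectrum[2], 1e-10)
})

test_that("the all-ones matrix has gPLV sqrt(n_c * n_s) and normalized gPLV 1", {
  C <- make_coupling(matrix(1 + 0i, 5, 8), mode = "plv", whitened = FALSE)
  res <- gpla_decompose(C)
  expect_equal(res$gplv, sqrt(5 * 8), tolerance = 1e-12)
  expect_equal(normalize_gplv(res), 1, tolerance = 1e-12)
  zero <- gpla_decompose(make_coupling(matrix(0i, 5, 8), mode = "plv",
                                       whitened = FALSE))
  expect_equal(normalize_gplv(zero), 0)
})

test_that("normalized gPLV of a homogeneous PLV-rho population equals |rho|", {
  rho <- 0.37 * exp(1i * 1.1)
  res <- gpla_decompose(make_coupling(matrix(rho, 7, 11), mode = "plv",
                                      whitened = FALSE))
  expect_equal(normalize_gplv(res), Mod(rho), tolerance = 1e-12)
})

test_that("normalization is refused in mode c", {
  res <- gpla_decompose(make_coupling(crandn(3, 3), mode = "c"))
  expect_error(normalize_gplv(res), "plv")
})

test_that("the singular spectrum matches a brute-force eig(C^H C) oracle", {
  set.seed(12)
  C <- crandn(20, 15)
  res <- gpla_decompose(make_coupling(C))
  oracle <- sqrt(sort(Re(eigen(Conj(t(C)) %*% C, symmetric = TRUE)$values),
                      decreasing = TRUE))
  expect_equal(res$spectrum, oracle, tolerance = 1e-10)
})

test_that("the phase convention zeroes the mean LFP phase and records Phi_d", {
  set.seed(13)
  res <- apply_conventions(gpla_decompose(make_coupling(crandn(10, 12))))
  expect_lt(abs(Arg(sum(res$lfp_vector))), 1e-10)
  expect_equal(gpla:::wrap_angle(-Arg(sum(res$spike_vector)) - res$phi_d), 0,
               tolerance = 1e-10)
  expect_equal(Mod(res$complex_gplv), res$gplv)
})

test_that("a global phase on C leaves the LFP vector and phase-referenced spike vector invariant, shifting Phi_d", {
  set.seed(14)
  C <- crandn(8, 6)
  theta <- 0.9
  r1 <- apply_conventions(gpla_decompose(make_coupling(C)))
  r2 <- apply_conventions(gpla_decompose(make_coupling(C * exp(1i * theta))))
  expect_equal(r1$lfp_vector, r2$lfp_vector, tolerance = 1e-8)
  expect_equal(gpla:::wrap_angle(r2$phi_d - r1$phi_d), theta,
               tolerance = 1e-8)
  # spike vector re-referenced to its own mean phase is invariant
  ref <- function(v) v * exp(-1i * Arg(sum(v)))
  expect_equal(ref(r1$spike_vector), ref(r2$spike_vector), tolerance = 1e-8)
})

test_that("permuting channels or units permutes vectors without changing the gPLV", {
  set.seed(15)
  C <- crandn(7, 9)
  pc <- sample(7); pu <- sample(9)
  r <- apply_conventions(gpla_decompose(make_coupling(C)))
  rp <- apply_conventions(gpla_decompose(make_coupling(C[pc, pu])))
  expect_equal(rp$gplv, r$gplv, tolerance = 1e-10)
  expect_equal(rp$lfp_vector, r$lfp_vector[pc], tolerance = 1e-8)
})

test_that("spike-count rescaling follows the Hadamard-division rule", {
  res <- gpla_decompose(make_coupling(matrix(1 + 0i, 3, 2)))
  res$spike_vector <- c(1, 1) / sqrt(2)
  out <- apply_conventions(res, counts = c(4, 1), rescale = TRUE)
  expect_equal(Mod(out$spike_vector), c(1, 2) / sqrt(5), tolerance = 1e-10)
})

test_that("equal spike counts leave the spike vector unchanged by rescaling", {
  set.seed(16)
  raw <- gpla_decompose(make_coupling(crandn(5, 4)))
  a <- apply_conventions(raw)
  b <- apply_conventions(raw, counts = rep(7, 4), rescale = TRUE)
  expect_equal(a$spike_vector, b$spike_vector, tolerance = 1e-10)
})

test_that("rank-1 plus small noise recovers the planted structure", {
  set.seed(17)
  a <- crandn(30, 1); a <- a / sqrt(sum(Mod(a)^2))
  b <- crandn(25, 1); b <- b / sqrt(sum(Mod(b)^2))
  d <- 5
  E <- 0.02 * crandn(30, 25)
  eps <- svd(E)$d[1]
  res <- gpla_decompose(make_coupling(d * a %*% Conj(t(b)) + E))
  expect_lte(abs(res$gplv - d), eps + 1e-12)
  expect_gte(Mod(sum(Conj(res$lfp_vector) * a)), 1 - (eps / d)^2)
})

test_that("phase-modulus regression recovers an exact linear relation and flags degeneracy", {
  mods <- seq(0.2, 1, length.out = 20)
  v <- mods * exp(1i * (-2 * mods + 0.5))
  fit <- suppressWarnings(phase_modulus_regression(v))
  expect_equal(fit$slope, -2, tolerance = 1e-8)
  expect_lt(fit$p_value, 1e-12)
  dg <- phase_modulus_regression(rep(exp(1i * 0.3), 5))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$slope))
  expect_error(phase_modulus_regression(c(1 + 0i, 2)), "at least 3")
})

test_that("phase-modulus p-values are calibrated under independence", {
  set.seed(18)
  p <- replicate(200, {
    v <- runif(15, 0.2, 1) * exp(1i * runif(15, -1, 1))
    phase_modulus_regression(v)$p_value
  })
  expect_gt(mean(p), 0.35)
  expect_lt(mean(p), 0.65)
  expect_lte(mean(p < 0.05), 0.12)
})

test_that("von Mises fitting recovers parameters and handles edge cases", {
  set.seed(19)
  x <- rvonmises(10000, 1.0, 4.0)
  fit <- fit_phase_distribution(x)
  expect_equal(fit$mu, 1.0, tolerance = 0.05)
  expect_equal(fit$kappa, 4.0, tolerance = 0.4)
  allsame <- fit_phase_distribution(rep(0.7, 10))
  expect_equal(allsame$mu, 0.7, tolerance = 1e-8)
  expect_equal(allsame$kappa, 1e4)  # capped
  unif <- fit_phase_distribution(seq(-pi, pi, length.out = 721)[-1])
  expect_lt(unif$kappa, 1e-6)
})
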