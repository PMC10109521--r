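# Jitter surrogates and the Marchenko-Pastur analytical test.

test_that("both jitter schemes preserve per-window and total spike counts", {
  set.seed(20)
  fs <- 100
  idx <- list(sort(sample(1000, 200)), sort(sample(1000, 150)))
  sp <- make_spikes(idx, 1000, fs)
  w_s <- 0.37  # 37-sample windows, last window partial
  for (jit in list(interval_jitter, group_preserved_jitter)) {
    out <- jit(sp, w_s)
    expect_equal(spike_counts(out), spike_counts(sp))
    w <- round(w_s * fs)
    for (m in 1:2) {
      expect_equal(table((out$times[[m]][[1]] - 1) %/% w),
                   table((sp$times[[m]][[1]] - 1) %/% w))
      expect_true(all(out$times[[m]][[1]] >= 1 & out$times[[m]][[1]] <= 1000))
    }
  }
})

test_that("a one-sample jitter window is the identity", {
  sp <- make_spikes(list(c(3L, 10L, 99L)), 100, 100)
  out <- interval_jitter(sp, 1 / 100)
  expect_identical(out$times[[1]][[1]], sp$times[[1]][[1]])
})

test_that("group-preserved jitter keeps within-window relative timing modulo the window", {
  set.seed(21)
  sp <- make_spikes(list(sort(sample(400, 120)), sort(sample(400, 90))), 400,
                    100)
  w <- 40L
  out <- group_preserved_jitter(sp, w / 100)
  # spikes of different units in the same window keep their differences mod w
  for (win in 0:9) {
    a0 <- sp$times[[1]][[1]]; b0 <- sp$times[[2]][[1]]
    a1 <- out$times[[1]][[1]]; b1 <- out$times[[2]][[1]]
    in_w <- function(v) sort(v[(v - 1) %/% w == win])
    if (length(in_w(a0)) && length(in_w(b0))) {
      d0 <- (in_w(a0)[1] - in_w(b0)[1]) %% w
      # find the shifted counterparts: same multiset of (x - 1) %% w offsets
      d1 <- outer(in_w(a1), in_w(b1), function(x, y) (x - y) %% w)
      expect_true(d0 %in% d1)
    }
  }
})

test_that("jitter at one oscillation cycle collapses the locking of a coherent train", {
  set.seed(22)
  f0 <- 10; fs <- 100
  ph <- 2 * pi * f0 * (0:9999) / fs
  an <- make_analytic(matrix(exp(1i * ph), 1))
  # perfectly locked: spikes at phase 0
  idx <- which(abs(gpla:::wrap_angle(ph)) < 1e-9)
  sp <- make_spikes(list(idx), 10000, fs)
  expect_gt(Mod(pairwise_plv(sp, an)), 0.99)
  n <- length(idx)
  plvs <- replicate(100, Mod(pairwise_plv(interval_jitter(sp, 1 / f0), an)))
  expect_lt(median(plvs), 2 / sqrt(n))
  plvs_g <- replicate(100,
    Mod(pairwise_plv(group_preserved_jitter(sp, 1 / f0), an)))
  expect_lt(median(plvs_g), 2 / sqrt(n))
})

test_that("surrogate p-values follow the add-one rule and are seed-reproducible", {
  set.seed(23)
  f0 <- 10; fs <- 100
  ph <- 2 * pi * f0 * (0:4999) / fs
  an <- make_analytic(matrix(exp(1i * ph), 1), fs = fs, band = c(8, 12))
  idx <- which(abs(gpla:::wrap_angle(ph)) < 0.2)
  sp <- make_spikes(list(idx), 5000, fs)
  r1 <- surrogate_test(sp, an, n_surrogates = 99, seed = 5)
  expect_equal(r1$p_value, 0.01)   # observed above every surrogate
  r2 <- surrogate_test(sp, an, n_surrogates = 99, seed = 5)
  expect_identical(r1$surrogates, r2$surrogates)
  expect_error(surrogate_test(sp, an, n_surrogates = 5), "19")
})

test_that("the MP law and threshold take their closed-form values", {
  law <- mp_threshold(10, 10)
  expect_equal(law$alpha, 1)
  expect_equal(law$threshold, 4)
  law2 <- mp_threshold(25, 100)
  expect_equal(law2$alpha, 0.25)
  expect_equal(law2$threshold, 2.25)
  expect_equal(law2$a, 0.25)
})

test_that("the MP density integrates to one and vanishes at the support edges", {
  for (alpha in c(0.2, 0.5, 0.9)) {
    a <- (1 - sqrt(alpha))^2; b <- (1 + sqrt(alpha))^2
    expect_equal(integrate(mp_density, a, b, alpha = alpha,
                           rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
    expect_equal(mp_density(c(a, b, a - 0.1, b + 0.1), alpha), rep(0, 4))
  }
  expect_equal(mp_cdf(c(0, 4), 0.5), c(0, 1))
})

test_that("MP support brackets the squared singular values of an iid matrix", {
  set.seed(24)
  n_c <- 50; n_u <- 200
  law <- mp_threshold(n_c, n_u)
  ell <- svd(crandn(n_c, n_u))$d^2 / n_u
  expect_lt(mean(ell < law$a - 0.05 | ell > law$b + 0.05), 0.01)
})

test_that("the analytic test is calibrated on null matrices and refuses wrong inputs", {
  set.seed(25)
  rejections <- vapply(1:20, function(i) {
    analytic_test(make_coupling(crandn(100, 100)))$significant
  }, logical(1))
  expect_lte(mean(rejections), 0.05)
  expect_error(analytic_test(make_coupling(crandn(5, 5), mode = "plv")),
               "mode")
  expect_error(analytic_test(make_coupling(crandn(5, 5), whitened = FALSE)),
               "whitened")
})

test_that("a strongly planted rank-1 signal is always detected", {
  set.seed(26)
  n_c <- 50; n_u <- 100
  law <- mp_threshold(n_c, n_u)
  d <- 2 * sqrt(n_u * law$threshold)   # well above the bound
  hits <- vapply(1:20, function(i) {
    a <- crandn(n_c, 1); a <- a / sqrt(sum(Mod(a)^2))
    b <- crandn(n_u, 1); b <- b / sqrt(sum(Mod(b)^2))
    C <- d * a %*% Conj(t(b)) + crandn(n_c, n_u)
    analytic_test(make_coupling(C))$significant
  }, logical(1))
  expect_true(all(hits))
})

test_that("with a single unit the test reduces to a threshold on |c|^2", {
  set.seed(27)
  cvec <- crandn(30, 1)
  rep_ <- analytic_test(make_coupling(cvec))
  expect_equal(rep_$statistic, sum(Mod(cvec)^2), tolerance = 1e-10)
  expect_equal(rep_$threshold, (1 + sqrt(30))^2)
})

test_that("significant components are counted downward to the first failure", {
  set.seed(28)
  n_c <- 40; n_u <- 100
  law <- mp_threshold(n_c, n_u)
  d1 <- 1.8 * sqrt(n_u * law$threshold)
  d2 <- 1.4 * sqrt(n_u * law$threshold)
  U <- qr.Q(qr(crandn(n_c, 2)))
  V <- qr.Q(qr(crandn(n_u, 2)))
  C <- U %*% diag(c(d1, d2)) %*% Conj(t(V)) + crandn(n_c, n_u)
  rep_ <- analytic_test(make_coupling(C))
  expect_equal(rep_$n_significant, 2L)
  res <- gpla_decompose(make_coupling(C))
  expect_equal(count_significant(res), 2L)
})
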