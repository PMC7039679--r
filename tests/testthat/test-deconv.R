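test_that("the miniature-event kernel peaks at exactly 20 pA", {
  for (kin in list(c(0.3, 5), c(0.5, 10), c(1, 30))) {
    k <- make_kernel(kin[1], kin[2])
    expect_identical(max(k$samples), 20)
  }
  # resolution invariance
  expect_identical(max(make_kernel(0.5, 10, dt = 2.5e-5)$samples), 20)
  # decays out: terminal sample below 1% of peak
  k <- make_kernel(0.5, 10, length_ms = 100)
  expect_lt(k$samples[length(k$samples)], 0.2)
  expect_error(make_kernel(10, 5), "degenerate")
  expect_error(make_kernel(0.5, 10, length_ms = 20), "5 \\* decay_tau")
})

test_that("binomial smoothing: identity, DC preservation, Gaussian limit", {
  x <- rnorm(500)
  expect_identical(binomial_smooth(x, 0), x)
  expect_equal(binomial_smooth(rep(3.5, 100), 50), rep(3.5, 100))

  # unit impulse after 50 repetitions: mass-preserving, Gaussian-like with
  # variance 50/2 sample units (CLT for the 1/4,1/2,1/4 kernel)
  n <- 401
  imp <- numeric(n); imp[201] <- 1
  sm <- binomial_smooth(imp, 50)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  idx <- seq_len(n) - 201
  expect_equal(sum(sm * idx^2), 50 / 2, tolerance = 0.01)
  expect_equal(which.max(sm), 201)
})

test_that("deconvolution of the kernel itself is a unit impulse", {
  k <- make_kernel(0.5, 10)
  n <- 8192
  tr <- numeric(n)
  i0 <- 2001L
  tr[i0 + seq_along(k$samples) - 1] <- k$samples
  rr <- release_rate(tr, k)
  auc <- sum(rr$rate) * rr$dt
  expect_equal(auc, 1, tolerance = 0.01)
  expect_identical(which.max(rr$rate), i0)
  # mass concentrated around the impulse (the spectral floor spreads a few
  # percent of it over neighbouring samples)
  expect_gt(sum(rr$rate[(i0 - 5):(i0 + 5)]) * rr$dt, 0.95)
})

test_that("two scaled impulses deconvolve with the right AUC ratio", {
  k <- make_kernel(0.5, 10)
  dt <- k$dt
  n <- 16384
  tr <- numeric(n)
  add_at <- function(x, i0, scale) {
    idx <- i0 + seq_along(k$samples) - 1
    x[idx] <- x[idx] + scale * k$samples
    x
  }
  i1 <- 2001
  i2 <- i1 + round(10e-3 / dt)
  tr <- add_at(tr, i1, 3)
  tr <- add_at(tr, i2, 1)
  rr <- release_rate(tr, k)
  mid <- (i1 + i2) %/% 2
  auc1 <- sum(rr$rate[1:mid]) * dt
  auc2 <- sum(rr$rate[(mid + 1):n]) * dt
  expect_equal(auc1 / auc2, 3, tolerance = 0.02)
  expect_equal(auc1 + auc2, 4, tolerance = 0.02 * 4)
})

test_that("deconvolution is linear and maps zero to zero", {
  k <- make_kernel(0.5, 10)
  expect_true(all(release_rate(numeric(4096), k)$rate == 0))
  set.seed(1)
  tr <- binomial_smooth(rnorm(4096), 50)
  r1 <- release_rate(tr, k)$rate
  r3 <- release_rate(3 * tr, k)$rate
  expect_equal(r3, 3 * r1, tolerance = 1e-9)
})

test_that("reconvolving the estimated rate reproduces the smoothed train", {
  k <- make_kernel(0.5, 10)
  pt <- 0.05 + (0:9) / 50
  g <- gen_synaptic_trace(pt, n_sweeps = 1, g_gaba = 1.5, cv_q = 0.3,
                          v_hold = -40, e_gaba = -60, noise_sd = 0,
                          async_fraction = 0.3, seed = 9)
  x <- binomial_smooth(g$sweeps[[1]]$samples, 50)
  rr <- release_rate(x, k)
  # quantal conservation: total AUC = trace charge / kernel charge
  expect_rel(sum(rr$rate) * rr$dt, sum(x) / sum(k$samples), 0.02)
  # reconstruction: rate * kernel = smoothed trace, < 5% relative RMS
  recon <- stats::convolve(rr$rate * rr$dt, rev(k$samples), type = "open")
  recon <- recon[seq_along(x)]
  rms <- sqrt(mean((recon - x)^2)) / sqrt(mean(x^2))
  expect_lt(rms, 0.05)
})

test_that("synchronicity bins partition the inter-pulse interval", {
  # handcrafted rate: equal mass in the sync and async bin of each pulse
  dt <- 5e-5
  n <- 8000
  rate <- numeric(n)
  onsets <- c(0.1, 0.12)
  put <- function(rate, t0, q) {
    i <- round(t0 / dt) + 1
    rate[i] <- rate[i] + q / dt
    rate
  }
  rate <- put(rate, 0.101, 2)   # sync bin of pulse 1
  rate <- put(rate, 0.110, 2)   # async bin of pulse 1 ([0.105, 0.12])
  rate <- put(rate, 0.121, 5)   # sync bin of pulse 2
  rate <- put(rate, 0.130, 5)   # async bin of pulse 2 (virtual next onset 0.14)
  rr <- structure(list(rate = rate, dt = dt, epsilon = 0), class = "pk_release_rate")
  tab <- synchronicity(rr, onsets)
  expect_equal(tab$sync_auc, c(2, 5), tolerance = 1e-9)
  expect_equal(tab$async_auc, c(2, 5), tolerance = 1e-9)
  expect_equal(tab$sr, c(1, 1), tolerance = 1e-9)

  # all release synchronous: async at floor -> SR flagged undefined
  rate2 <- numeric(n)
  rate2 <- put(rate2, 0.101, 3)
  rr2 <- structure(list(rate = rate2, dt = dt, epsilon = 0), class = "pk_release_rate")
  tab2 <- synchronicity(rr2, onsets)
  expect_equal(tab2$sync_auc[1], 3, tolerance = 1e-9)
  expect_true(is.na(tab2$sr[1]))
})

test_that("SR declines across trains with a rising asynchronous fraction", {
  k <- make_kernel(0.5, 10)
  pt <- 0.1 + (0:24) / 50
  g <- gen_synaptic_trace(pt, n_sweeps = 10, g_gaba = 1.5, cv_q = 0.3,
                          v_hold = -40, e_gaba = -60, noise_sd = 0.5,
                          async_fraction = seq(0, 0.6, length.out = 25),
                          seed = 5)
  dec <- deconvolve_train(g$sweeps, k, pulse_times = pt)
  sm <- dec$sr_mean
  ok <- !is.na(sm$sr)
  expect_gt(sum(ok), 15)
  rho <- stats::cor(sm$pulse[ok], sm$sr[ok], method = "spearman")
  expect_lt(rho, -0.8)
})

test_that("estimated SR matches the generator's quantal counts ratio", {
  # noiseless train, constant async fraction, many sweeps: counts oracle
  k <- make_kernel(0.5, 10)
  pt <- 0.1 + (0:9) / 50
  g <- gen_synaptic_trace(pt, n_sweeps = 40, g_gaba = 1.5, v_hold = -40,
                          e_gaba = -60, noise_sd = 0,
                          async_fraction = 0.5, async_window_ms = 15, seed = 21)
  dec <- deconvolve_train(g$sweeps, k, pulse_times = pt)
  # oracle: quanta counts in each bin from the generator's release times
  truth <- g$truth
  per <- dec$sr_mean[1:9, ]  # last pulse's async window has no following events
  counts_sr <- vapply(1:9, function(i) {
    sync_n <- sum(truth$release_time >= pt[i] & truth$release_time < pt[i] + 5e-3)
    async_n <- sum(truth$release_time >= pt[i + 1] - 15e-3 & truth$release_time < pt[i + 1])
    sync_n / async_n
  }, numeric(1))
  est <- per$sync_auc / per$async_auc
  expect_lt(median(abs(est - counts_sr) / counts_sr), 0.10)
})
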