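strict_params <- function(s_min = 2.5, g = 0.8) {
  deconv_params(g = g, sn = 1, s_min = s_min, optimize_g = 0,
                merge_window_s = 0, candidate_factor = 1)
}

test_that("g estimation recovers AR(1) dynamics and rejects white noise", {
  set.seed(31)
  x <- as.numeric(stats::filter(rnorm(10000), 0.9, "recursive"))
  expect_lt(abs(estimate_g(x) - 0.9), 0.03)
  expect_lt(estimate_g(rnorm(10000)), 0.1)
  # clipping contract over assorted inputs
  for (rep in 1:10) {
    g <- estimate_g(rnorm(500) + sin(seq_len(500) / 10))
    expect_gte(g, 0)
    expect_lte(g, 0.999)
  }
  expect_error(estimate_g(rep(1, 100)), "zero")
})

test_that("spectral noise estimate is calibrated on white noise", {
  set.seed(32)
  sn <- replicate(20, estimate_noise_sd(rnorm(1200, 0, 0.7)))
  expect_lt(abs(mean(sn) - 0.7), 0.07)
})

test_that("deconvolution recovers planted spikes exactly on noiseless traces", {
  # empty signal
  f0 <- deconvolve_oasis(rep(0, 100), strict_params(), 20)
  expect_equal(nrow(f0$events), 0)
  expect_equal(f0$denoised, rep(0, 100))

  # planted spikes {(100, 5), (400, 4)} at g = 0.95 on 1200 frames
  g <- 0.95
  s <- numeric(1200); s[100] <- 5; s[400] <- 4
  y <- ar1_trace(s, g)
  fit <- deconvolve_oasis(y, strict_params(g = g), 20)
  expect_equal(fit$events$frame, c(100L, 400L))
  expect_equal(fit$events$amplitude, c(5, 4), tolerance = 1e-6)
  expect_lt(sum((y - fit$denoised)^2), 1e-12)

  # a third spike below s_min is suppressed
  s[700] <- 1.0
  y2 <- ar1_trace(s, g)
  fit2 <- deconvolve_oasis(y2, strict_params(g = g), 20)
  expect_equal(fit2$events$frame, c(100L, 400L))

  expect_error(deconvolve_oasis(y, deconv_params(g = 1.5)), "g must be")
})

test_that("pooled solution equals brute-force enumeration on noiseless toys", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(10:16, 1)
    s <- numeric(n)
    nev <- sample(0:2, 1)
    if (nev) {
      pos <- sort(sample(3:(n - 1), nev))
      if (nev == 2 && diff(pos) < 2) pos[2] <- pos[2] + 1L
      s[pos] <- runif(nev, 2.6, 6)
    }
    y <- ar1_trace(s, 0.8)
    bf <- brute_force_deconv(y, 0.8, 2.5)
    fit <- deconvolve_oasis(y, strict_params(g = 0.8), 20)
    expect_identical(fit$events$frame, as.integer(bf$support))
    if (length(bf$support))
      expect_equal(fit$events$amplitude, bf$amplitude, tolerance = 1e-6)
  }
  # thresholding contract: mixed sub/supra-threshold spikes on a 20-frame toy
  s <- numeric(20); s[5] <- 5; s[11] <- 1.0; s[16] <- 4
  y <- ar1_trace(s, 0.8)
  bf <- brute_force_deconv(y, 0.8, 2.5)
  fit <- deconvolve_oasis(y, strict_params(g = 0.8), 20)
  expect_identical(fit$events$frame, as.integer(bf$support))
  expect_identical(fit$events$frame, c(5L, 16L))
})

test_that("residual and impulse count are monotone in s_min", {
  set.seed(34)
  grid <- c(0.5, 1, 1.5, 2, 2.5, 3, 4)
  for (rep in 1:10) {
    n <- 20
    s <- numeric(n)
    pos <- sort(sample(3:(n - 1), 2))
    s[pos] <- runif(2, 1, 6)
    y <- ar1_trace(s, 0.8) + rnorm(n, 0, 0.05)
    res <- sapply(grid, function(sm) {
      f <- deconvolve_oasis(y, strict_params(s_min = sm), 20)
      c(sse = sum((y - f$denoised)^2), k = sum(f$spikes >= sm - 1e-9))
    })
    expect_true(all(diff(res["sse", ]) >= -1e-9))
    expect_true(all(diff(res["k", ]) <= 0))
  }
})

test_that("oasis_fit methods expose the fit coherently", {
  g <- 0.9
  s <- numeric(300); s[50] <- 4
  y <- ar1_trace(s, g) + rnorm(300, 0, 0.01)
  fit <- deconvolve_oasis(y, strict_params(g = g), 20)
  expect_s3_class(fit, "oasis_fit")
  expect_equal(unname(coef(fit)["g"]), g)
  expect_equal(fitted(fit), fit$denoised)
  expect_equal(residuals(fit), y - fit$denoised)
  expect_output(print(fit), "events")
})

test_that("event rates average over repeat recordings", {
  expect_equal(event_rate(list(seq_len(12)), 60), 0.2)
  expect_equal(event_rate(list(1:6, 1:18), 60), 0.2)
  expect_error(event_rate(list(), 60), "no recordings")
  ev <- data.frame(time_s = c(1, 2, 3))
  expect_equal(event_rate(list(ev), 30), 0.1)
})

test_that("peak amplitudes are read off the dF/F trace at event times", {
  expect_length(peak_amplitudes(rnorm(100), integer(0)), 0)
  k <- geci_kernel("custom", amplitude_dff = 1.0, rise_s = 0.07, decay_s = 0.7)
  raw <- render_trace(10, k, 60, 20, f0 = 100)
  pt <- process_trace(raw, baseline_order = 0, okada_iterations = 0)
  onset <- 10 * 20 + 1
  pk <- peak_amplitudes(pt$dff, onset, 20, window_s = 1)
  expect_lt(abs(pk - 1.0), 0.02 + 0.02)  # peak sampling + baseline offset
  # truncated window at the trace end is tolerated
  expect_length(peak_amplitudes(pt$dff, length(pt$dff) - 2L, 20), 1)
})

test_that("brighter kernels yield proportionally larger measured amplitudes", {
  set.seed(36)
  measure <- function(kern, n_ev = 120) {
    amps <- numeric(0)
    while (length(amps) < n_ev) {
      tt <- runif(1, 2, 55)
      raw <- render_trace(tt, kern, 60, 20, f0 = 100, noise_sd = 0.03)
      pt <- process_trace(raw)
      fit <- detect_events(pt)
      if (nrow(fit$events) == 1)
        amps <- c(amps, peak_amplitudes(pt$dff, fit$events$frame, 20))
    }
    mean(amps)
  }
  m6 <- measure(geci_kernel("6s-like"))                      # amplitude 1.0
  m7 <- measure(geci_kernel("7b-like"))                      # amplitude 1.5
  expect_gt(m7 / m6, 1.35)
  expect_lt(m7 / m6, 1.65)
})
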