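test_that("Poisson event trains have the right moments and determinism", {
  expect_length(simulate_event_train(0, 60, seed = 1), 0)
  expect_error(simulate_event_train(-0.1, 60), "non-negative")

  expect_identical(simulate_event_train(0.3, 60, seed = 7),
                   simulate_event_train(0.3, 60, seed = 7))

  set.seed(11)
  counts <- replicate(2000, length(simulate_event_train(0.2, 60)))
  # mean within 3 SE of lambda * T = 12
  expect_lt(abs(mean(counts) - 12), 3 * sqrt(12 / 2000))
  # index of dispersion ~ 1 for a Poisson process
  expect_gt(var(counts) / mean(counts), 0.9)
  expect_lt(var(counts) / mean(counts), 1.1)

  tr <- simulate_event_train(0.5, 30, seed = 3)
  expect_true(all(diff(tr) > 0))
  expect_true(all(tr >= 0 & tr < 30))
})

test_that("trace renderer implements the forward model", {
  k <- geci_kernel("7b-like", amplitude_dff = 1)
  # identity: no events, no drift, no noise, no bleach
  flat <- render_trace(numeric(0), k, 10, 20, f0 = 50)
  expect_equal(flat, rep(50, 200))

  # single event: max dF/F equals the kernel amplitude within 2% sampling
  tr <- render_trace(5, k, 60, 20, f0 = 100)
  expect_lt(abs(max(tr / 100 - 1) - 1), 0.02)

  # bleach-only trace matches the biexponential pointwise
  bl <- c(0.3, 2, 0.7, 200)
  tr2 <- render_trace(numeric(0), k, 60, 20, f0 = 1, bleach = bl)
  t <- (0:1199) / 20
  expect_equal(tr2, bl[1] * exp(-t / bl[2]) + bl[3] * exp(-t / bl[4]))

  # additivity in events (noise off): union = sum of deviations
  a <- render_trace(c(5, 20), k, 60, 20, f0 = 100)
  b <- render_trace(c(12), k, 60, 20, f0 = 100)
  ab <- render_trace(c(5, 12, 20), k, 60, 20, f0 = 100)
  expect_equal(ab - 100, (a - 100) + (b - 100), tolerance = 1e-12)
})

test_that("kernel evaluation peaks at amplitude_dff and presets are ordered", {
  k <- geci_kernel("6s-like")
  tt <- seq(0, 10, by = 1e-4)
  expect_equal(max(kernel_eval(k, tt)), k$amplitude_dff, tolerance = 1e-6)
  expect_equal(kernel_eval(k, c(-1, -0.01)), c(0, 0))
  # the 7b-like preset is brighter than 6s-like
  expect_gt(geci_kernel("7b-like")$amplitude_dff,
            geci_kernel("6s-like")$amplitude_dff)
  expect_error(geci_kernel("custom", amplitude_dff = 1, rise_s = 2, decay_s = 1),
               "rise_s < decay_s")
})

test_that("spine population reproduces configured survival probabilities", {
  # large flat population: 2000 spines, survival 0.6 vs 0.85 by proximity
  cf <- c(intercept = log(0.6 / 0.4), abeta = 0,
          astro = log(0.85 / 0.15) - log(0.6 / 0.4),
          abeta_astro = 0, tboa_abeta_astro = 0)
  cfg <- sim_config(n_animals = 10, slices_per_animal = 4,
                    spines_per_dendrite = 50, survival_logit = cf,
                    p_proximity = 0.5, seed = 5)
  pop <- simulate_spine_population(cfg)
  sp <- pop$spines
  for (gr in list(list(prox = 0, p = 0.6), list(prox = 1, p = 0.85))) {
    d <- sp[sp$proximal == gr$prox, ]
    se <- sqrt(gr$p * (1 - gr$p) / nrow(d))
    expect_lt(abs(mean(d$survived) - gr$p), 3 * se)
  }
})

test_that("null survival model gives equal fractions and multiplier 1 gives flat rates", {
  cf0 <- c(intercept = 1, abeta = 0, astro = 0, abeta_astro = 0,
           tboa_abeta_astro = 0)
  cfg <- sim_config(n_animals = 8, spines_per_dendrite = 40,
                    survival_logit = cf0, abeta_rate_multiplier = 1,
                    lost_rate_multiplier = 1, seed = 9)
  pop <- simulate_spine_population(cfg)
  sp <- merge(pop$spines, pop$truth[, c("spine_id", "true_pre_rate",
                                        "true_post_rate")])
  p0 <- plogis(1)
  for (ab in 0:1) {
    d <- sp[sp$abeta == ab, ]
    expect_lt(abs(mean(d$survived) - p0), 3 * sqrt(p0 * (1 - p0) / nrow(d)))
  }
  expect_equal(mean(sp$true_post_rate / sp$true_pre_rate), 1)
})

test_that("population structure is stratified within animal with full truth", {
  cfg <- sim_config(n_animals = 4, seed = 2)
  pop <- simulate_spine_population(cfg)
  # every animal contributes all four arms
  arms <- table(pop$spines$animal, pop$spines$treatment)
  expect_true(all(arms > 0))
  # lost spines have no 24-h rate; survivors keep one
  tr <- pop$truth
  expect_true(all(is.na(tr$true_rate_24h[tr$survived == 0])))
  expect_true(all(!is.na(tr$true_rate_24h[tr$survived == 1])))
  expect_error(simulate_spine_population("x"))
  # identical config + seed reproduces byte-identical tables
  pop2 <- simulate_spine_population(sim_config(n_animals = 4, seed = 2))
  expect_identical(pop, pop2)
})

test_that("simulated recordings carry ground-truth events and drop lost ROIs", {
  cfg <- sim_config(n_animals = 1, slices_per_animal = 4,
                    spines_per_dendrite = 3, seed = 4)
  pop <- simulate_spine_population(cfg)
  rec <- simulate_recordings(pop, cfg)
  n_frames <- 1200
  expect_true(all(table(rec$traces$spine_id, rec$traces$session,
                        rec$traces$recording_idx) %in% c(0, n_frames)))
  lost <- pop$truth$spine_id[pop$truth$survived == 0]
  expect_false(any(rec$traces$spine_id %in% lost &
                     rec$traces$session == "24h"))
  # event counts match rates: true rate = n_events / duration per recording
  ev <- rec$events[rec$events$session == "PRE", ]
  expect_true(all(ev$t_event_s >= 0 & ev$t_event_s < 60))
})

test_that("proximity stacks have correct geometry and labels", {
  expect_false(any(simulate_proximity_stack(10, c(64, 64), 3, 0,
                                            seed = 1)$proximal))
  expect_true(all(simulate_proximity_stack(10, c(64, 64), 3, 1,
                                           seed = 1)$proximal))
  st <- simulate_proximity_stack(25, c(96, 96), 3, 0.25, seed = 3)
  # spines do not overlap
  d <- as.matrix(dist(st$spines[, c("x", "y")]))
  diag(d) <- Inf
  expect_gt(min(d), 2 * 3)
  # labels equal the exhaustive pixel-distance oracle
  lab <- vapply(seq_len(25), function(i)
    proximity_oracle(c(st$spines$x[i], st$spines$y[i]), st$spines$radius[i],
                     st$astro_mask), logical(1))
  expect_identical(st$proximal, lab)
  expect_error(simulate_proximity_stack(500, c(32, 32), 6, 0.2, seed = 1),
               "overcrowded")
})
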