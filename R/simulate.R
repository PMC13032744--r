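#' GECI transient kernel
#'
#' Difference-of-exponentials model of a unitary genetically encoded calcium
#' indicator (GECI) transient, peak-normalised and scaled to `amplitude_dff`.
#' Presets mimic the qualitative behaviour of common variants: a slow
#' 6s-like kernel, a brighter 7b-like kernel (higher unitary dF/F peak), and
#' a fast 8s-like kernel.
#'
#' @param name one of `"6s-like"`, `"7b-like"`, `"8s-like"`, or `"custom"`.
#' @param amplitude_dff peak dF/F of a unitary event (required for
#'   `"custom"`, overrides the preset otherwise).
#' @param rise_s,decay_s rise and decay time constants in seconds
#'   (`rise_s < decay_s`).
#' @return object of class `geci_kernel`.
#' @export
geci_kernel <- function(name = c("7b-like", "6s-like", "8s-like", "custom"),
                        amplitude_dff = NULL, rise_s = NULL, decay_s = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    "6s-like" = list(amplitude_dff = 1.0, rise_s = 0.18, decay_s = 1.00),
    "7b-like" = list(amplitude_dff = 1.5, rise_s = 0.07, decay_s = 0.70),
    "8s-like" = list(amplitude_dff = 1.0, rise_s = 0.02, decay_s = 0.20),
    "custom"  = list(amplitude_dff = NA_real_, rise_s = NA_real_, decay_s = NA_real_))
  k <- list(name = name,
            amplitude_dff = if (is.null(amplitude_dff)) preset$amplitude_dff else amplitude_dff,
            rise_s = if (is.null(rise_s)) preset$rise_s else rise_s,
            decay_s = if (is.null(decay_s)) preset$decay_s else decay_s)
  if (!is.finite(k$amplitude_dff) || k$amplitude_dff <= 0)
    stop("amplitude_dff must be positive")
  if (!is.finite(k$rise_s) || !is.finite(k$decay_s) || k$rise_s <= 0 ||
      k$decay_s <= 0 || k$rise_s >= k$decay_s)
    stop("kernel requires 0 < rise_s < decay_s")
  structure(k, class = "geci_kernel")
}

#' Evaluate a GECI kernel at times since event onset
#'
#' @param kernel a [geci_kernel()].
#' @param t numeric vector of times (s) since the event; negative times give 0.
#' @return dF/F contribution of one unitary event at each `t`; the maximum
#'   over `t >= 0` is exactly `amplitude_dff`.
#' @export
kernel_eval <- function(kernel, t) {
  stopifnot(inherits(kernel, "geci_kernel"))
  tr <- kernel$rise_s; td <- kernel$decay_s
  # peak time of e^(-t/td) - e^(-t/tr), used to normalise the peak to 1
  tpk <- tr * td * log(td / tr) / (td - tr)
  pk <- exp(-tpk / td) - exp(-tpk / tr)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- kernel$amplitude_dff * (exp(-t[pos] / td) - exp(-t[pos] / tr)) / pk
  out
}

#' Simulate a homogeneous Poisson synaptic event train
#'
#' @param rate events per second (>= 0).
#' @param duration recording length in seconds.
#' @param seed optional integer seed; when given, output is reproducible.
#' @return strictly increasing event times in `[0, duration)`.
#' @export
simulate_event_train <- function(rate, duration, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stop("rate must be a single non-negative number")
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1L, rate * duration)
  if (n == 0L) return(numeric(0))
  sort(runif(n, 0, duration))
}

#' Smooth random baseline drift
#'
#' Low-order random polynomial over the recording, scaled so its maximum
#' absolute excursion equals `amplitude` (a fraction of baseline
#' fluorescence). Emulates slow focus/physiology drift that the 10th-order
#' baseline fit must remove.
#'
#' @param n_frames number of frames.
#' @param order polynomial order (>= 1).
#' @param amplitude maximum |drift| as a fraction of F0.
#' @return numeric vector of length `n_frames`.
#' @export
random_drift <- function(n_frames, order = 4L, amplitude = 0.1) {
  stopifnot(n_frames >= 2, order >= 1, amplitude >= 0)
  if (amplitude == 0) return(numeric(n_frames))
  x <- seq(-1, 1, length.out = n_frames)
  cf <- rnorm(order + 1L)
  d <- drop(outer(x, 0:order, `^`) %*% cf)
  d <- d - mean(d)
  mx <- max(abs(d))
  if (mx == 0) return(numeric(n_frames))
  amplitude * d / mx
}

#' Render a fluorescence trace from an event train
#'
#' Forward model of a 60-s spine recording:
#' `F(t) = F0 * bleach(t) * (1 + drift(t) + sum_i kernel(t - t_i)) + noise`,
#' with Gaussian noise of sd `noise_sd * F0`. Bleaching multiplies the whole
#' signal (baseline and transients), as photobleaching acts at the
#' fluorophore level.
#'
#' @param event_times event onset times in seconds.
#' @param kernel a [geci_kernel()].
#' @param duration_s,frame_rate_hz recording geometry; their product must be
#'   a whole number of frames.
#' @param f0 baseline fluorescence (arbitrary units).
#' @param drift per-frame fractional drift (vector of length n_frames), or
#'   `NULL` for none.
#' @param bleach biexponential parameters `c(A, tau1, B, tau2)` (seconds),
#'   or `NULL` for none; `A + B` should be 1 so the profile starts at 1.
#' @param noise_sd Gaussian noise sd as a fraction of `f0`.
#' @return numeric vector of length `duration_s * frame_rate_hz`.
#' @export
render_trace <- function(event_times, kernel, duration_s = 60,
                         frame_rate_hz = 20, f0 = 100, drift = NULL,
                         bleach = NULL, noise_sd = 0) {
  n <- duration_s * frame_rate_hz
  if (abs(n - round(n)) > 1e-9) stop("duration_s * frame_rate_hz must be an integer frame count")
  n <- as.integer(round(n))
  t <- (seq_len(n) - 1L) / frame_rate_hz
  sig <- numeric(n)
  if (length(event_times)) {
    if (any(event_times > duration_s))
      warning("events beyond the recording are truncated")
    for (te in event_times[event_times <= duration_s]) {
      sig <- sig + kernel_eval(kernel, t - te)
    }
  }
  dr <- if (is.null(drift)) 0 else { stopifnot(length(drift) == n); drift }
  bl <- if (is.null(bleach)) 1 else {
    stopifnot(length(bleach) == 4L, bleach[2] > 0, bleach[4] > 0)
    bleach[1] * exp(-t / bleach[2]) + bleach[3] * exp(-t / bleach[4])
  }
  trace <- f0 * bl * (1 + dr + sig)
  if (noise_sd > 0) trace <- trace + rnorm(n, 0, noise_sd * f0)
  trace
}

#' Simulation configuration
#'
#' Bundles every generative parameter of the synthetic study: hierarchy
#' sizes, recording geometry, per-spine event rates and the treatment effect
#' on them, the GECI kernel, drift/noise/bleaching, astrocyte-proximity
#' probability, the logistic survival model, and PsVue change effects.
#' Defaults encode the study conditions: 60-s recordings at 20 Hz, two
#' recordings per session, four treatment arms crossed within each animal,
#' and a doubling of event rate after amyloid-beta challenge.
#'
#' @param n_animals,slices_per_animal,dendrites_per_slice,spines_per_dendrite
#'   hierarchy sizes. `slices_per_animal` must be a multiple of 4 so each
#'   animal contributes all four treatment arms.
#' @param duration_s,frame_rate_hz recording geometry.
#' @param recordings_per_session repeat recordings per spine per time point.
#' @param baseline_rate_hz median per-spine event rate before treatment.
#' @param rate_sdlog log-sd of spine-to-spine rate heterogeneity.
#' @param abeta_rate_multiplier multiplicative rate change after treatment in
#'   amyloid-positive arms (>= 1).
#' @param lost_rate_multiplier additional POST-rate multiplier for
#'   amyloid-positive spines that will be lost at 24 h (>= 1): spines headed
#'   for elimination hyperactivate more than survivors.
#' @param kernel a [geci_kernel()].
#' @param drift_order,drift_amplitude slow-baseline drift settings.
#' @param noise_sd Gaussian noise sd as fraction of F0.
#' @param bleach biexponential bleaching parameters `c(A, tau1, B, tau2)` or
#'   `NULL`.
#' @param p_proximity probability a spine is astrocyte-proximal.
#' @param survival_logit named coefficients of the survival model on the
#'   logit scale: `intercept`, `abeta`, `astro`, `abeta_astro`,
#'   `tboa_abeta_astro`.
#' @param psvue_effects named list: mean fractional PsVue change is
#'   `base + is_abeta * (abeta + lost * is_lost + nonprox * (1 - proximal))`
#'   with Gaussian sd `sd`.
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_animals = 10L, slices_per_animal = 4L,
                       dendrites_per_slice = 1L, spines_per_dendrite = 15L,
                       duration_s = 60, frame_rate_hz = 20,
                       recordings_per_session = 2L,
                       baseline_rate_hz = 0.1, rate_sdlog = 0.4,
                       abeta_rate_multiplier = 2,
                       lost_rate_multiplier = 1.5,
                       kernel = geci_kernel("7b-like"),
                       drift_order = 4L, drift_amplitude = 0.08,
                       noise_sd = 0.05,
                       bleach = c(0.15, 3, 0.85, 400),
                       p_proximity = 0.5,
                       survival_logit = c(intercept = 2.197, abeta = -1.792,
                                          astro = 0, abeta_astro = 1.329,
                                          tboa_abeta_astro = -1.329),
                       psvue_effects = list(base = 0.05, abeta = 0.25,
                                            lost = 0.45, nonprox = 0.25,
                                            sd = 0.15),
                       seed = 1L) {
  stopifnot(n_animals >= 1, slices_per_animal >= 1, dendrites_per_slice >= 1,
            spines_per_dendrite >= 1, duration_s > 0, frame_rate_hz > 0,
            recordings_per_session >= 1, baseline_rate_hz >= 0,
            abeta_rate_multiplier >= 1, lost_rate_multiplier >= 1,
            p_proximity >= 0, p_proximity <= 1,
            noise_sd >= 0, drift_amplitude >= 0)
  nf <- duration_s * frame_rate_hz
  if (abs(nf - round(nf)) > 1e-9) stop("frame_rate_hz * duration_s must be an integer")
  if (!is.null(bleach)) stopifnot(length(bleach) == 4, bleach[2] > 0, bleach[4] > 0)
  stopifnot(inherits(kernel, "geci_kernel"))
  need <- c("intercept", "abeta", "astro", "abeta_astro", "tboa_abeta_astro")
  stopifnot(all(need %in% names(survival_logit)))
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_sp <- x$n_animals * x$slices_per_animal * x$dendrites_per_slice *
    x$spines_per_dendrite
  cat("Synthetic spine-imaging study configuration\n")
  cat(sprintf("  %d animals x %d slices x %d dendrites x %d spines = %d spines\n",
              x$n_animals, x$slices_per_animal, x$dendrites_per_slice,
              x$spines_per_dendrite, n_sp))
  cat(sprintf("  %g s at %g Hz, %d recordings/session; baseline rate %g Hz, Abeta multiplier %g\n",
              x$duration_s, x$frame_rate_hz, x$recordings_per_session,
              x$baseline_rate_hz, x$abeta_rate_multiplier))
  invisible(x)
}

surv_prob <- function(cf, abeta, astro, tboa) {
  eta <- cf[["intercept"]] + cf[["abeta"]] * abeta + cf[["astro"]] * astro +
    cf[["abeta_astro"]] * abeta * astro +
    cf[["tboa_abeta_astro"]] * tboa * abeta * astro
  1 / (1 + exp(-eta))
}

#' Simulate the spine population with ground truth
#'
#' Draws the full spine table: hierarchy ids, within-animal treatment
#' assignment (every animal contributes all four arms: amyloid-beta +/- BH
#' crossed with TBOA/vehicle), sex, astrocyte proximity, true per-session
#' event rates (POST rate = PRE rate x multiplier in amyloid-positive arms;
#' survivors keep the POST rate at 24 h), survival from the logistic model,
#' and PsVue intensities PRE/POST.
#'
#' @param config a [sim_config()].
#' @return list with `spines` (the observable metadata table) and `truth`
#'   (one row per spine: true rates, survival, proximity, PsVue change).
#' @export
simulate_spine_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_sp_total <- cfg$n_animals * cfg$slices_per_animal * cfg$dendrites_per_slice *
    cfg$spines_per_dendrite
  if (n_sp_total == 0L) stop("configuration yields zero spines")
  set.seed(cfg$seed)
  arms <- data.frame(abeta = c(1, 1, 0, 0), tboa = c(0, 1, 0, 1))
  rows <- vector("list", cfg$n_animals * cfg$slices_per_animal)
  k <- 0L
  for (a in seq_len(cfg$n_animals)) {
    sex <- if (runif(1) < 0.5) "F" else "M"
    # stratified within-animal assignment: cycle through the four arms
    arm_order <- sample(nrow(arms))
    for (s in seq_len(cfg$slices_per_animal)) {
      arm <- arms[arm_order[((s - 1L) %% nrow(arms)) + 1L], ]
      for (d in seq_len(cfg$dendrites_per_slice)) {
        n_sp <- cfg$spines_per_dendrite
        k <- k + 1L
        rows[[k]] <- data.frame(
          animal = sprintf("A%02d", a), slice = sprintf("A%02d_S%d", a, s),
          dendrite = sprintf("A%02d_S%d_D%d", a, s, d), roi = seq_len(n_sp),
          sex = sex, abeta = arm$abeta, tboa = arm$tboa)
      }
    }
  }
  sp <- do.call(rbind, rows)
  sp$spine_id <- paste0(sp$dendrite, "_R", sp$roi)
  n <- nrow(sp)
  proximal <- rbinom(n, 1L, cfg$p_proximity)
  pre_rate <- cfg$baseline_rate_hz * exp(rnorm(n, 0, cfg$rate_sdlog) -
                                           cfg$rate_sdlog^2 / 2)
  p_surv <- surv_prob(cfg$survival_logit, sp$abeta, proximal, sp$tboa)
  survived <- rbinom(n, 1L, p_surv)
  # spines headed for elimination hyperactivate more than survivors
  mult <- ifelse(sp$abeta == 1,
                 cfg$abeta_rate_multiplier *
                   ifelse(survived == 0L, cfg$lost_rate_multiplier, 1), 1)
  post_rate <- pre_rate * mult
  rate_24h <- ifelse(survived == 1L, post_rate, NA_real_)
  eff <- cfg$psvue_effects
  mu_change <- eff$base + sp$abeta * (eff$abeta + eff$lost * (1 - survived) +
                                        eff$nonprox * (1 - proximal))
  psvue_change <- mu_change + rnorm(n, 0, eff$sd)
  psvue_pre <- rnorm(n, 100, 10)
  psvue_post <- psvue_pre * (1 + psvue_change)
  spines <- data.frame(sp[, c("animal", "slice", "dendrite", "roi", "spine_id",
                              "sex", "abeta", "tboa")],
                       treatment = paste0(ifelse(sp$abeta == 1, "Abeta+", "Abeta-"),
                                          "/", ifelse(sp$tboa == 1, "TBOA", "vehicle")),
                       proximal = proximal, survived = survived,
                       psvue_pre = psvue_pre, psvue_post = psvue_post)
  truth <- data.frame(spine_id = sp$spine_id, true_pre_rate = pre_rate,
                      true_post_rate = post_rate, true_rate_24h = rate_24h,
                      p_survival = p_surv, survived = survived,
                      proximal = proximal, true_psvue_change = psvue_change)
  list(spines = spines, truth = truth)
}

#' Simulate the full recording set for a population
#'
#' For each spine and session (`PRE`, `POST`, and `24h` for survivors) draws
#' `recordings_per_session` independent Poisson event trains at the spine's
#' true session rate and renders each into a noisy fluorescence trace with
#' the configured kernel, drift and bleaching. Lost spines have no 24-h
#' recording: the ROI has disappeared.
#'
#' @param population output of [simulate_spine_population()].
#' @param config the same [sim_config()].
#' @param sessions which sessions to render (default all three).
#' @return list with `traces` (long data.frame: spine_id, session,
#'   recording_idx, frame, intensity) and `events` (data.frame of true event
#'   times: spine_id, session, recording_idx, t_event_s).
#' @export
simulate_recordings <- function(population, config,
                                sessions = c("PRE", "POST", "24h")) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  n_frames <- as.integer(round(cfg$duration_s * cfg$frame_rate_hz))
  tr_list <- list(); ev_list <- list(); k <- 0L
  truth <- population$truth
  rate_col <- c(PRE = "true_pre_rate", POST = "true_post_rate",
                `24h` = "true_rate_24h")
  for (i in seq_len(nrow(truth))) {
    for (ses in sessions) {
      rate <- truth[[rate_col[[ses]]]][i]
      if (is.na(rate)) next  # lost spine: no 24-h ROI
      for (r in seq_len(cfg$recordings_per_session)) {
        ev <- simulate_event_train(rate, cfg$duration_s)
        drift <- random_drift(n_frames, cfg$drift_order, cfg$drift_amplitude)
        tr <- render_trace(ev, cfg$kernel, cfg$duration_s, cfg$frame_rate_hz,
                           f0 = 100, drift = drift, bleach = cfg$bleach,
                           noise_sd = cfg$noise_sd)
        k <- k + 1L
        tr_list[[k]] <- data.frame(spine_id = truth$spine_id[i], session = ses,
                                   recording_idx = r, frame = seq_len(n_frames),
                                   intensity = tr)
        ev_list[[k]] <- if (length(ev))
          data.frame(spine_id = truth$spine_id[i], session = ses,
                     recording_idx = r, t_event_s = ev) else NULL
      }
    }
  }
  list(traces = do.call(rbind, tr_list),
       events = do.call(rbind, ev_list[!vapply(ev_list, is.null, logical(1))]))
}

#' Write a simulated study to CSV files
#'
#' Writes `spines.csv` (one row per spine with treatment, proximity and
#' survival labels), `ground_truth.csv` (true rates and effects) and, when
#' recordings are supplied, `traces.csv` (long format) and `events.csv`
#' (true event times).
#'
#' @param population output of [simulate_spine_population()].
#' @param recordings optional output of [simulate_recordings()].
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(population, recordings = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, file) {
    path <- file.path(dir, file)
    write.csv(df, path, row.names = FALSE)
    paths <<- c(paths, path)
  }
  wr(population$spines, "spines.csv")
  wr(population$truth, "ground_truth.csv")
  if (!is.null(recordings)) {
    wr(recordings$traces, "traces.csv")
    wr(recordings$events, "events.csv")
  }
  invisible(paths)
}

#' Simulate a two-channel spine/astrocyte image stack
#'
#' Places non-overlapping spine discs in a synthetic field and an astrocyte
#' mask built from random blobs covering approximately `astro_coverage` of
#' the field. Ground-truth proximity labels are computed by an exhaustive
#' pixel scan: a spine is proximal if any astrocyte pixel lies within twice
#' its radius of the centroid.
#'
#' @param n_spines number of spines to place.
#' @param image_size `c(nrow, ncol)` in pixels.
#' @param spine_radius_px spine-head radius.
#' @param astro_coverage target astrocyte area fraction in `[0, 1]`.
#' @param seed optional RNG seed.
#' @param max_tries placement retries before giving up.
#' @return list with `spine_img`, `astro_img` (intensity matrices),
#'   `astro_mask` (logical matrix), `spines` (centroid/radius table) and
#'   `proximal` (true labels).
#' @export
simulate_proximity_stack <- function(n_spines, image_size = c(96L, 96L),
                                     spine_radius_px = 3, astro_coverage = 0.2,
                                     seed = NULL, max_tries = 2000L) {
  stopifnot(n_spines >= 1, astro_coverage >= 0, astro_coverage <= 1,
            spine_radius_px > 0)
  if (!is.null(seed)) set.seed(seed)
  nr <- image_size[1]; nc <- image_size[2]
  margin <- ceiling(spine_radius_px) + 1
  if (2 * margin >= min(nr, nc)) stop("image too small for requested spine radius")
  cx <- numeric(0); cy <- numeric(0); tries <- 0L
  while (length(cx) < n_spines) {
    tries <- tries + 1L
    if (tries > max_tries) stop("could not place spines without overlap; field overcrowded")
    x <- runif(1, margin, nc - margin); y <- runif(1, margin, nr - margin)
    if (length(cx) == 0 ||
        all((cx - x)^2 + (cy - y)^2 > (2 * spine_radius_px)^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  px_x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  px_y <- matrix(rep(seq_len(nr), nc), nr, nc)
  spine_img <- matrix(0, nr, nc)
  for (i in seq_len(n_spines)) {
    spine_img <- spine_img +
      ((px_x - cx[i])^2 + (px_y - cy[i])^2 <= spine_radius_px^2)
  }
  astro_mask <- matrix(FALSE, nr, nc)
  if (astro_coverage >= 1) {
    astro_mask[] <- TRUE
  } else if (astro_coverage > 0) {
    blob_r <- max(3, round(min(nr, nc) / 12))
    guard <- 0L
    while (mean(astro_mask) < astro_coverage && guard < 10000L) {
      guard <- guard + 1L
      bx <- runif(1, 1, nc); by <- runif(1, 1, nr)
      r <- runif(1, blob_r / 2, blob_r)
      astro_mask <- astro_mask | ((px_x - bx)^2 + (px_y - by)^2 <= r^2)
    }
  }
  # exhaustive ground-truth labelling over every mask pixel
  proximal <- logical(n_spines)
  mask_x <- px_x[astro_mask]; mask_y <- px_y[astro_mask]
  for (i in seq_len(n_spines)) {
    proximal[i] <- length(mask_x) > 0 &&
      any((mask_x - cx[i])^2 + (mask_y - cy[i])^2 <= (2 * spine_radius_px)^2)
  }
  list(spine_img = spine_img * 200,
       astro_img = astro_mask * 150,
       astro_mask = astro_mask,
       spines = data.frame(roi = seq_len(n_spines), x = cx, y = cy,
                           radius = spine_radius_px),
       proximal = proximal)
}
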