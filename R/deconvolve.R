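#' Estimate the AR(1) decay coefficient from a trace
#'
#' Uses the lag-1/lag-2 autocovariance ratio: for a calcium signal that
#' decays as an AR(1) process observed in white noise, the autocovariance at
#' lags k >= 1 is proportional to g^k, so gamma(2)/gamma(1) estimates g free
#' of the noise variance that contaminates lag 0. If the lag-1
#' autocovariance is not significantly positive (below 2 * gamma(0)/sqrt(n),
#' the white-noise sampling scale) the trace carries no usable temporal
#' correlation and 0 is returned. The estimate is clipped to [0, 0.999].
#'
#' @param z numeric trace (typically z-scored).
#' @param max_lag unused beyond lag 2; kept for interface stability.
#' @return estimated g in `[0, 0.999]`.
#' @export
estimate_g <- function(z, max_lag = 5L) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  n <- length(z)
  if (n < 10L) stop("trace too short to estimate g")
  zc <- z - mean(z)
  g0 <- sum(zc^2) / n
  if (!is.finite(g0) || g0 == 0) stop("non-finite or zero autocovariance")
  g1 <- sum(zc[-n] * zc[-1]) / n
  g2 <- sum(zc[seq_len(n - 2L)] * zc[-(1:2)]) / n
  if (g1 <= 2 * g0 / sqrt(n)) return(0)
  min(max(g2 / g1, 0), 0.999)
}

#' Estimate the noise level from the high-frequency periodogram
#'
#' Calcium transients live at low frequencies; the upper half of the
#' periodogram is dominated by measurement noise. The noise sd is the square
#' root of the median periodogram ordinate over frequencies in (fs/4, fs/2],
#' debiased by log(2) (periodogram ordinates of white noise are
#' exponentially distributed around the noise variance).
#'
#' @param y numeric trace.
#' @return estimated noise standard deviation (same units as `y`).
#' @export
estimate_noise_sd <- function(y) {
  stopifnot(is.numeric(y), all(is.finite(y)), length(y) >= 16)
  n <- length(y)
  pg <- Mod(fft(y - mean(y)))^2 / n
  idx <- seq.int(floor(n / 4) + 1L, floor(n / 2))
  sqrt(median(pg[idx]) / log(2))
}

#' Deconvolution parameters
#'
#' @param g AR(1) decay per frame in `[0, 1)`, or `"estimate"` to use
#'   [estimate_g()].
#' @param sn noise level in trace units, or `"estimate"` to use
#'   [estimate_noise_sd()]. The acceptance threshold on deconvolved event
#'   amplitude is `s_min * sn`, so on a z-scored trace with `sn` estimated
#'   from its high frequencies, `s_min = 2.5` accepts events above 2.5 noise
#'   standard deviations.
#' @param s_min minimal accepted deconvolved amplitude, in units of `sn`:
#'   `s_min = 2.5` accepts events above 2.5 noise standard deviations.
#' @param optimize_g number of large isolated transients used to refine `g`
#'   from their measured decay (0 disables refinement).
#' @param merge_window_s impulses closer than this are counted as one event
#'   (an indicator transient sampled during its rise yields impulses on
#'   neighbouring frames; the default spans a typical rise-to-peak time).
#' @param candidate_factor candidate impulses are admitted during pool
#'   merging at `candidate_factor * s_min * sn` so that a transient whose
#'   rise is split across frames can accumulate its mass; final event
#'   acceptance is unchanged: a grouped event is returned only if its total
#'   deconvolved amplitude reaches `s_min * sn`.
#' @param g_decay_range_s physiological range of indicator decay time
#'   constants, in seconds. Estimated or refined `g` values are constrained
#'   to this range: a fitted decay far outside what a calcium indicator can
#'   produce means the fit latched onto noise correlation, not transients.
#'   A `g` passed as a number is used as given.
#' @return object of class `deconv_params`.
#' @export
deconv_params <- function(g = "estimate", sn = "estimate", s_min = 2.5,
                          optimize_g = 5L, merge_window_s = 0.25,
                          candidate_factor = 0.5,
                          g_decay_range_s = c(0.2, 2.0)) {
  if (is.numeric(g) && (g < 0 || g >= 1)) stop("g must be in [0, 1)")
  if (is.numeric(sn) && sn <= 0) stop("sn must be positive")
  stopifnot(s_min >= 0, optimize_g >= 0, merge_window_s >= 0,
            candidate_factor > 0, candidate_factor <= 1,
            length(g_decay_range_s) == 2, g_decay_range_s[1] > 0,
            g_decay_range_s[1] < g_decay_range_s[2])
  structure(list(g = g, sn = sn, s_min = s_min,
                 optimize_g = as.integer(optimize_g),
                 merge_window_s = merge_window_s,
                 candidate_factor = candidate_factor,
                 g_decay_range_s = g_decay_range_s),
            class = "deconv_params")
}

# Core greedy pool-merging pass for min ||y - c||^2 s.t. c_{t+1} >= g c_t,
# with new pools kept separate only when the implied spike clears s_min_abs.
# Pools store (v, w, t, l): fitted pool height is v/w, decaying by g within
# the pool; merging pool i into its predecessor j uses
# v_j += g^{l_j} v_i, w_j += g^{2 l_j} w_i.
oasis_pools <- function(y, g, s_min_abs) {
  n <- length(y)
  v <- numeric(n); w <- numeric(n); tt <- integer(n); l <- integer(n)
  np <- 0L
  for (t in seq_len(n)) {
    np <- np + 1L
    v[np] <- y[t]; w[np] <- 1; tt[np] <- t; l[np] <- 1L
    while (np > 1L) {
      hj <- max(v[np - 1L] / w[np - 1L], 0)
      hi <- v[np] / w[np]
      gl <- g^l[np - 1L]
      if (hi >= gl * hj + s_min_abs) break
      # spike below threshold: re-absorb the pool into its predecessor
      v[np - 1L] <- v[np - 1L] + gl * v[np]
      w[np - 1L] <- w[np - 1L] + gl^2 * w[np]
      l[np - 1L] <- l[np - 1L] + l[np]
      np <- np - 1L
    }
  }
  list(v = v[1:np], w = w[1:np], t = tt[1:np], l = l[1:np], n = n)
}

# Split refinement: greedy backward merging never revisits a pool, so a
# transient whose rise is spread over several frames (finite indicator rise
# time) can be absorbed into the preceding baseline pool without any single
# frame clearing s_min. Test every interior split of each pool: accept the
# SSE-minimising split whose implied spike clears the threshold, and recurse
# on both halves. Left/right weighted fits come from forward prefix sums and
# a backward recurrence, O(length) per attempt.
split_pools <- function(p, y, g, s_min_abs) {
  out_v <- numeric(0); out_w <- numeric(0); out_t <- integer(0); out_l <- integer(0)
  stack <- lapply(seq_along(p$v), function(i)
    list(t = p$t[i], l = p$l[i]))
  while (length(stack)) {
    pool <- stack[[1]]; stack <- stack[-1]
    t0 <- pool$t; L <- pool$l
    seg <- y[t0:(t0 + L - 1L)]
    gk <- g^(seq_len(L) - 1L)
    A <- cumsum(seg * gk)            # A[m] = sum_{k<m} y_k g^k  (1-based m)
    B <- cumsum(gk^2)
    P <- cumsum(seg^2)
    best <- NULL
    if (L >= 2L && g > 0) {
      RA <- numeric(L); RB <- numeric(L)   # RA[m] = sum_j y_{m+j} g^j, 0-off
      RA[L] <- seg[L]; RB[L] <- 1
      if (L > 1L) for (m in (L - 1L):1L) {
        RA[m] <- seg[m] + g * RA[m + 1L]
        RB[m] <- 1 + g^2 * RB[m + 1L]
      }
      m <- seq_len(L - 1L)                 # split: right pool starts at m+1
      hl <- pmax(A[m] / B[m], 0)
      hr <- pmax(RA[m + 1L] / RB[m + 1L], 0)
      sse <- (P[m] - hl^2 * B[m]) +
        ((P[L] - P[m]) - hr^2 * RB[m + 1L])
      jump <- hr - hl * g^m
      h0 <- max(A[L] / B[L], 0)
      sse0 <- P[L] - h0^2 * B[L]
      ok <- jump >= s_min_abs - 1e-12 & sse < sse0 - 1e-10
      if (any(ok)) best <- m[ok][which.min(sse[ok])]
    }
    if (is.null(best)) {
      out_v <- c(out_v, A[L]); out_w <- c(out_w, B[L])
      out_t <- c(out_t, t0); out_l <- c(out_l, L)
    } else {
      stack <- c(list(list(t = t0, l = best),
                      list(t = t0 + best, l = L - best)), stack)
    }
  }
  ord <- order(out_t)
  list(v = out_v[ord], w = out_w[ord], t = out_t[ord], l = out_l[ord], n = p$n)
}

pools_to_solution <- function(p, g) {
  c_hat <- numeric(p$n)
  for (i in seq_len(length(p$v))) {
    h <- max(p$v[i] / p$w[i], 0)
    idx <- p$t[i]:(p$t[i] + p$l[i] - 1L)
    c_hat[idx] <- h * g^(seq_along(idx) - 1L)
  }
  s <- c(0, c_hat[-1] - g * c_hat[-p$n])
  s[s < 0] <- 0  # numerical dust from long-pool underflow
  list(c = c_hat, s = s)
}

#' Sparse non-negative AR(1) deconvolution with an amplitude threshold
#'
#' Solves the constrained deconvolution problem behind calcium event
#' detection: find calcium `c` and non-negative impulses `s` with
#' `c_t = g c_{t-1} + s_t` minimising `||z - c||^2`, where any impulse
#' smaller than `s_min * sn` is suppressed and its mass re-absorbed into the
#' preceding decay (greedy pool merging, processed online left to right).
#' Because an AR(1) impulse cannot represent a finite indicator rise time, a
#' transient sampled during its rise can produce impulses on consecutive
#' frames; these are grouped into single events (maximal runs of
#' supra-threshold impulses; event time is the run onset, amplitude the
#' summed impulse mass). Frame-level impulses are retained in the fit.
#'
#' @param z numeric trace (the z-scored processed trace in the standard
#'   pipeline).
#' @param params a [deconv_params()].
#' @param frame_rate_hz frames per second, used to convert event frames to
#'   seconds.
#' @return object of class `oasis_fit`: list with `z`, `denoised` (fitted
#'   calcium), `spikes` (frame-level impulse vector), `events` (data.frame
#'   with `frame`, `time_s`, `amplitude`), `g`, `sn`, `threshold`,
#'   `frame_rate_hz`.
#' @export
deconvolve_oasis <- function(z, params = deconv_params(), frame_rate_hz = 20) {
  stopifnot(is.numeric(z), all(is.finite(z)), inherits(params, "deconv_params"))
  sn <- if (identical(params$sn, "estimate")) estimate_noise_sd(z) else params$sn
  thr <- params$s_min * sn
  # clip estimated/refined g to the physiological indicator-decay range;
  # an explicitly supplied numeric g is trusted as given
  rng <- sort(exp(-1 / (frame_rate_hz * params$g_decay_range_s)))
  estimated <- identical(params$g, "estimate")
  g <- if (estimated) min(max(estimate_g(z), rng[1]), rng[2]) else params$g
  if (g < 0 || g >= 1) stop("g must be in [0, 1)")
  if (params$optimize_g > 0L) {
    g <- refine_g(z, g, thr, n_events = params$optimize_g)
    if (estimated) g <- min(max(g, rng[1]), rng[2])
  }
  thr_cand <- params$candidate_factor * thr
  pools <- oasis_pools(z, g, thr_cand)
  pools <- split_pools(pools, z, g, thr_cand)
  fit1 <- pools_to_solution(pools, g)
  gap <- as.integer(round(params$merge_window_s * frame_rate_hz))
  ev <- group_events(fit1$s, thr_cand, frame_rate_hz, gap_frames = gap)
  ev <- ev[ev$amplitude >= thr - 1e-9, , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(z = as.numeric(z), denoised = fit1$c, spikes = fit1$s,
                 events = ev, g = g, sn = sn, s_min = params$s_min,
                 threshold = thr, frame_rate_hz = frame_rate_hz),
            class = "oasis_fit")
}

# impulses within gap_frames of a group onset belong to that group (time =
# onset frame, amplitude = summed impulse mass); the window is anchored at
# the onset, not chained, so nearby but distinct transients stay separate
group_events <- function(s, thr, frame_rate_hz, gap_frames = 0L) {
  active <- which(s >= thr - 1e-9)
  if (!length(active)) {
    return(data.frame(frame = integer(0), time_s = numeric(0),
                      amplitude = numeric(0)))
  }
  frame <- integer(0); amplitude <- numeric(0)
  i <- 1L
  while (i <= length(active)) {
    onset <- active[i]
    in_grp <- active[active >= onset & active <= onset + gap_frames]
    frame <- c(frame, onset)
    amplitude <- c(amplitude, sum(s[in_grp]))
    i <- i + length(in_grp)
  }
  data.frame(frame = frame, time_s = (frame - 1L) / frame_rate_hz,
             amplitude = amplitude)
}

# Refine g by least squares on the decay of the largest isolated transients.
# Candidate transients are supra-threshold local maxima of the trace itself
# (robust to a poor initial g, which can merge every event away if trusted);
# within each decay window z_{t+1} ~ g z_t is pooled through the origin.
# Run twice so the isolation window reflects the refined decay constant
# rather than a possibly inflated initial estimate.
refine_g <- function(z, g0, thr, n_events = 5L) {
  g <- refine_g_once(z, g0, thr, n_events)
  refine_g_once(z, g, thr, n_events)
}

refine_g_once <- function(z, g0, thr, n_events = 5L) {
  n <- length(z)
  interior <- 2:(n - 1L)
  pk <- interior[z[interior] >= z[interior - 1L] & z[interior] > z[interior + 1L] &
                   z[interior] >= thr]
  if (!length(pk)) return(g0)
  tau0 <- if (g0 > 0 && g0 < 1) -1 / log(g0) else Inf
  iso_win <- as.integer(min(max(ceiling(5 * tau0), 10L), max(10L, n %/% 10L)))
  isolated <- pk[vapply(pk, function(f) {
    others <- pk[pk != f]
    !length(others) || min(abs(others - f)) > iso_win
  }, logical(1))]
  # prefer isolated transients; fall back to the largest peaks with decay
  # windows truncated at the next peak
  use <- if (length(isolated)) isolated else pk
  use <- head(use[order(z[use], decreasing = TRUE)], n_events)
  num <- 0; den <- 0
  for (f in use) {
    end <- min(n, f + iso_win)
    nxt <- pk[pk > f]
    if (length(nxt)) end <- min(end, min(nxt) - 1L)
    if (end <= f + 1L) next
    seg <- z[f:end]
    # follow the decay while it stays clear of the noise floor
    below <- which(seg < thr / 4)
    if (length(below) > 1L) seg <- seg[seq_len(max(2L, below[1]))]
    if (length(seg) < 2L) next
    num <- num + sum(seg[-length(seg)] * seg[-1])
    den <- den + sum(seg[-length(seg)]^2)
  }
  if (den <= 0) return(g0)
  min(max(num / den, 0), 0.999)
}

#' @export
print.oasis_fit <- function(x, ...) {
  dur <- length(x$z) / x$frame_rate_hz
  cat("Sparse AR(1) deconvolution fit\n")
  cat(sprintf("  %d frames (%.1f s at %g Hz), g = %.4f, sn = %.4f, threshold = %.3f\n",
              length(x$z), dur, x$frame_rate_hz, x$g, x$sn, x$threshold))
  cat(sprintf("  %d events (%.3f Hz); residual SS = %.4f\n",
              nrow(x$events), nrow(x$events) / dur,
              sum((x$z - x$denoised)^2)))
  invisible(x)
}

#' @export
coef.oasis_fit <- function(object, ...) {
  c(g = object$g, sn = object$sn, s_min = object$s_min,
    threshold = object$threshold)
}

#' @export
fitted.oasis_fit <- function(object, ...) object$denoised

#' @export
residuals.oasis_fit <- function(object, ...) object$z - object$denoised

#' @export
plot.oasis_fit <- function(x, ...) {
  t <- (seq_along(x$z) - 1) / x$frame_rate_hz
  plot(t, x$z, type = "l", col = "grey60", xlab = "time (s)",
       ylab = "z-scored fluorescence", ...)
  lines(t, x$denoised, col = "dodgerblue3")
  if (nrow(x$events))
    points(x$events$time_s, rep(min(x$z), nrow(x$events)), pch = 3, col = "red")
  invisible(x)
}

#' Per-spine event rate over repeat recordings
#'
#' The rate of each recording is its event count divided by the recording
#' duration; the per-spine rate is the unweighted mean over the repeat
#' recordings of that session.
#'
#' @param trains list of event trains; each element may be an `oasis_fit`, a
#'   data.frame with a `time_s` column, or a numeric vector of event times.
#' @param duration_s recording duration in seconds.
#' @return mean rate in Hz.
#' @export
event_rate <- function(trains, duration_s) {
  stopifnot(duration_s > 0)
  if (!is.list(trains) || inherits(trains, "data.frame")) trains <- list(trains)
  if (!length(trains)) stop("no recordings supplied")
  counts <- vapply(trains, function(tr) {
    if (inherits(tr, "oasis_fit")) nrow(tr$events)
    else if (is.data.frame(tr)) nrow(tr)
    else length(tr)
  }, numeric(1))
  mean(counts / duration_s)
}

#' Peak dF/F amplitudes at detected event times
#'
#' For each event, the maximum dF/F value in the window
#' `[t_event, t_event + window_s]`; windows running past the end of the
#' recording are truncated.
#'
#' @param dff dF/F trace.
#' @param event_frames integer event onset frames (1-based), or an
#'   `oasis_fit` whose events are used.
#' @param frame_rate_hz frames per second.
#' @param window_s look-ahead window in seconds (default 1).
#' @return numeric vector of peak amplitudes, one per event.
#' @export
peak_amplitudes <- function(dff, event_frames, frame_rate_hz = 20,
                            window_s = 1.0) {
  if (inherits(event_frames, "oasis_fit")) event_frames <- event_frames$events$frame
  if (!length(event_frames)) return(numeric(0))
  stopifnot(all(event_frames >= 1), all(event_frames <= length(dff)))
  w <- as.integer(round(window_s * frame_rate_hz))
  vapply(event_frames, function(f) max(dff[f:min(length(dff), f + w)]),
         numeric(1))
}
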