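# Independent oracles used across the suite. Each re-implements the defining
# rule of an operation as directly (and slowly) as possible, sharing no code
# with the package internals.

# Okada update rule, straightforward synchronous re-implementation
okada_oracle <- function(x, iterations) {
  n <- length(x)
  for (it in seq_len(iterations)) {
    old <- x
    for (t in 2:(n - 1)) {
      if ((old[t] - old[t - 1]) * (old[t] - old[t + 1]) > 0)
        x[t] <- (old[t - 1] + old[t + 1]) / 2
    }
  }
  x
}

# Exhaustive search over all feasible event placements for the sparse
# non-negative AR(1) deconvolution with amplitude threshold s_min:
# for every support (subset of frames 2..n), fit each inter-spike segment by
# weighted least squares (height h, c decaying as h * g^k), reject supports
# whose implied spikes fall below s_min or whose heights are negative, and
# return the support with minimal SSE (ties: fewer spikes).
brute_force_deconv <- function(y, g, s_min) {
  n <- length(y)
  fit_segment <- function(idx) {
    gk <- g^(seq_along(idx) - 1)
    h <- sum(y[idx] * gk) / sum(gk^2)
    list(h = h, sse = sum((y[idx] - h * gk)^2))
  }
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    support <- which(intToBits(mask)[seq_len(n - 1)] == 1) + 1L
    bounds <- c(1L, support, n + 1L)
    heights <- numeric(length(bounds) - 1L)
    sse <- 0
    feasible <- TRUE
    for (j in seq_len(length(bounds) - 1L)) {
      idx <- bounds[j]:(bounds[j + 1L] - 1L)
      f <- fit_segment(idx)
      if (f$h < -1e-9) { feasible <- FALSE; break }
      heights[j] <- max(f$h, 0)
      sse <- sse + f$sse
    }
    if (!feasible) next
    ok <- TRUE
    for (j in seq_along(support)) {
      l_prev <- bounds[j + 1L] - bounds[j]
      spike <- heights[j + 1L] - g^l_prev * heights[j]
      if (spike < s_min - 1e-9) { ok <- FALSE; break }
    }
    if (!ok) next
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (abs(sse - best$sse) <= 1e-12 && length(support) < length(best$support))) {
      best <- list(support = support, sse = sse, heights = heights,
                   bounds = bounds)
    }
  }
  spikes <- numeric(0)
  if (length(best$support)) {
    for (j in seq_along(best$support)) {
      l_prev <- best$bounds[j + 1L] - best$bounds[j]
      spikes <- c(spikes, best$heights[j + 1L] - g^l_prev * best$heights[j])
    }
  }
  list(support = best$support, amplitude = spikes, sse = best$sse)
}

# AR(1) forward model: calcium trace from spike vector
ar1_trace <- function(s, g) {
  cc <- numeric(length(s))
  cc[1] <- s[1]
  for (t in 2:length(s)) cc[t] <- g * cc[t - 1] + s[t]
  cc
}

# exhaustive pixel-distance proximity oracle over the whole mask
proximity_oracle <- function(centroid, radius, mask, reach_radii = 2) {
  hits <- which(mask, arr.ind = TRUE)
  if (!nrow(hits)) return(FALSE)
  d2 <- (hits[, "col"] - centroid[1])^2 + (hits[, "row"] - centroid[2])^2
  any(d2 <= (reach_radii * radius)^2 + 1e-9)
}

# render one synthetic recording and run the standard conditioning chain
render_and_process <- function(events, kernel, noise_sd = 0.05, f0 = 100,
                               duration_s = 60, frame_rate_hz = 20, ...) {
  raw <- render_trace(events, kernel, duration_s = duration_s,
                      frame_rate_hz = frame_rate_hz, f0 = f0,
                      noise_sd = noise_sd, ...)
  process_trace(raw)
}

# pipeline event count for one processed trace, using the chain's own noise
# estimate as in extract_event_rates()
detect_events <- function(pt, frame_rate_hz = 20, params = deconv_params()) {
  if (identical(params$sn, "estimate") && is.finite(pt$sn_z)) params$sn <- pt$sn_z
  deconvolve_oasis(pt$z, params, frame_rate_hz = frame_rate_hz)
}
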