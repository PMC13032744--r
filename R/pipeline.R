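#' Run the full event-extraction pipeline over a recording table
#'
#' For every spine, session and repeat recording in a long trace table,
#' applies the standard conditioning chain (polynomial baseline, Okada
#' filter, dF/F, z-score), deconvolves the z-scored trace, and averages
#' event rates over repeat recordings to one rate per spine per session.
#'
#' @param traces long data.frame with columns `spine_id`, `session`,
#'   `recording_idx`, `frame`, `intensity` (as written by
#'   [simulate_recordings()]).
#' @param frame_rate_hz frames per second.
#' @param baseline_order,okada_iterations conditioning settings (main
#'   pipeline defaults: order 10, four iterations).
#' @param params a [deconv_params()].
#' @return data.frame with one row per spine and session: `spine_id`,
#'   `session`, `rate_hz`, `n_recordings`, `n_events`.
#' @export
extract_event_rates <- function(traces, frame_rate_hz = 20,
                                baseline_order = 10L, okada_iterations = 4L,
                                params = deconv_params()) {
  need <- c("spine_id", "session", "recording_idx", "frame", "intensity")
  stopifnot(all(need %in% names(traces)))
  key <- interaction(traces$spine_id, traces$session, drop = TRUE)
  rows <- lapply(split(traces, key), function(d) {
    recs <- split(d, d$recording_idx)
    counts <- vapply(recs, function(r) {
      y <- r$intensity[order(r$frame)]
      pt <- process_trace(y, baseline_order = baseline_order,
                          okada_iterations = okada_iterations)
      # the chain knows the recording's noise level in z units; use it
      # unless the caller forced a numeric sn
      p <- params
      if (identical(p$sn, "estimate") && is.finite(pt$sn_z)) p$sn <- pt$sn_z
      fit <- deconvolve_oasis(pt$z, p, frame_rate_hz = frame_rate_hz)
      nrow(fit$events)
    }, numeric(1))
    dur <- max(d$frame) / frame_rate_hz
    data.frame(spine_id = d$spine_id[1], session = d$session[1],
               rate_hz = mean(counts / dur), n_recordings = length(recs),
               n_events = sum(counts))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the per-spine analysis table
#'
#' Merges per-session extracted rates onto the spine metadata table and adds
#' the relative-change statistics the downstream group comparisons use:
#' `rate_pre`, `rate_post`, `rel_change_hz`, and - when PsVue intensities
#' are present - `rel_change_psvue`.
#'
#' @param spines spine metadata table (`spine_id`, `animal`, `slice`,
#'   `dendrite`, `treatment`, `survived`, `proximal`, ...).
#' @param rates output of [extract_event_rates()].
#' @return the spine table with rate and change columns added.
#' @export
analyze_spine_dataset <- function(spines, rates) {
  stopifnot("spine_id" %in% names(spines),
            all(c("spine_id", "session", "rate_hz") %in% names(rates)))
  wide <- stats::reshape(rates[, c("spine_id", "session", "rate_hz")],
                         idvar = "spine_id", timevar = "session",
                         direction = "wide")
  names(wide) <- sub("^rate_hz\\.", "rate_", names(wide))
  names(wide) <- sub("^rate_PRE$", "rate_pre", names(wide))
  names(wide) <- sub("^rate_POST$", "rate_post", names(wide))
  names(wide) <- sub("^rate_24h$", "rate_24h", names(wide))
  out <- merge(spines, wide, by = "spine_id", all.x = TRUE, sort = FALSE)
  if (all(c("rate_pre", "rate_post") %in% names(out))) {
    out$rel_change_hz <- relative_change(out$rate_pre, out$rate_post)$rel_change
  }
  if (all(c("psvue_pre", "psvue_post") %in% names(out))) {
    out$rel_change_psvue <- relative_change(out$psvue_pre,
                                            out$psvue_post)$rel_change
  }
  out
}
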