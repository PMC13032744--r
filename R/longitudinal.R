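#' Match spines across imaging days and annotate survival
#'
#' Estimates a single rigid translation aligning the day-2 field to day 1 by
#' minimising the summed nearest-neighbour distance over candidate shifts
#' (all day-2 minus day-1 centroid differences within `max_shift_px`, plus
#' zero), refined by the mean displacement of provisional matches. Spines
#' are then assigned one-to-one, nearest pair first, ties broken by lowest
#' ROI id; a day-1 spine survives iff its assigned day-2 spine lies within
#' the day-1 spine radius after alignment.
#'
#' @param day1,day2 data.frames with columns `roi`, `x`, `y`, `radius`
#'   (pixels), both from the same dendrite. `day2` may be empty (all spines
#'   lost).
#' @param max_shift_px largest field shift considered.
#' @return list with `shift` (length-2 x/y translation applied to day 2),
#'   `matches` (data.frame `roi_day1`, `roi_day2`, `dist`), and `survived`
#'   (logical, one per day-1 row).
#' @export
match_spines <- function(day1, day2, max_shift_px = 10) {
  stopifnot(is.data.frame(day1), is.data.frame(day2))
  if (nrow(day1) == 0L) stop("no day-1 spines to match")
  if (nrow(day2) == 0L) {
    return(list(shift = c(0, 0),
                matches = data.frame(roi_day1 = integer(0),
                                     roi_day2 = integer(0), dist = numeric(0)),
                survived = rep(FALSE, nrow(day1))))
  }
  nn_cost <- function(sh) {
    sum(vapply(seq_len(nrow(day1)), function(i) {
      min(sqrt((day2$x - sh[1] - day1$x[i])^2 + (day2$y - sh[2] - day1$y[i])^2))
    }, numeric(1)))
  }
  cand <- unique(rbind(c(0, 0), do.call(rbind, lapply(seq_len(nrow(day1)), function(i) {
    cbind(day2$x - day1$x[i], day2$y - day1$y[i])
  }))))
  cand <- cand[abs(cand[, 1]) <= max_shift_px & abs(cand[, 2]) <= max_shift_px, ,
               drop = FALSE]
  costs <- apply(cand, 1, nn_cost)
  shift <- cand[which.min(costs), ]
  # refine: mean displacement of provisional within-radius matches
  for (it in 1:2) {
    disp <- do.call(rbind, lapply(seq_len(nrow(day1)), function(i) {
      d <- sqrt((day2$x - shift[1] - day1$x[i])^2 +
                  (day2$y - shift[2] - day1$y[i])^2)
      j <- which.min(d)
      if (d[j] <= day1$radius[i])
        c(day2$x[j] - day1$x[i], day2$y[j] - day1$y[i]) else NULL
    }))
    if (is.null(disp)) break
    shift <- colMeans(disp)
  }
  # one-to-one greedy assignment: nearest pair first, then id order
  pairs <- expand.grid(i = seq_len(nrow(day1)), j = seq_len(nrow(day2)))
  pairs$dist <- sqrt((day2$x[pairs$j] - shift[1] - day1$x[pairs$i])^2 +
                       (day2$y[pairs$j] - shift[2] - day1$y[pairs$i])^2)
  pairs <- pairs[order(pairs$dist, day1$roi[pairs$i], day2$roi[pairs$j]), ]
  used1 <- logical(nrow(day1)); used2 <- logical(nrow(day2))
  mi <- integer(0); mj <- integer(0); md <- numeric(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used1[i] || used2[j]) next
    if (pairs$dist[k] > day1$radius[i]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    mi <- c(mi, i); mj <- c(mj, j); md <- c(md, pairs$dist[k])
  }
  survived <- logical(nrow(day1)); survived[mi] <- TRUE
  list(shift = as.numeric(shift),
       matches = data.frame(roi_day1 = day1$roi[mi], roi_day2 = day2$roi[mj],
                            dist = md),
       survived = survived)
}

#' Classify astrocyte proximity of a spine
#'
#' A spine counts as astrocyte-proximal if any astrocyte-positive pixel lies
#' within twice the spine radius of its centroid (the ROI extent plus one
#' further spine radius), boundary inclusive - covering both direct signal
#' superposition and astrocyte presence within one synapse radius of the
#' ROI. Only pixels in a window around the centroid are examined; the result
#' is identical to a whole-image scan because farther pixels cannot satisfy
#' the distance bound.
#'
#' @param centroid length-2 `c(x, y)` in pixel coordinates (x = column,
#'   y = row).
#' @param radius spine-head radius in pixels.
#' @param astro_mask logical matrix (rows = y, cols = x).
#' @param reach_radii proximity reach in units of the spine radius
#'   (default 2).
#' @return logical.
#' @export
classify_proximity <- function(centroid, radius, astro_mask, reach_radii = 2) {
  stopifnot(is.matrix(astro_mask), radius > 0, length(centroid) == 2)
  nr <- nrow(astro_mask); nc <- ncol(astro_mask)
  x <- centroid[1]; y <- centroid[2]
  if (x < 1 || x > nc || y < 1 || y > nr)
    stop("spine centroid outside mask bounds")
  reach <- reach_radii * radius
  rows <- max(1L, floor(y - reach)):min(nr, ceiling(y + reach))
  cols <- max(1L, floor(x - reach)):min(nc, ceiling(x + reach))
  sub <- astro_mask[rows, cols, drop = FALSE]
  if (!any(sub)) return(FALSE)
  d2 <- outer((rows - y)^2, (cols - x)^2, `+`)
  any(sub & d2 <= reach^2 + 1e-9)
}

#' Percent spine loss on a dendrite
#'
#' Spines lost after 24 h as a percentage of the spines present on day 1;
#' survivors and lost spines always sum to the day-1 count.
#'
#' @param survived logical vector, one entry per day-1 spine.
#' @return percentage in `[0, 100]`.
#' @export
percent_spine_loss <- function(survived) {
  stopifnot(is.logical(survived) || all(survived %in% c(0, 1)))
  if (!length(survived)) stop("no day-1 spines")
  100 * sum(!as.logical(survived)) / length(survived)
}

#' Per-dendrite survival fractions split by astrocyte proximity
#'
#' @param records data.frame with columns `dendrite`, `survived`,
#'   `proximal` (0/1 or logical).
#' @return data.frame with one row per dendrite: `surv_proximal`,
#'   `surv_nonproximal` (NA when the group is absent on that dendrite),
#'   and group sizes.
#' @export
survival_by_proximity <- function(records) {
  stopifnot(all(c("dendrite", "survived", "proximal") %in% names(records)))
  frac <- function(x) if (length(x)) mean(as.logical(x)) else NA_real_
  out <- do.call(rbind, lapply(split(records, records$dendrite), function(d) {
    pr <- d[as.logical(d$proximal), "survived"]
    np <- d[!as.logical(d$proximal), "survived"]
    data.frame(dendrite = d$dendrite[1],
               surv_proximal = frac(pr), surv_nonproximal = frac(np),
               n_proximal = length(pr), n_nonproximal = length(np))
  }))
  rownames(out) <- NULL
  out
}

#' Relative change (POST - PRE) / PRE
#'
#' The standard relative-change statistic for event rates (delta-Hz/Hz) and
#' PsVue intensities. A spine silent before treatment but active after has
#' an infinite relative change: the `Inf` sentinel is returned and flagged
#' so downstream averaging can exclude and count it. `pre = post = 0` gives
#' 0.
#'
#' @param pre,post non-negative numeric vectors (recycled to equal length).
#' @return data.frame with `pre`, `post`, `rel_change`, `is_infinite`.
#' @export
relative_change <- function(pre, post) {
  stopifnot(is.numeric(pre), is.numeric(post))
  if (any(pre < 0, na.rm = TRUE) || any(post < 0, na.rm = TRUE))
    stop("rates and intensities must be non-negative")
  n <- max(length(pre), length(post))
  pre <- rep_len(pre, n); post <- rep_len(post, n)
  rc <- ifelse(pre > 0, (post - pre) / pre,
               ifelse(post > 0, Inf, 0))
  data.frame(pre = pre, post = post, rel_change = rc,
             is_infinite = is.infinite(rc))
}

#' Mean PsVue intensity in a spine ROI or whole field
#'
#' Background-subtracts each plane of the stack, sums the planes (sum
#' projection), subtracts a post-projection background, and averages over
#' the ROI disc (or the whole field for `psvue_field_intensity`).
#'
#' @param stack numeric matrix (single plane) or 3-D array
#'   (rows, cols, planes).
#' @param centroid,radius ROI disc: `c(x, y)` centre and radius in pixels.
#' @param background per-plane background level subtracted before
#'   projection.
#' @param background_post background subtracted after projection.
#' @return mean intensity over the ROI pixels.
#' @export
psvue_spine_intensity <- function(stack, centroid, radius, background = 0,
                                  background_post = 0) {
  proj <- sum_projection(stack, background) - background_post
  nr <- nrow(proj); nc <- ncol(proj)
  d2 <- outer((seq_len(nr) - centroid[2])^2, (seq_len(nc) - centroid[1])^2, `+`)
  inroi <- d2 <= radius^2
  if (!any(inroi)) stop("ROI contains no pixels")
  mean(proj[inroi])
}

#' @rdname psvue_spine_intensity
#' @export
psvue_field_intensity <- function(stack, background = 0, background_post = 0) {
  mean(sum_projection(stack, background) - background_post)
}

sum_projection <- function(stack, background = 0) {
  if (is.matrix(stack)) return(stack - background)
  stopifnot(length(dim(stack)) == 3)
  apply(stack - background, c(1, 2), sum)
}
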