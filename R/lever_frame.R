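# Lever-centered analyses.
#
# Positions are transformed into a lever-centered coordinate system and the
# direction of the animal around the lever box is measured in one of three
# directional reference frames: Cardinal (zero at south), Bridge (zero
# toward the bridge center), or Lever (zero toward the pressable lever).
# From these come directional tuning curves, the lever-anchored-field
# criteria, the per-trial directional drift, and its coupling with homing
# direction.

# Rotation (deg) taking the Cardinal frame to the requested frame for one
# lever pose.
frame_rotation <- function(pose, geometry, frame) {
  switch(frame,
         cardinal = 0,
         bridge = angle_from_south(geometry$bridge_center[1] - pose$cx,
                                   geometry$bridge_center[2] - pose$cy),
         lever = angle_from_south(pose$dx, pose$dy))
}

#' Transform positions into a lever-centered reference frame
#'
#' Subtracts the lever-box center, rotates so that the frame's reference
#' vector points south, and drops samples farther than the lever-frame
#' radius (12 cm) from the lever-box wall.
#'
#' @param positions Data frame with `t`, `x`, `y`.
#' @param lever_pose List or one-row data frame with `cx`, `cy`, `dx`, `dy`.
#' @param geometry An [arena_geometry()].
#' @param frame `"cardinal"`, `"bridge"`, or `"lever"`.
#' @return Data frame with `t`, lever-centered `x`, `y`, `direction` (deg in
#'   \[-180, 180), measured from the frame's reference vector), and
#'   `wall_distance` (cm).
#' @export
to_lever_frame <- function(positions, lever_pose, geometry,
                           frame = c("cardinal", "bridge", "lever")) {
  frame <- match.arg(frame)
  pose <- as.list(lever_pose)
  wd <- lever_wall_distance(positions$x, positions$y,
                            c(pose$cx, pose$cy), c(pose$dx, pose$dy))
  keep <- wd <= geometry$lever_frame_radius
  p <- positions[keep, , drop = FALSE]
  rot <- frame_rotation(pose, geometry, frame)
  xy <- rotate_xy(p$x - pose$cx, p$y - pose$cy, -rot)
  data.frame(t = p$t, x = xy$x, y = xy$y,
             direction = angle_from_south(xy$x, xy$y),
             wall_distance = wd[keep])
}

# Pool lever-frame data over the lever-pressed journeys of a condition,
# using each trial's own lever pose.
collect_lever_frame <- function(session, trials, journeys, light = NULL,
                                frame = "cardinal", journey_subset = NULL) {
  j <- journeys[journeys$lever_pressed, , drop = FALSE]
  keep_tr <- trials$trial_id[!trials$excluded &
                               (if (is.null(light)) TRUE else trials$light == light)]
  j <- j[j$trial_id %in% keep_tr, , drop = FALSE]
  if (!is.null(journey_subset)) j <- j[journey_subset(seq_len(nrow(j))), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(j))) {
    tr <- trials[trials$trial_id == j$trial_id[i], ]
    p <- positions_between(session, j$t_start[i], j$t_end[i])
    fd <- to_lever_frame(p, list(cx = tr$lever_cx, cy = tr$lever_cy,
                                 dx = tr$lever_dx, dy = tr$lever_dy),
                         session$geometry, frame)
    if (nrow(fd)) out[[length(out) + 1]] <- fd
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Directional tuning around the lever box
#'
#' Occupancy-normalized firing rate in 36 bins of 10 degrees, circularly
#' smoothed (kernel SD 1 bin). The mean vector length and preferred
#' direction are computed from the rate-weighted resultant of the bin
#' centers by default; `method = "spikes"` uses the raw per-spike
#' directions instead (not occupancy-corrected).
#'
#' @param frame_data Output of [to_lever_frame()] (possibly pooled over
#'   journeys).
#' @param spike_times Spike times of one neuron.
#' @param method `"rate_vector"` (default) or `"spikes"`.
#' @return Object of class `directional_tuning` with the binned `rate`,
#'   `mvl`, `preferred_direction` (deg), and `peak_rate` (Hz).
#' @export
directional_tuning <- function(frame_data, spike_times,
                               method = c("rate_vector", "spikes")) {
  method <- match.arg(method)
  if (is.null(frame_data) || !nrow(frame_data)) stop("zero occupancy everywhere")
  h <- rate_histogram_1d(frame_data$direction, dwell_times(frame_data$t),
                         frame_data$direction[restrict_spikes(spike_times, frame_data)],
                         range = c(-180, 180), n_bins = 36,
                         smoothing_sd = 1, circular = TRUE)
  if (method == "rate_vector") {
    w <- ifelse(is.finite(h$rate), pmax(h$rate, 0), 0)
    mvl <- mean_vector_length(h$mids, w)
    pd <- circular_mean(h$mids, w)
  } else {
    sd_dir <- frame_data$direction[restrict_spikes(spike_times, frame_data)]
    mvl <- mean_vector_length(sd_dir)
    pd <- circular_mean(sd_dir)
  }
  structure(list(breaks = h$breaks, mids = h$mids, occupancy = h$occupancy,
                 rate = h$rate, mvl = mvl, preferred_direction = pd,
                 peak_rate = if (any(is.finite(h$rate))) max(h$rate, na.rm = TRUE) else 0,
                 n_spikes = sum(h$spike_count), mean_rate = h$mean_rate),
            class = "directional_tuning")
}

# Firing rate as a function of lever-wall distance over pooled journeys:
# occupancy and rate smoothed with SD 1 bin over 2-cm bins.
lever_distance_curve <- function(distance, dwell, spike_distance,
                                 breaks = seq(0, 40, by = 2)) {
  n_bins <- length(breaks) - 1
  bin_of <- function(v) {
    b <- findInterval(v, breaks, rightmost.closed = TRUE)
    b[b < 1 | b > n_bins] <- NA
    b
  }
  bx <- bin_of(distance)
  occ <- vapply(seq_len(n_bins), function(b) sum(dwell[which(bx == b)]), numeric(1))
  spk <- tabulate(bin_of(spike_distance), nbins = n_bins)
  occ_na <- ifelse(occ > 0, occ, NA)
  occ_s <- smooth_1d(occ_na, 1)
  rate <- smooth_1d(spk / occ_s, 1)
  list(mids = (breaks[-1] + breaks[-length(breaks)]) / 2, occupancy = occ,
       rate = rate)
}

#' Classify a lever-box-anchored firing field
#'
#' A neuron has a lever-anchored field in a condition and reference frame
#' when (1) the peak of its firing-rate-vs-lever-distance curve lies within
#' 10 cm of the box wall and exceeds the 95th percentile of a shuffle
#' distribution (circular time-shifts of the spike train by at least 20 s),
#' (2) the peak of its 2D lever-centered rate map (1-cm bins, 2-cm kernel
#' SD) exceeds 7.5 Hz, and (3) the Pearson similarity between lever-centered
#' maps from two independent sets of trials (odd/even lever-pressed
#' journeys) exceeds 0.4.
#'
#' @param session A `homing_session`.
#' @param trials,journeys Outputs of [segment_trials()]/[segment_journeys()].
#' @param neuron_id Neuron name.
#' @param light Condition (`TRUE`, `FALSE`, or `NULL` for all trials).
#' @param frame Directional reference frame.
#' @param n_shuffles Shuffles for criterion 1 (default 500).
#' @param seed RNG seed for the shuffles.
#' @param min_journeys Minimum lever-pressed journeys required (default 10).
#' @return Object of class `lever_anchored_result`: criterion flags
#'   (`peak_near_lever`, `peak_rate_ok`, `split_half_stable`), `anchored`
#'   (all three), the measured values, and the directional tuning summary
#'   (`mvl`, `preferred_direction`, `peak_rate`).
#' @export
classify_lever_anchored <- function(session, trials, journeys, neuron_id,
                                    light = NULL,
                                    frame = c("cardinal", "bridge", "lever"),
                                    n_shuffles = 500, seed = 1,
                                    min_journeys = 10) {
  frame <- match.arg(frame)
  g <- session$geometry
  spk <- session$spikes[[neuron_id]]
  if (is.null(spk)) stop("unknown neuron: ", neuron_id)
  j <- journeys[journeys$lever_pressed, , drop = FALSE]
  keep_tr <- trials$trial_id[!trials$excluded &
                               (if (is.null(light)) TRUE else trials$light == light)]
  j <- j[j$trial_id %in% keep_tr, , drop = FALSE]
  if (nrow(j) < min_journeys)
    stop("need at least ", min_journeys, " lever-pressed journeys, got ", nrow(j))

  # pooled journey samples with per-trial lever-wall distance
  pooled <- list()
  for (i in seq_len(nrow(j))) {
    tr <- trials[trials$trial_id == j$trial_id[i], ]
    p <- positions_between(session, j$t_start[i], j$t_end[i])
    p$wall_distance <- lever_wall_distance(p$x, p$y,
                                           c(tr$lever_cx, tr$lever_cy),
                                           c(tr$lever_dx, tr$lever_dy))
    p$odd <- i %% 2 == 1
    pooled[[i]] <- p
  }
  pooled <- do.call(rbind, pooled)
  dw <- dwell_times(pooled$t)

  # criterion 1: distance-curve peak near the box, above the shuffle null.
  # The occupancy term is identical across shuffles, so it is smoothed once
  # and only the spike binning is recomputed per circular time-shift.
  breaks <- seq(0, 40, by = 2)
  n_bins <- length(breaks) - 1
  bx <- findInterval(pooled$wall_distance, breaks, rightmost.closed = TRUE)
  bx[bx < 1 | bx > n_bins] <- NA
  occ <- vapply(seq_len(n_bins), function(b) sum(dw[which(bx == b)]), numeric(1))
  occ_s <- smooth_1d(ifelse(occ > 0, occ, NA), 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  curve_rate <- function(spike_times) {
    sb <- bx[restrict_spikes(spike_times, pooled)]
    smooth_1d(tabulate(sb[!is.na(sb)], nbins = n_bins) / occ_s, 1)
  }
  rate_c <- curve_rate(spk)
  pk <- which.max(rate_c)
  peak_rate_dist <- rate_c[pk]
  peak_loc <- mids[pk]
  set.seed(seed)
  t0 <- min(session$positions$t); t1 <- max(session$positions$t)
  span <- t1 - t0
  null_peaks <- vapply(seq_len(n_shuffles), function(i) {
    off <- stats::runif(1, 20, span - 20)
    rs <- curve_rate(sort(t0 + (spk - t0 + off) %% span))
    if (any(is.finite(rs))) max(rs, na.rm = TRUE) else 0
  }, numeric(1))
  crit1 <- is.finite(peak_rate_dist) && peak_loc <= 10 &&
    peak_rate_dist > stats::quantile(null_peaks, 0.95, names = FALSE)

  # criteria 2 and 3 on lever-centered maps within the 12-cm frame radius
  lever_map <- function(subset) {
    fr <- list()
    for (i in seq_len(nrow(j))) {
      if (!is.null(subset) && (i %% 2 == 1) != subset) next
      tr <- trials[trials$trial_id == j$trial_id[i], ]
      p <- positions_between(session, j$t_start[i], j$t_end[i])
      fd <- to_lever_frame(p, list(cx = tr$lever_cx, cy = tr$lever_cy,
                                   dx = tr$lever_dx, dy = tr$lever_dy), g, frame)
      if (nrow(fd)) fr[[length(fr) + 1]] <- fd
    }
    if (!length(fr)) return(NULL)
    fr <- do.call(rbind, fr)
    rate_map_2d(fr, spk, bin_size = 1, smoothing_sd = 2,
                xlim = c(-12, 12), ylim = c(-12, 12))
  }
  full_map <- lever_map(NULL)
  peak2d <- if (is.null(full_map)) 0 else map_peak_rate(full_map)
  crit2 <- peak2d > 7.5
  m_odd <- lever_map(TRUE); m_even <- lever_map(FALSE)
  split_r <- if (is.null(m_odd) || is.null(m_even)) NA_real_ else
    map_similarity(m_odd, m_even)
  crit3 <- is.finite(split_r) && split_r > 0.4

  fd_all <- collect_lever_frame(session, trials, journeys, light, frame)
  tun <- tryCatch(directional_tuning(fd_all, spk), error = function(e) NULL)

  structure(list(neuron_id = neuron_id, frame = frame, light = light,
                 peak_near_lever = crit1, peak_rate_ok = crit2,
                 split_half_stable = crit3,
                 anchored = crit1 && crit2 && crit3,
                 distance_peak_rate = peak_rate_dist,
                 distance_peak_location = peak_loc,
                 map_peak_rate = peak2d, split_half_r = split_r,
                 mvl = if (is.null(tun)) NA_real_ else tun$mvl,
                 preferred_direction = if (is.null(tun)) NA_real_ else
                   tun$preferred_direction,
                 n_journeys = nrow(j)),
            class = "lever_anchored_result")
}

# Circularly roll a vector left by k bins (element k+1 becomes first).
roll_left <- function(v, k) {
  n <- length(v)
  k <- ((k %% n) + n) %% n
  if (k == 0) v else c(v[(k + 1):n], v[1:k])
}

# Circular cross-correlation of mean-subtracted vectors; NA treated as the
# row mean (zero after centering). Returns one value per lag 0..n-1, where
# lag L measures agreement of `row` with `ref` shifted forward by L bins.
circ_xcorr <- function(row, ref) {
  n <- length(row)
  center <- function(v) {
    m <- mean(v, na.rm = TRUE)
    ifelse(is.finite(v), v - m, 0)
  }
  r <- center(row); f <- center(ref)
  vapply(0:(n - 1), function(L) sum(r * roll_left(f, -L)), numeric(1))
}

#' Per-trial directional drift of a lever-anchored field
#'
#' From a direction trial matrix: (i) the matrix is circularly rolled so the
#' peak of the mean firing rate sits at direction 0; (ii) an idealized
#' tuning curve is built by re-aligning each row's own peak to 0 and
#' averaging; (iii) each row is circularly cross-correlated with the
#' idealized curve; (iv) the drift is the lag of the cross-correlation
#' maximum (degrees in \[-180, 180)), refined by parabolic interpolation
#' around the peak; ties go to the smaller absolute lag. Zero-rate rows are
#' masked.
#'
#' @param matrix A `trial_matrix` on `lever_direction`.
#' @param reference Optional fixed tuning curve (length = number of bins).
#'   When supplied, steps (i)-(ii) are skipped and each row's drift is its
#'   lag relative to this curve; the estimator is then exactly
#'   shift-equivariant (adding a circular shift c to every row adds c to
#'   every drift). The default (NULL) follows the peak-aligned procedure,
#'   which measures drift relative to the session-average tuning and
#'   therefore absorbs a common shift of all rows.
#' @param min_rows Minimum usable rows (default 5).
#' @return Object of class `drift_result` with `delta` (deg per row, NA for
#'   masked rows), the `idealized` tuning curve, and the row metadata.
#' @export
trial_drift <- function(matrix, reference = NULL, min_rows = 5) {
  stopifnot(inherits(matrix, "trial_matrix"))
  if (!matrix$circular) stop("trial_drift requires a circular (direction) matrix")
  rate <- matrix$rate
  n <- ncol(rate)
  bw <- matrix$bin_size
  ok <- usable_rows(rate)
  if (sum(ok) < min_rows) stop("fewer than ", min_rows, " usable rows")
  mean_curve <- colMeans(rate, na.rm = TRUE)
  if (!any(is.finite(mean_curve))) stop("all rows masked")
  if (is.null(reference)) {
    shift0 <- which.max(mean_curve) - 1
    rolled <- t(apply(rate, 1, roll_left, k = shift0))
    aligned <- t(apply(rolled, 1, function(r) {
      if (!any(is.finite(r))) return(r)
      roll_left(r, which.max(r) - 1)
    }))
    idealized <- colMeans(aligned[ok, , drop = FALSE], na.rm = TRUE)
  } else {
    stopifnot(length(reference) == n)
    shift0 <- 0
    rolled <- rate
    idealized <- reference
  }
  delta <- rep(NA_real_, nrow(rate))
  for (i in which(ok)) {
    cc <- circ_xcorr(rolled[i, ], idealized)
    mx <- max(cc)
    cand <- which(cc >= mx - 1e-12) - 1
    lags <- ifelse(cand > n / 2, cand - n, cand)
    L <- lags[which.min(abs(lags))]
    k <- ((L %% n) + n) %% n
    y0 <- cc[k + 1]
    yl <- cc[((k - 1 + n) %% n) + 1]
    yr <- cc[((k + 1) %% n) + 1]
    denom <- yl - 2 * y0 + yr
    off <- if (abs(denom) > 1e-12) 0.5 * (yl - yr) / denom else 0
    off <- max(min(off, 0.5), -0.5)
    delta[i] <- wrap180((L + off) * bw)
  }
  structure(list(delta = delta, usable = ok, idealized = idealized,
                 mean_peak_shift = shift0 * bw, meta = matrix$meta,
                 bin_size = bw),
            class = "drift_result")
}

#' Coupling between trial drift and homing direction
#'
#' Fisher-Lee circular-circular correlation between the per-trial drift of
#' a lever-anchored field and the homing direction of the animal, with a
#' permutation p-value (homing directions shuffled across trials) and the
#' least-squares slope of drift on homing direction after centering both on
#' their circular means.
#'
#' @param drift A `drift_result` or a numeric vector of drifts (deg).
#' @param homing Per-trial homing directions (deg); defaults to the drift
#'   row metadata.
#' @param n_shuffles Number of permutations (default 500).
#' @param seed RNG seed.
#' @return List with `r`, `p`, `slope`, and `n` pairs.
#' @export
drift_homing_coupling <- function(drift, homing = NULL, n_shuffles = 500,
                                  seed = 1) {
  delta <- if (inherits(drift, "drift_result")) drift$delta else drift
  if (is.null(homing)) {
    if (!inherits(drift, "drift_result") || is.null(drift$meta$homing_direction))
      stop("homing directions required")
    homing <- drift$meta$homing_direction
  }
  ok <- is.finite(delta) & is.finite(homing)
  delta <- delta[ok]; homing <- homing[ok]
  if (length(delta) < 10) stop("need at least 10 paired drift/homing values")
  if (diff(range(delta)) == 0) stop("degenerate (constant) drift")
  r_obs <- circular_correlation(delta, homing)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(i)
    circular_correlation(delta, homing[sample.int(length(homing))]),
    numeric(1))
  p <- (sum(abs(null) >= abs(r_obs)) + 1) / (n_shuffles + 1)
  dc <- wrap180(delta - circular_mean(delta))
  hc <- wrap180(homing - circular_mean(homing))
  slope <- sum(dc * hc) / sum(hc^2)
  list(r = r_obs, p = p, slope = slope, n = length(delta))
}

#' Preferred-direction change across a homing split
#'
#' Splits trials at the median homing direction, computes the pooled
#' directional tuning curve of each group from the rows of a direction
#' trial matrix, and tests the circular difference in preferred direction
#' against a null built by shuffling the homing directions.
#'
#' @param matrix A `trial_matrix` on `lever_direction` with homing
#'   directions in its row metadata (or supplied via `homing`).
#' @param homing Optional per-row homing directions (deg).
#' @param n_shuffles Number of shuffles (default 500).
#' @param seed RNG seed.
#' @param min_group Minimum rows per group (default 5).
#' @return List with `delta_pd` (deg, high minus low group), `p`, and the
#'   two groups' preferred directions.
#' @export
preferred_direction_split_test <- function(matrix, homing = NULL,
                                           n_shuffles = 500, seed = 1,
                                           min_group = 5) {
  stopifnot(inherits(matrix, "trial_matrix"))
  if (is.null(homing)) homing <- matrix$meta$homing_direction
  ok <- is.finite(homing) & apply(matrix$rate_raw, 1, function(r) any(is.finite(r)))
  if (sum(ok) < 2 * min_group) stop("too few rows with homing directions")
  spk <- matrix$rate_raw * matrix$occupancy  # per-row spike counts per bin
  occ <- matrix$occupancy
  group_pd <- function(rows) {
    s <- colSums(spk[rows, , drop = FALSE], na.rm = TRUE)
    o <- colSums(occ[rows, , drop = FALSE], na.rm = TRUE)
    r <- ifelse(o > 0, s / o, NA)
    r <- smooth_1d(r, 1, circular = TRUE)
    circular_mean(matrix$mids, ifelse(is.finite(r), pmax(r, 0), 0))
  }
  idx <- which(ok)
  split_delta <- function(h) {
    grp <- split_trials_by_median(h)
    lo <- idx[grp$low]; hi <- idx[grp$high]
    if (length(lo) < min_group || length(hi) < min_group)
      stop("homing split group too small")
    wrap180(group_pd(hi) - group_pd(lo))
  }
  d_obs <- split_delta(homing[idx])
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(i)
    split_delta(homing[idx][sample.int(length(idx))]), numeric(1))
  list(delta_pd = d_obs,
       p = (sum(abs(null) >= abs(d_obs)) + 1) / (n_shuffles + 1))
}
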