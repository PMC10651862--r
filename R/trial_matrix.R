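# Single-trial firing rate matrices.
#
# Each row is one lever-pressed journey; columns are bins of a behavioral
# variable (y coordinate, distance from the lever box, or direction around
# the lever box). Rows are smoothed with a 1D Gaussian kernel of SD 2 bins
# (wrapping for the direction variable). The trial matrix correlation (mean
# pairwise Pearson r between rows) measures across-trial reliability, and
# the peak-location-vs-lever test detects lever-distance coding against a
# within-row shuffle null.

#' Build a trial firing rate matrix
#'
#' @param session A `homing_session`.
#' @param trials,journeys Outputs of [segment_trials()] and
#'   [segment_journeys()].
#' @param neuron_id Name of the neuron in `session$spikes`.
#' @param variable `"y_coordinate"` (2-cm bins), `"lever_distance"` (2-cm
#'   bins), or `"lever_direction"` (20-degree bins, circular).
#' @param segment Which part of each journey to use: `"search"`,
#'   `"homing"`, or `"at_lever"` (samples within the lever-frame radius,
#'   used for directional matrices).
#' @param light `TRUE`/`FALSE` to restrict to one condition, `NULL` for all
#'   trials.
#' @param frame Directional reference frame for `"lever_direction"`.
#' @param row_smoothing_sd Row kernel SD in bins (default 2).
#' @param min_occupied_bins Rows from journeys occupying fewer bins are
#'   dropped (default 5).
#' @return Object of class `trial_matrix`: smoothed `rate` (rows x bins),
#'   raw rate and occupancy, bin `mids`, and per-row metadata (trial id,
#'   lever y position, homing direction, light flag).
#' @export
build_trial_matrix <- function(session, trials, journeys, neuron_id,
                               variable = c("y_coordinate", "lever_distance",
                                            "lever_direction"),
                               segment = c("search", "homing", "at_lever"),
                               light = NULL,
                               frame = c("cardinal", "bridge", "lever"),
                               row_smoothing_sd = 2, min_occupied_bins = 5) {
  variable <- match.arg(variable)
  segment <- match.arg(segment)
  frame <- match.arg(frame)
  g <- session$geometry
  spk_all <- session$spikes[[neuron_id]]
  if (is.null(spk_all)) stop("unknown neuron: ", neuron_id)
  circular <- variable == "lever_direction"
  if (circular) {
    br <- seq(-180, 180, by = 20)
  } else if (variable == "y_coordinate") {
    br <- seq(-42.5, 39.5, by = 2)
  } else {
    br <- seq(0, 40, by = 2)
  }
  n_bins <- length(br) - 1
  j <- journeys[journeys$lever_pressed, , drop = FALSE]
  keep_tr <- trials$trial_id[!trials$excluded &
                               (if (is.null(light)) TRUE else trials$light == light)]
  j <- j[j$trial_id %in% keep_tr, , drop = FALSE]
  if (nrow(j) < 2) stop("need at least 2 lever-pressed journeys in condition")
  hg <- tryCatch(homing_geometry(j, trials, g), error = function(e) NULL)
  rate_raw <- occ_m <- matrix(NA_real_, nrow(j), n_bins)
  meta <- list()
  for (i in seq_len(nrow(j))) {
    ji <- j[i, ]
    tr <- trials[trials$trial_id == ji$trial_id, ]
    iv <- switch(segment,
                 search = c(ji$search_start, ji$search_end),
                 homing = c(ji$homing_start, ji$homing_end),
                 at_lever = c(ji$t_start, ji$t_end))
    if (anyNA(iv)) next
    p <- positions_between(session, iv[1], iv[2])
    if (nrow(p) < 2) next
    if (segment == "at_lever" || variable != "y_coordinate") {
      wd <- lever_wall_distance(p$x, p$y, c(tr$lever_cx, tr$lever_cy),
                                c(tr$lever_dx, tr$lever_dy))
    }
    if (segment == "at_lever") {
      p <- p[wd <= g$lever_frame_radius, , drop = FALSE]
      if (nrow(p) < 2) next
    }
    val <- switch(variable,
      y_coordinate = p$y,
      lever_distance = lever_wall_distance(p$x, p$y,
                                           c(tr$lever_cx, tr$lever_cy),
                                           c(tr$lever_dx, tr$lever_dy)),
      lever_direction = direction_around_lever(
        p$x, p$y,
        list(cx = tr$lever_cx, cy = tr$lever_cy,
             dx = tr$lever_dx, dy = tr$lever_dy), g, frame))
    dw <- dwell_times(p$t)
    sidx <- restrict_spikes(spk_all, p)
    bin_of <- function(v) {
      b <- findInterval(v, br, rightmost.closed = TRUE)
      b[b < 1 | b > n_bins] <- NA
      b
    }
    bx <- bin_of(val)
    occ <- vapply(seq_len(n_bins), function(b) sum(dw[which(bx == b)]), numeric(1))
    if (sum(occ > 0) < min_occupied_bins) next
    spk <- tabulate(bin_of(val[sidx]), nbins = n_bins)
    rr <- ifelse(occ > 0, spk / occ, NA)
    rate_raw[i, ] <- rr
    occ_m[i, ] <- occ
    meta[[length(meta) + 1]] <- data.frame(
      row = i, trial_id = ji$trial_id, journey_id = ji$journey_id,
      light = tr$light, lever_y = tr$lever_cy,
      homing_direction = if (!is.null(hg)) {
        hm <- hg$homing_direction[hg$trial_id == ji$trial_id &
                                    hg$journey_id == ji$journey_id]
        if (length(hm)) hm[1] else NA_real_
      } else NA_real_)
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    stop("no usable journeys for trial matrix")
  rate_raw <- rate_raw[meta$row, , drop = FALSE]
  occ_m <- occ_m[meta$row, , drop = FALSE]
  meta$row <- NULL
  if (nrow(rate_raw) < 2) stop("need at least 2 usable rows")
  rate <- t(apply(rate_raw, 1, smooth_1d, sd_bins = row_smoothing_sd,
                  circular = circular))
  structure(list(variable = variable, segment = segment, frame = frame,
                 breaks = br, mids = (br[-1] + br[-length(br)]) / 2,
                 bin_size = diff(br)[1], rate = rate, rate_raw = rate_raw,
                 occupancy = occ_m, meta = meta, circular = circular,
                 row_smoothing_sd = row_smoothing_sd),
            class = "trial_matrix")
}

# Rows with at least 2 finite values and nonzero variance.
usable_rows <- function(rate) {
  apply(rate, 1, function(r) {
    r <- r[is.finite(r)]
    length(r) >= 2 && stats::sd(r) > 0
  })
}

#' Trial matrix correlation
#'
#' Pearson correlation for every distinct pair of rows (over jointly valid
#' bins), averaged over the off-diagonal upper triangle. Zero-variance rows
#' are excluded and counted.
#'
#' @param matrix A `trial_matrix`, or a plain numeric matrix of row rates.
#' @return List with `value`, `n_pairs`, and `n_excluded` rows.
#' @export
trial_matrix_correlation <- function(matrix) {
  rate <- if (inherits(matrix, "trial_matrix")) matrix$rate else matrix
  ok <- usable_rows(rate)
  if (sum(ok) < 2) stop("fewer than 2 rows with nonzero variance")
  cm <- suppressWarnings(stats::cor(t(rate[ok, , drop = FALSE]),
                                    use = "pairwise.complete.obs"))
  up <- cm[upper.tri(cm)]
  up <- up[is.finite(up)]
  if (!length(up)) stop("no valid row pairs")
  list(value = mean(up), n_pairs = length(up), n_excluded = sum(!ok))
}

# Shuffle the finite values within each row (multiset preserved exactly).
shuffle_within_rows <- function(rate) {
  t(apply(rate, 1, function(r) {
    f <- which(is.finite(r))
    r[f] <- r[f][sample.int(length(f))]
    r
  }))
}

#' Significance of a trial matrix correlation
#'
#' Compares the observed trial matrix correlation against a null built by
#' shuffling the firing rate values within each row.
#'
#' @param matrix A `trial_matrix`.
#' @param n_shuffles Number of shuffles (default 500).
#' @param seed RNG seed.
#' @return List with `value`, `p` (fraction of shuffles >= observed), and
#'   the null distribution.
#' @export
trial_matrix_correlation_test <- function(matrix, n_shuffles = 500, seed = 1) {
  obs <- trial_matrix_correlation(matrix)
  rate <- matrix$rate
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(i) {
    trial_matrix_correlation(shuffle_within_rows(rate))$value
  }, numeric(1))
  list(value = obs$value, n_pairs = obs$n_pairs,
       p = (sum(null >= obs$value) + 1) / (n_shuffles + 1), null = null)
}

# Per-row peak location: bin center of the row maximum; ties resolved by
# the bin closest to the row's (circular) center of mass.
row_peak_locations <- function(rate, mids, circular) {
  apply(rate, 1, function(r) {
    f <- is.finite(r)
    if (!any(f)) return(NA_real_)
    mx <- max(r[f])
    cand <- which(f & r >= mx - 1e-12)
    if (length(cand) == 1) return(mids[cand])
    com <- if (circular) circular_mean(mids[f], pmax(r[f], 0))
           else sum(mids[f] * pmax(r[f], 0)) / sum(pmax(r[f], 0))
    d <- if (circular) abs(wrap180(mids[cand] - com)) else abs(mids[cand] - com)
    pick <- which.min(d)
    if (!length(pick)) pick <- 1  # fully tied row (e.g. constant rate)
    mids[cand[pick]]
  })
}

#' Peak-location-vs-lever-position test
#'
#' Tests whether the per-trial location of the firing rate peak (in the
#' y-coordinate trial matrix) follows the y position of the lever box. The
#' null distribution is built by permuting the firing rate values within
#' each row and recomputing the correlation; the observed r is significant
#' when it exceeds the null's 95th percentile.
#'
#' @param matrix A `trial_matrix` on the y coordinate.
#' @param lever_y Lever y positions per row; defaults to the matrix row
#'   metadata.
#' @param n_shuffles Number of within-row shuffles (default 500).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed.
#' @return List with `r`, `p`, `significant`, per-row `peaks`, and the null
#'   distribution of r.
#' @export
peak_location_vs_lever <- function(matrix, lever_y = NULL, n_shuffles = 500,
                                   alpha = 0.05, seed = 1) {
  if (is.null(lever_y)) lever_y <- matrix$meta$lever_y
  ok <- usable_rows(matrix$rate) & is.finite(lever_y)
  if (sum(ok) < 5) stop("fewer than 5 usable rows")
  rate <- matrix$rate[ok, , drop = FALSE]
  ly <- lever_y[ok]
  peaks <- row_peak_locations(rate, matrix$mids, matrix$circular)
  r_obs <- stats::cor(peaks, ly)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(i) {
    sp <- row_peak_locations(shuffle_within_rows(rate), matrix$mids,
                             matrix$circular)
    suppressWarnings(stats::cor(sp, ly))
  }, numeric(1))
  null <- null[is.finite(null)]
  crit <- stats::quantile(null, 1 - alpha, names = FALSE)
  list(r = r_obs,
       p = (sum(null >= r_obs) + 1) / (length(null) + 1),
       significant = r_obs > crit, peaks = peaks, null = null)
}
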