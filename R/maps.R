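# Firing-rate maps and histograms.
#
# Occupancy uses per-sample dwell time (gap to the next sample, capped at 3x
# the median gap). Gaussian smoothing renormalizes the kernel over valid
# bins, so there is no zero-padding bleed at the arena edge; bins never
# visited before smoothing stay masked.

# Gaussian kernel over +-4 SD (in bins); sd 0 gives an identity kernel.
gauss_kernel <- function(sd_bins) {
  if (sd_bins <= 0) return(1)
  half <- max(1, ceiling(4 * sd_bins))
  k <- exp(-((-half:half)^2) / (2 * sd_bins^2))
  k / sum(k)
}

# 1D smoothing with renormalization over valid (non-NA) bins; circular
# wraps around the ends.
smooth_1d <- function(v, sd_bins, circular = FALSE) {
  k <- gauss_kernel(sd_bins)
  if (length(k) == 1) return(v)
  valid <- as.numeric(is.finite(v))
  v0 <- ifelse(is.finite(v), v, 0)
  n <- length(v)
  half <- (length(k) - 1) / 2
  if (circular) {
    pad <- function(z) c(z[(n - half + 1):n], z, z[1:half])
    num <- stats::convolve(pad(v0), rev(k), type = "filter")
    den <- stats::convolve(pad(valid), rev(k), type = "filter")
  } else {
    pad <- function(z) c(rep(0, half), z, rep(0, half))
    num <- stats::convolve(pad(v0), rev(k), type = "filter")
    den <- stats::convolve(pad(valid), rev(k), type = "filter")
  }
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  ifelse(is.finite(v), out, NA_real_)
}

# Separable 2D smoothing with valid-bin renormalization; NA = invalid.
smooth_2d <- function(m, sd_bins) {
  k <- gauss_kernel(sd_bins)
  if (length(k) == 1) return(m)
  valid <- is.finite(m)
  m0 <- ifelse(valid, m, 0)
  conv_mat <- function(z) {
    z1 <- apply(z, 2, function(col) sconv(col, k))
    t(apply(z1, 1, function(row) sconv(row, k)))
  }
  num <- conv_mat(m0)
  den <- conv_mat(valid * 1)
  out <- ifelse(den > 1e-12, num / den, NA_real_)
  out[!valid] <- NA_real_
  out
}

# same-length linear convolution, zero padded
sconv <- function(v, k) {
  half <- (length(k) - 1) / 2
  stats::convolve(c(rep(0, half), v, rep(0, half)), rev(k), type = "filter")
}

# Map spike times onto rows of a (possibly condition-restricted) position
# table; spikes falling in gaps longer than the dwell cap are dropped.
restrict_spikes <- function(spike_times, positions) {
  idx <- spike_sample_index(spike_times, positions$t)
  ok <- !is.na(idx)
  gap <- spike_times[ok] - positions$t[idx[ok]]
  cap <- 3 * stats::median(diff(positions$t))
  idx[ok][gap <= cap]
}

#' 2D firing rate map
#'
#' Occupancy (seconds per bin) is Gaussian-smoothed; spike counts per bin
#' are divided by the smoothed occupancy and the resulting rate map is
#' smoothed again. Defaults are 3-cm bins with a 5-cm kernel SD for arena
#' maps; lever-centered maps use 1-cm bins with a 2-cm SD.
#'
#' @param positions Data frame with `t`, `x`, `y`; may be a concatenation
#'   of path segments (dwell times are capped across gaps).
#' @param spike_times Spike times (s) of one neuron.
#' @param bin_size Bin side (cm).
#' @param smoothing_sd Gaussian kernel SD (cm).
#' @param xlim,ylim Map extent (cm).
#' @return Object of class `rate_map`: bin edges, raw and smoothed
#'   occupancy, spike counts, smoothed `rate`, and a validity mask (bins
#'   with nonzero raw occupancy).
#' @export
rate_map_2d <- function(positions, spike_times, bin_size = 3, smoothing_sd = 5,
                        xlim = NULL, ylim = NULL) {
  stopifnot(bin_size > 0)
  if (!nrow(positions)) stop("no position samples")
  if (is.null(xlim)) xlim <- range(positions$x)
  if (is.null(ylim)) ylim <- range(positions$y)
  xe <- seq(floor(xlim[1] / bin_size) * bin_size,
            ceiling(xlim[2] / bin_size) * bin_size + bin_size, by = bin_size)
  ye <- seq(floor(ylim[1] / bin_size) * bin_size,
            ceiling(ylim[2] / bin_size) * bin_size + bin_size, by = bin_size)
  nx <- length(xe) - 1; ny <- length(ye) - 1
  ix <- findInterval(positions$x, xe, rightmost.closed = TRUE)
  iy <- findInterval(positions$y, ye, rightmost.closed = TRUE)
  inb <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  dw <- dwell_times(positions$t)
  occ <- matrix(0, nx, ny)
  for (s in which(inb)) occ[ix[s], iy[s]] <- occ[ix[s], iy[s]] + dw[s]
  if (sum(occ) == 0) stop("zero total occupancy")
  sidx <- restrict_spikes(spike_times, positions)
  spk <- matrix(0, nx, ny)
  keep <- sidx[inb[sidx]]
  for (s in keep) spk[ix[s], iy[s]] <- spk[ix[s], iy[s]] + 1
  valid <- occ > 0
  occ_na <- occ; occ_na[!valid] <- NA
  spk_na <- spk; spk_na[!valid] <- NA
  sdb <- smoothing_sd / bin_size
  occ_s <- smooth_2d(occ_na, sdb)
  rate <- smooth_2d(spk_na / occ_s, sdb)
  structure(list(bin_size = bin_size, x_edges = xe, y_edges = ye,
                 occupancy_raw = occ, occupancy = occ_s,
                 spike_count = spk, rate = rate, valid = valid,
                 smoothing_sd = smoothing_sd),
            class = "rate_map")
}

#' Peak firing rate of a map
#' @param map A `rate_map`.
#' @return Maximum smoothed rate (Hz) over valid bins.
#' @export
map_peak_rate <- function(map) {
  if (!any(is.finite(map$rate))) return(0)
  max(map$rate, na.rm = TRUE)
}

#' Common histogram range across light and dark conditions
#'
#' The maximum is the smaller of the two conditions' 90th percentiles; the
#' minimum is fixed at -42.5 cm for the y coordinate (the gap between arena
#' and bridge) and 12.0 cm for the distance from the lever box, ensuring
#' sufficient sampling in all bins.
#'
#' @param values_light,values_dark Per-sample values of the behavioral
#'   variable in the two conditions.
#' @param variable `"y_coordinate"` or `"lever_distance"`.
#' @return Numeric `c(min, max)`.
#' @export
histogram_range <- function(values_light, values_dark,
                            variable = c("y_coordinate", "lever_distance")) {
  variable <- match.arg(variable)
  if (!length(values_light) || !length(values_dark))
    stop("both condition samples must be non-empty")
  hi <- min(stats::quantile(values_light, 0.9, names = FALSE),
            stats::quantile(values_dark, 0.9, names = FALSE))
  lo <- if (variable == "y_coordinate") -42.5 else 12.0
  c(lo, hi)
}

#' 1D firing rate histogram
#'
#' 20 bins over a fixed range. Occupancy is smoothed with a Gaussian kernel
#' of SD 1 bin; the rate (spikes / smoothed occupancy) is smoothed the same
#' way. Unsmoothed occupancy probabilities and rates are retained for the
#' information score. Bins with zero pre-smoothing occupancy are masked.
#'
#' @param x Per-sample values of the behavioral variable (pooled paths of
#'   one condition).
#' @param dwell Per-sample dwell times (s), same length as `x`.
#' @param spike_x Variable values at spike times.
#' @param range Numeric `c(min, max)` from [histogram_range()].
#' @param n_bins Number of bins (default 20).
#' @param smoothing_sd Kernel SD in bins (default 1).
#' @param circular Wrap smoothing around the ends (for directional
#'   variables).
#' @return Object of class `rate_histogram` with `breaks`, raw/smoothed
#'   occupancy, `p` (occupancy probability over valid bins), raw and
#'   smoothed `rate`, and `mean_rate`.
#' @export
rate_histogram_1d <- function(x, dwell, spike_x, range, n_bins = 20,
                              smoothing_sd = 1, circular = FALSE) {
  stopifnot(length(x) == length(dwell), n_bins >= 2, range[2] > range[1])
  br <- seq(range[1], range[2], length.out = n_bins + 1)
  bin_of <- function(v) {
    i <- findInterval(v, br, rightmost.closed = TRUE)
    i[i < 1 | i > n_bins] <- NA
    i
  }
  bx <- bin_of(x)
  occ <- vapply(seq_len(n_bins), function(b) sum(dwell[which(bx == b)]), numeric(1))
  spk <- tabulate(bin_of(spike_x), nbins = n_bins)
  valid <- occ > 0
  if (!any(valid)) stop("zero occupancy in all bins")
  if (!all(valid)) warning(sum(!valid), " bin(s) with zero occupancy masked")
  occ_na <- occ; occ_na[!valid] <- NA
  spk_na <- as.numeric(spk); spk_na[!valid] <- NA
  occ_s <- smooth_1d(occ_na, smoothing_sd, circular)
  rate <- smooth_1d(spk_na / occ_s, smoothing_sd, circular)
  p <- occ / sum(occ)
  rate_raw <- ifelse(valid, spk / occ, NA)
  structure(list(breaks = br, mids = (br[-1] + br[-length(br)]) / 2,
                 occupancy_raw = occ, occupancy = occ_s, p = p,
                 spike_count = spk, rate = rate, rate_raw = rate_raw,
                 mean_rate = sum(spk[valid]) / sum(occ[valid]),
                 valid = valid, circular = circular),
            class = "rate_histogram")
}

#' Spatial information score (bits per spike)
#'
#' `sum_i p_i (lambda_i / lambda) log2(lambda_i / lambda)` over valid bins,
#' with `0 log 0 = 0`. Computed from the unsmoothed occupancy probabilities
#' and rates of the histogram; `lambda` is the occupancy-weighted mean rate.
#'
#' @param hist A `rate_histogram`.
#' @return Information score in bits per spike.
#' @export
information_score <- function(hist) {
  v <- hist$valid
  p <- hist$p[v] / sum(hist$p[v])
  lam_i <- hist$rate_raw[v]
  lam <- sum(p * lam_i)
  if (!is.finite(lam) || lam <= 0) stop("mean rate is zero; information undefined")
  ratio <- lam_i / lam
  terms <- ifelse(ratio > 0, p * ratio * log2(ratio), 0)
  sum(terms)
}
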