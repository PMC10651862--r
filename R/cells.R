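# Spike-train quality control and pyramidal/interneuron classification.

#' Refractory period ratio
#'
#' Spike-time autocorrelation from 0 to 25 ms in 0.5-ms bins; the ratio is
#' the mean count in the bins up to 1.5 ms divided by the maximum count in
#' any bin between 5 and 25 ms. Well-isolated units have a ratio near 0;
#' units with a ratio above 0.25 are conventionally discarded.
#'
#' @param spike_times Sorted spike times (s); at least 100 spikes.
#' @return The ratio (unitless); `Inf` when the 5-25 ms window is empty
#'   (such units fail the quality criterion).
#' @export
refractory_ratio <- function(spike_times) {
  st <- sort(spike_times)
  n <- length(st)
  if (n < 100) stop("need at least 100 spikes, got ", n)
  max_lag <- 0.025
  counts <- numeric(50)
  k <- 1
  repeat {
    if (k >= n) break
    dt <- st[(k + 1):n] - st[1:(n - k)]
    dt <- dt[dt <= max_lag]
    if (!length(dt)) break
    b <- ceiling(dt / 5e-4)
    b[b < 1] <- 1
    tb <- tabulate(b, nbins = 50)
    counts <- counts + tb
    k <- k + 1
  }
  early <- mean(counts[1:3])       # (0, 1.5] ms
  late <- max(counts[11:50])       # (5, 25] ms
  if (late == 0) return(Inf)
  early / late
}

# Peak-align (trough to center) and amplitude-normalize waveforms.
normalize_waveforms <- function(wf) {
  t(apply(wf, 1, function(w) {
    ctr <- ceiling(length(w) / 2)
    w <- roll_left(w, which.min(w) - ctr)
    a <- max(abs(w))
    if (a > 0) w / a else w
  }))
}

#' Classify units as pyramidal cells or interneurons
#'
#' Principal-component reduction of the mean waveforms (peak-aligned,
#' amplitude-normalized; 3 components) and of the spike-time
#' autocorrelations (3 components), combined with the mean firing rate into
#' 7 features. Features are standardized and clustered with k-means
#' (k = 2, best of 10 restarts under a fixed seed); the cluster with the
#' lower mean firing rate is labeled pyramidal.
#'
#' @param features List with `mean_rate`, `waveform` (units x samples), and
#'   `autocorrelation` (units x bins), as from [generate_unit_features()].
#' @param seed RNG seed for the k-means restarts.
#' @param log_rate Log-transform the mean rate before clustering (default
#'   `FALSE`).
#' @return Factor of per-unit classes (`pyramidal`/`interneuron`), in input
#'   order.
#' @export
classify_units <- function(features, seed = 1, log_rate = FALSE) {
  n <- length(features$mean_rate)
  if (n < 4) stop("need at least 4 units")
  wf <- normalize_waveforms(as.matrix(features$waveform))
  ac <- as.matrix(features$autocorrelation)
  pc <- function(m) {
    keep <- apply(m, 2, stats::sd) > 0
    if (sum(keep) < 3) stop("degenerate feature matrix")
    p <- stats::prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    p$x[, seq_len(min(3, ncol(p$x))), drop = FALSE]
  }
  rate <- if (log_rate) log(features$mean_rate + 1e-6) else features$mean_rate
  X <- cbind(rate, pc(wf), pc(ac))
  sds <- apply(X, 2, stats::sd)
  if (sum(sds > 0) < 2 || qr(X)$rank < 2) stop("degenerate feature matrix")
  X <- scale(X[, sds > 0, drop = FALSE])
  set.seed(seed)
  km <- stats::kmeans(X, centers = 2, nstart = 10)
  mean_rates <- tapply(features$mean_rate, km$cluster, mean)
  pyr_cluster <- as.integer(names(which.min(mean_rates)))
  factor(ifelse(km$cluster == pyr_cluster, "pyramidal", "interneuron"),
         levels = c("pyramidal", "interneuron"))
}
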