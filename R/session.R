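# Session container: positions, spike trains, task events, lever poses,
# geometry, and metadata for one recording session.

EVENT_KINDS <- c("door_open", "door_close", "lever_press", "magazine_beam",
                 "light_on", "light_off", "arena_rotation")

#' Construct a session
#'
#' Bundles all per-session data in the canonical frame (cm, arena center at
#' the origin, bridge on the negative-y axis). Validation enforces the type
#' invariants: strictly increasing position timestamps, non-decreasing spike
#' and event times, disjoint ordered lever-pose epochs, and every lever press
#' falling inside some lever-pose epoch.
#'
#' @param geometry An [arena_geometry()].
#' @param positions Data frame with columns `t`, `x`, `y` (s, cm, cm).
#' @param spikes Named list of numeric spike-time vectors (s), one per neuron.
#' @param events Data frame with columns `t`, `kind`, `payload`.
#' @param lever_poses Data frame with columns `t_start`, `t_end`, `cx`, `cy`,
#'   `dx`, `dy` (epoch, box center, unit lever direction).
#' @param sample_rate Nominal position sampling rate (Hz).
#' @param metadata Named list (animal id, date, condition flags, ...).
#' @param validate Run [validate_session()] (default `TRUE`).
#' @return An object of class `homing_session`.
#' @export
homing_session <- function(geometry, positions, spikes, events, lever_poses,
                           sample_rate, metadata = list(), validate = TRUE) {
  s <- structure(list(
    geometry = geometry,
    positions = as.data.frame(positions),
    spikes = spikes,
    events = as.data.frame(events),
    lever_poses = as.data.frame(lever_poses),
    sample_rate = sample_rate,
    metadata = metadata
  ), class = "homing_session")
  if (validate) validate_session(s)
  s
}

#' Validate a session
#'
#' @param session A `homing_session`.
#' @return The session, invisibly; errors name the first offending component.
#' @export
validate_session <- function(session) {
  p <- session$positions
  if (is.null(p) || !nrow(p)) stop("positions missing")
  if (!all(c("t", "x", "y") %in% names(p))) stop("positions must have columns t, x, y")
  if (any(!is.finite(p$t)) || any(diff(p$t) <= 0))
    stop("position timestamps must be finite and strictly increasing; first violation at index ",
         which(c(FALSE, diff(p$t) <= 0))[1])
  if (any(!is.finite(p$x)) || any(!is.finite(p$y))) stop("positions must be finite")
  e <- session$events
  if (is.null(e) || !nrow(e)) stop("events missing")
  if (!all(c("t", "kind") %in% names(e))) stop("events must have columns t, kind")
  if (is.unsorted(e$t)) stop("event times must be non-decreasing")
  bad <- setdiff(unique(e$kind), EVENT_KINDS)
  if (length(bad)) stop("unknown event kind: ", bad[1])
  lp <- session$lever_poses
  if (is.null(lp) || !nrow(lp)) stop("lever_poses missing")
  if (any(lp$t_end <= lp$t_start)) stop("lever pose epochs must have t_end > t_start")
  if (nrow(lp) > 1 && any(lp$t_start[-1] < lp$t_end[-nrow(lp)]))
    stop("lever pose epochs must be disjoint and ordered")
  nrm <- sqrt(lp$dx^2 + lp$dy^2)
  if (any(abs(nrm - 1) > 1e-6)) stop("lever_direction must be a unit vector")
  for (id in names(session$spikes)) {
    st <- session$spikes[[id]]
    if (length(st) && is.unsorted(st))
      stop("spike times must be non-decreasing for neuron ", id)
  }
  presses <- e$t[e$kind == "lever_press"]
  if (length(presses)) {
    inside <- vapply(presses, function(tt)
      any(tt >= lp$t_start & tt <= lp$t_end), logical(1))
    if (!all(inside))
      stop("lever press at t = ", presses[!inside][1],
           " falls outside all lever pose epochs")
  }
  invisible(session)
}

# Per-sample dwell time: gap to the next sample, capped at 3x the median gap
# to guard against tracking dropouts; the last sample gets the median gap.
dwell_times <- function(t) {
  if (length(t) < 2) return(rep(0, length(t)))
  d <- diff(t)
  md <- stats::median(d)
  c(pmin(d, 3 * md), md)
}

# Map spike times onto position-sample indices (sample whose timestamp is
# the latest <= spike time). Spikes before the first sample get index NA.
spike_sample_index <- function(spike_times, t) {
  i <- findInterval(spike_times, t)
  i[i == 0] <- NA_integer_
  i
}

# Lever pose active at given times; returns row indices into lever_poses
# (NA when no epoch covers the time).
lever_pose_at <- function(lever_poses, times) {
  idx <- rep(NA_integer_, length(times))
  for (k in seq_len(nrow(lever_poses))) {
    sel <- times >= lever_poses$t_start[k] & times <= lever_poses$t_end[k]
    idx[sel] <- k
  }
  idx
}

#' Canonicalize session coordinates
#'
#' Translates and rotates all spatial data so that the arena center is at the
#' origin and the bridge center lies on the negative-y axis. Applying the
#' transform twice is a no-op.
#'
#' @param session A `homing_session` (possibly in a rotated/offset frame).
#' @return The session in the canonical frame.
#' @export
canonicalize_session <- function(session) {
  g <- session$geometry
  ctr <- g$arena_center
  br <- g$bridge_center - ctr
  # rotation that brings the bridge onto the negative-y axis
  rot <- -angle_from_south(br[1], br[2])
  tr <- function(x, y) rotate_xy(x - ctr[1], y - ctr[2], rot)
  p <- tr(session$positions$x, session$positions$y)
  session$positions$x <- p$x
  session$positions$y <- p$y
  lc <- tr(session$lever_poses$cx, session$lever_poses$cy)
  session$lever_poses$cx <- lc$x
  session$lever_poses$cy <- lc$y
  ld <- rotate_xy(session$lever_poses$dx, session$lever_poses$dy, rot)
  session$lever_poses$dx <- ld$x
  session$lever_poses$dy <- ld$y
  nb <- tr(g$bridge_center[1], g$bridge_center[2])
  session$geometry$bridge_center <- c(nb$x, nb$y)
  session$geometry$arena_center <- c(0, 0)
  session
}

#' Write a session to a directory container
#'
#' Layout: `positions.tsv` (t,x,y), `events.tsv` (t,kind,payload),
#' `spikes/<neuron_id>.tsv` (t), `lever_poses.tsv`
#' (t_start,t_end,cx,cy,dx,dy), `geometry.yaml`, `metadata.yaml`. All tables
#' are UTF-8, tab-delimited, with a header row. Writing the same session
#' twice produces byte-identical files.
#'
#' @param session A valid `homing_session`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(path, "spikes"), showWarnings = FALSE)
  wt <- function(df, file)
    utils::write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  pos <- session$positions
  pos$t <- sprintf("%.6f", pos$t)
  wt(pos, "positions.tsv")
  ev <- session$events
  if (!"payload" %in% names(ev)) ev$payload <- ""
  ev$t <- sprintf("%.6f", ev$t)
  wt(ev, "events.tsv")
  lp <- session$lever_poses
  lp$t_start <- sprintf("%.6f", lp$t_start)
  lp$t_end <- sprintf("%.6f", lp$t_end)
  wt(lp, "lever_poses.tsv")
  for (id in names(session$spikes))
    wt(data.frame(t = sprintf("%.6f", session$spikes[[id]])),
       file.path("spikes", paste0(id, ".tsv")))
  g <- session$geometry
  yaml::write_yaml(lapply(unclass(g), as.numeric),
                   file.path(path, "geometry.yaml"))
  meta <- session$metadata
  meta$sample_rate <- session$sample_rate
  yaml::write_yaml(meta, file.path(path, "metadata.yaml"))
  invisible(path)
}

#' Read a session from a directory container
#'
#' Reads the layout documented in [write_session()], converts coordinates to
#' the canonical frame, and validates all invariants.
#'
#' @param path Session directory.
#' @return A validated `homing_session`.
#' @export
read_session <- function(path) {
  need <- c("positions.tsv", "events.tsv", "lever_poses.tsv",
            "geometry.yaml", "metadata.yaml")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop(sub("\\..*$", "", f), " missing (expected ", f, " in ", path, ")")
  rt <- function(file, colClasses)
    utils::read.delim(file.path(path, file), colClasses = colClasses,
                      fileEncoding = "UTF-8")
  positions <- rt("positions.tsv", c("numeric", "numeric", "numeric"))
  events <- rt("events.tsv", c("numeric", "character", "character"))
  lever_poses <- rt("lever_poses.tsv", rep("numeric", 6))
  gy <- yaml::read_yaml(file.path(path, "geometry.yaml"))
  geometry <- arena_geometry(
    arena_radius = gy$arena_radius,
    bridge_center = gy$bridge_center - gy$arena_center,
    periphery_threshold = gy$periphery_threshold,
    lever_proximity_threshold = gy$lever_proximity_threshold,
    lever_frame_radius = gy$lever_frame_radius,
    lever_center_max_radius = gy$lever_center_max_radius)
  geometry$arena_center <- gy$arena_center
  geometry$bridge_center <- gy$bridge_center
  meta <- yaml::read_yaml(file.path(path, "metadata.yaml"))
  sample_rate <- meta$sample_rate
  meta$sample_rate <- NULL
  spike_files <- sort(list.files(file.path(path, "spikes"), pattern = "\\.tsv$"))
  spikes <- stats::setNames(
    lapply(spike_files, function(f)
      rt(file.path("spikes", f), "numeric")$t),
    sub("\\.tsv$", "", spike_files))
  s <- homing_session(geometry, positions, spikes, events, lever_poses,
                      sample_rate, meta, validate = FALSE)
  s <- canonicalize_session(s)
  validate_session(s)
  s
}

#' @export
print.homing_session <- function(x, ...) {
  cat("homing_session:", nrow(x$positions), "position samples,",
      length(x$spikes), "neurons,", nrow(x$events), "events,",
      nrow(x$lever_poses), "lever poses\n")
  cat(sprintf("  time range %.1f-%.1f s, arena radius %.0f cm\n",
              min(x$positions$t), max(x$positions$t),
              x$geometry$arena_radius))
  invisible(x)
}
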