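# Synthetic session generator.
#
# Produces complete sessions for the automated homing task together with the
# ground truth (injected field parameters, per-trial field rotations, homing
# errors) needed to validate every analysis stage. The trajectory model is a
# discrete-time correlated random walk with goal attraction toward the lever,
# a single circumnavigation of the lever box, and a straight homing path at a
# drawn homing direction; spikes come from an inhomogeneous Poisson process
# with rate = baseline + field template evaluated along the trajectory.

#' Behavioral specification for the synthetic generator
#'
#' Defaults emulate the task conditions: ~100 trials per session starting
#' with seven light trials then alternating light/dark, random lever
#' placement within 75% of the arena radius (re-drawn every 4th trial, with
#' arena rotations by multiples of 45 degrees in between), search paths more
#' tortuous and slower in darkness, and homing errors whose concentration
#' decreases with search path length so that error correlates positively
#' with search length in the dark.
#'
#' @param n_trials Number of trials (default 100).
#' @param light_dark_alternation Alternate light/dark after the seven
#'   initial light trials (default `TRUE`; otherwise all trials are lit).
#' @param search_tortuosity_light,search_tortuosity_dark SD of the
#'   per-step Gaussian turning noise (degrees per step at `sample_rate`).
#' @param speed_light,speed_dark Search running speed (cm/s).
#' @param homing_speed_light,homing_speed_dark Homing running speed (cm/s);
#'   defaults are the observed task means (64.18 and 31.58 cm/s).
#' @param homing_error_kappa_base Von Mises concentration of the homing
#'   error for an instantaneous search path; also the fixed concentration
#'   used on light trials, where landmarks prevent error accumulation.
#' @param homing_error_length_coupling Per-cm decay of the dark-trial error
#'   concentration: kappa = kappa_base / (1 + coupling * search_length).
#' @param goal_attraction_light,goal_attraction_dark Per-step fractional
#'   turn toward the lever (unitless in \[0, 1\]).
#' @param lever_loop Run a full circumnavigation of the lever box before
#'   homing (default `TRUE`).
#' @param loop_speed Running speed around the lever box (cm/s).
#' @param multi_journey_prob_light,multi_journey_prob_dark Probability that
#'   a trial starts with a failed journey (no lever press); default 0 for
#'   determinism of trial/journey counts.
#' @param sample_rate Position sampling rate (Hz, default 50).
#' @return Object of class `behavior_spec`.
#' @export
behavior_spec <- function(n_trials = 100,
                          light_dark_alternation = TRUE,
                          search_tortuosity_light = 10,
                          search_tortuosity_dark = 30,
                          speed_light = 25,
                          speed_dark = 15,
                          homing_speed_light = 64.18,
                          homing_speed_dark = 31.58,
                          homing_error_kappa_base = 80,
                          homing_error_length_coupling = 0.1,
                          goal_attraction_light = 0.2,
                          goal_attraction_dark = 0.05,
                          lever_loop = TRUE,
                          loop_speed = 10,
                          multi_journey_prob_light = 0,
                          multi_journey_prob_dark = 0,
                          sample_rate = 50) {
  stopifnot(n_trials >= 1, speed_light > 0, speed_dark > 0,
            homing_error_kappa_base > 0, sample_rate > 0)
  structure(as.list(environment()), class = "behavior_spec")
}

#' Firing-field specification for a synthetic neuron
#'
#' Three archetypes: `place` (world-anchored Gaussian field),
#' `lever_distance` (fires at a fixed distance from the lever-box wall),
#' and `lever_anchored` (fires at a specific direction around the lever box
#' in a stated reference frame, with a per-trial rotation
#' `delta_t = drift_slope * homing_direction + N(0, drift_noise_sd)`).
#'
#' @param kind One of `"place"`, `"lever_distance"`, `"lever_anchored"`.
#' @param peak_rate,baseline_rate Field peak and baseline rate (Hz).
#' @param place_center,place_sd Gaussian place-field center (cm) and SD
#'   (cm); `place` only.
#' @param preferred_distance,distance_sd Preferred lever-wall distance and
#'   Gaussian SD (cm); `lever_distance` only.
#' @param preferred_direction Preferred direction around the lever box
#'   (degrees in the chosen `reference_frame`); `lever_anchored` only.
#' @param concentration Von Mises concentration of the angular tuning.
#' @param reference_frame `"cardinal"`, `"bridge"`, or `"lever"`.
#' @param drift_slope,drift_noise_sd Coupling of the per-trial field
#'   rotation to the homing direction, and its Gaussian noise SD (degrees).
#' @param field_distance_sd SD (cm) of the radial envelope of a
#'   lever-anchored field around the box wall.
#' @return Object of class `field_spec`.
#' @export
field_spec <- function(kind = c("place", "lever_distance", "lever_anchored"),
                       peak_rate = 10, baseline_rate = 0.1,
                       place_center = c(0, 0), place_sd = 8,
                       preferred_distance = 20, distance_sd = 5,
                       preferred_direction = 0, concentration = 4,
                       reference_frame = c("cardinal", "bridge", "lever"),
                       drift_slope = 0, drift_noise_sd = 5,
                       field_distance_sd = 4) {
  kind <- match.arg(kind)
  reference_frame <- match.arg(reference_frame)
  stopifnot(peak_rate > baseline_rate, baseline_rate >= 0,
            concentration >= 0, place_sd > 0, distance_sd > 0)
  structure(as.list(environment()), class = "field_spec")
}

# Correlated random walk from `start` until within `stop_dist` of the
# lever-box wall; returns matrix of (x, y). Attraction ramps up after 60 s
# and the walk goes straight to the lever after 240 s so search always ends.
sim_search_walk <- function(start, pose, geom, speed, tort, attract, dt) {
  max_n <- ceiling(260 / dt)
  xs <- numeric(max_n); ys <- numeric(max_n)
  x <- start[1]; y <- start[2]
  h <- pi / 2  # heading north, onto the arena
  step <- speed * dt
  R <- geom$arena_radius
  turn_sd <- deg2rad(tort)
  n <- 0
  repeat {
    n <- n + 1
    if (n > max_n) break
    a <- attract
    if (n * dt > 60) a <- max(a, 0.3)
    if (n * dt > 240) { a <- 1; turn_sd <- 0 }
    target <- atan2(pose$cy - y, pose$cx - x)
    dh <- atan2(sin(target - h), cos(target - h))
    h <- h + a * dh + stats::rnorm(1, 0, turn_sd)
    xn <- x + step * cos(h)
    yn <- y + step * sin(h)
    if (sqrt(xn^2 + yn^2) > R - 2) {  # steer back off the wall
      h <- atan2(-y, -x)
      xn <- x + step * cos(h)
      yn <- y + step * sin(h)
    }
    x <- xn; y <- yn
    xs[n] <- x; ys[n] <- y
    if (lever_wall_distance(x, y, c(pose$cx, pose$cy),
                            c(pose$dx, pose$dy)) < geom$lever_proximity_threshold - 1)
      break
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

# Straight path from `from` to `to` at `speed`; excludes the start point.
sim_straight <- function(from, to, speed, dt) {
  d <- sqrt(sum((to - from)^2))
  n <- max(1, ceiling(d / (speed * dt)))
  f <- seq_len(n) / n
  cbind(from[1] + f * (to[1] - from[1]), from[2] + f * (to[2] - from[2]))
}

# One full circumnavigation of the lever box at radius r_loop, starting at
# the angle of `from` around the box; `dir` is +1 (ccw) or -1 (cw).
sim_loop <- function(from, pose, r_loop, speed, dir, dt) {
  phi0 <- atan2(from[2] - pose$cy, from[1] - pose$cx)
  n <- max(8, ceiling(2 * pi * r_loop / (speed * dt)))
  phi <- phi0 + dir * 2 * pi * seq_len(n) / n
  cbind(pose$cx + r_loop * cos(phi), pose$cy + r_loop * sin(phi))
}

# Walk along the arena periphery (radius R - 1) from the angle of `from`
# to the bridge entry, then step down to the home position.
sim_edge_return <- function(from, home, geom, speed, dt) {
  R <- geom$arena_radius - 1
  a0 <- atan2(from[2], from[1])
  a1 <- -pi / 2
  d <- atan2(sin(a1 - a0), cos(a1 - a0))  # shorter way around
  arc_len <- abs(d) * R
  n <- max(1, ceiling(arc_len / (speed * dt)))
  ang <- a0 + d * seq_len(n) / n
  arc <- cbind(R * cos(ang), R * sin(ang))
  rbind(arc, sim_straight(arc[nrow(arc), ], home, speed, dt))
}

# Direction (deg) of points around the lever box in a reference frame.
direction_around_lever <- function(x, y, pose, geom, frame) {
  th <- angle_from_south(x - pose$cx, y - pose$cy)
  ref <- switch(frame,
    cardinal = 0,
    bridge = angle_from_south(geom$bridge_center[1] - pose$cx,
                              geom$bridge_center[2] - pose$cy),
    lever = angle_from_south(pose$dx, pose$dy))
  wrap180(th - ref)
}

# Field rate template along a trajectory for one neuron on one trial.
field_rate <- function(fs, x, y, pose, geom, delta) {
  r <- rep(fs$baseline_rate, length(x))
  amp <- fs$peak_rate - fs$baseline_rate
  if (fs$kind == "place") {
    d2 <- (x - fs$place_center[1])^2 + (y - fs$place_center[2])^2
    r <- r + amp * exp(-d2 / (2 * fs$place_sd^2))
  } else if (fs$kind == "lever_distance") {
    d <- lever_wall_distance(x, y, c(pose$cx, pose$cy), c(pose$dx, pose$dy))
    r <- r + amp * exp(-(d - fs$preferred_distance)^2 / (2 * fs$distance_sd^2))
  } else {  # lever_anchored
    d <- lever_wall_distance(x, y, c(pose$cx, pose$cy), c(pose$dx, pose$dy))
    th <- direction_around_lever(x, y, pose, geom, fs$reference_frame)
    ang <- exp(fs$concentration *
                 (cos(deg2rad(th - fs$preferred_direction - delta)) - 1))
    r <- r + amp * ang * exp(-d^2 / (2 * fs$field_distance_sd^2))
  }
  r
}

#' Generate a synthetic session with ground truth
#'
#' Simulates a full session of the homing task (positions, task events,
#' lever poses, spike trains) plus the ground truth needed for recovery
#' tests. Identical seeds give identical output.
#'
#' @param behavior A [behavior_spec()].
#' @param fields List of [field_spec()] objects, one per neuron; may be
#'   empty. Neurons are named `n01`, `n02`, ...
#' @param seed Integer seed; all randomness derives from it.
#' @param geometry An [arena_geometry()].
#' @param fields_dark Optional list of [field_spec()] (same length as
#'   `fields`) used on dark trials instead of `fields`, to emulate
#'   light/dark remapping. Default `NULL`: fields are condition-invariant.
#' @param metadata Extra metadata stored in the session.
#' @return List with elements `session` (a `homing_session`) and `truth`
#'   (list with per-trial data frame `trials` — light flag, lever pose,
#'   true search path length, signed/absolute homing error at the
#'   periphery, true lever-frame homing direction — a `drift` matrix of the
#'   injected per-trial rotation for each lever-anchored neuron, and the
#'   field specifications).
#' @export
generate_session <- function(behavior, fields = list(), seed = 1,
                             geometry = arena_geometry(),
                             fields_dark = NULL, metadata = list()) {
  stopifnot(inherits(behavior, "behavior_spec"))
  if (geometry$lever_center_max_radius > geometry$arena_radius - LEVER_BOX_LONG / 2)
    stop("infeasible geometry: lever placement radius allows the box outside the arena")
  set.seed(seed)
  b <- behavior
  g <- geometry
  dt <- 1 / b$sample_rate
  home <- c(0, g$bridge_center[2])
  bridge_y <- -(g$arena_radius + 2)

  light_seq <- if (b$light_dark_alternation) {
    c(rep(TRUE, min(7, b$n_trials)),
      rep(c(FALSE, TRUE), length.out = max(0, b$n_trials - 7)))
  } else rep(TRUE, b$n_trials)

  draw_pose <- function() {
    r <- g$lever_center_max_radius * sqrt(stats::runif(1))
    a <- stats::runif(1, 0, 2 * pi)
    phi <- stats::runif(1, 0, 2 * pi)
    list(cx = r * cos(a), cy = r * sin(a), dx = cos(phi), dy = sin(phi))
  }
  rotate_pose <- function(p, deg) {
    c1 <- rotate_xy(p$cx, p$cy, deg); d1 <- rotate_xy(p$dx, p$dy, deg)
    list(cx = c1$x, cy = c1$y, dx = d1$x, dy = d1$y)
  }

  pos_chunks <- list(); ev <- list(); poses <- list()
  trial_rows <- list(); seg_rows <- list()
  t_now <- 0
  pose <- draw_pose()
  add_pos <- function(xy) {
    n <- nrow(xy)
    ts <- t_now + dt * seq_len(n)
    pos_chunks[[length(pos_chunks) + 1]] <<- cbind(ts, xy)
    t_now <<- ts[n]
    xy[n, ]
  }

  for (tr in seq_len(b$n_trials)) {
    light <- light_seq[tr]
    if (tr > 1) {
      rot <- 45 * sample(0:7, 1)
      pose <- if ((tr - 1) %% 4 == 0) draw_pose() else rotate_pose(pose, rot)
      ev[[length(ev) + 1]] <- list(t = t_now + dt, kind = "arena_rotation",
                                   payload = as.character(rot))
    }
    if (sqrt(pose$cx^2 + pose$cy^2) + LEVER_BOX_LONG / 2 > g$arena_radius)
      stop("infeasible geometry: lever box outside the arena")
    # inter-trial interval at the home base (small jitter keeps variance > 0)
    iti <- cbind(home[1] + stats::rnorm(round(2 / dt), 0, 0.2),
                 home[2] + stats::rnorm(round(2 / dt), 0, 0.2))
    cur <- add_pos(iti)
    ev[[length(ev) + 1]] <- list(t = t_now, kind = if (light) "light_on" else "light_off",
                                 payload = "")
    t_open <- t_now + dt / 2
    ev[[length(ev) + 1]] <- list(t = t_open, kind = "door_open", payload = "")
    speed <- if (light) b$speed_light else b$speed_dark
    tort <- if (light) b$search_tortuosity_light else b$search_tortuosity_dark
    attract <- if (light) b$goal_attraction_light else b$goal_attraction_dark
    hspeed <- if (light) b$homing_speed_light else b$homing_speed_dark

    # optional failed journey before the successful one
    pj <- if (light) b$multi_journey_prob_light else b$multi_journey_prob_dark
    if (stats::runif(1) < pj) {
      out <- sim_straight(cur, c(stats::runif(1, -15, 15), stats::runif(1, -10, 20)),
                          speed, dt)
      cur <- add_pos(out)
      cur <- add_pos(sim_straight(cur, home, speed, dt))
    }

    # bridge -> arena
    cur <- add_pos(sim_straight(cur, c(0, bridge_y + 1), speed, dt))
    search_t0 <- t_now
    walk <- sim_search_walk(cur, pose, g, speed, tort, attract, dt)
    search_len <- sum(sqrt(diff(c(cur[1], walk[, 1]))^2 +
                           diff(c(cur[2], walk[, 2]))^2))
    cur <- add_pos(walk)
    search_t1 <- t_now

    # loop around the lever box; press happens halfway around
    if (b$lever_loop) {
      loop <- sim_loop(cur, pose, 7, b$loop_speed, sample(c(-1, 1), 1), dt)
      half <- t_now + dt * ceiling(nrow(loop) / 2)
      cur <- add_pos(loop)
      t_press <- half
    } else {
      t_press <- t_now + dt
      cur <- add_pos(sim_straight(cur, cur + c(0.5, 0), b$loop_speed, dt))
    }
    ev[[length(ev) + 1]] <- list(t = t_press, kind = "lever_press", payload = "")

    # homing: error drawn with concentration shrinking with search length
    kappa <- if (light) b$homing_error_kappa_base else
      b$homing_error_kappa_base / (1 + b$homing_error_length_coupling * search_len)
    err <- rvonmises_deg(1, 0, kappa)
    arr_ang <- deg2rad(-90 + err)  # bridge is due south of the center
    arrival <- g$arena_radius * c(cos(arr_ang), sin(arr_ang))
    cur <- add_pos(sim_straight(cur, arrival, hspeed, dt))
    cur <- add_pos(sim_edge_return(cur, home, g, hspeed, dt))
    ev[[length(ev) + 1]] <- list(t = t_now + dt, kind = "magazine_beam", payload = "")
    t_close <- t_now + 2 * dt
    ev[[length(ev) + 1]] <- list(t = t_close, kind = "door_close", payload = "")
    t_now <- t_close + dt

    # true lever-frame homing direction: angle at the box center between
    # the vector to the bridge and the vector to the periphery arrival
    v_br <- angle_from_south(g$bridge_center[1] - pose$cx,
                             g$bridge_center[2] - pose$cy)
    v_ar <- angle_from_south(arrival[1] - pose$cx, arrival[2] - pose$cy)
    trial_rows[[tr]] <- data.frame(
      trial_id = tr, light = light, t_start = t_open, t_end = t_close,
      lever_cx = pose$cx, lever_cy = pose$cy,
      lever_dx = pose$dx, lever_dy = pose$dy,
      search_length = search_len,
      homing_error_signed = err, homing_error = abs(wrap180(err)),
      homing_direction = wrap180(v_ar - v_br),
      t_search0 = search_t0, t_search1 = search_t1, t_press = t_press)
    poses[[tr]] <- data.frame(t_start = t_open - 1.5, t_end = t_close + 0.5,
                              cx = pose$cx, cy = pose$cy,
                              dx = pose$dx, dy = pose$dy)
  }

  truth_trials <- do.call(rbind, trial_rows)
  positions <- do.call(rbind, pos_chunks)
  positions <- data.frame(t = positions[, 1], x = positions[, 2], y = positions[, 3])
  events <- do.call(rbind, lapply(ev, as.data.frame))
  events <- events[order(events$t), ]
  lever_poses <- do.call(rbind, poses)

  # injected per-trial rotations for lever-anchored neurons
  ids <- sprintf("n%02d", seq_along(fields))
  anchored <- which(vapply(fields, function(f) f$kind == "lever_anchored", logical(1)))
  drift <- NULL
  if (length(anchored)) {
    drift <- matrix(NA_real_, nrow = b$n_trials, ncol = length(anchored),
                    dimnames = list(NULL, ids[anchored]))
    for (j in seq_along(anchored)) {
      fs <- fields[[anchored[j]]]
      drift[, j] <- wrap180(fs$drift_slope * truth_trials$homing_direction +
                              stats::rnorm(b$n_trials, 0, fs$drift_noise_sd))
    }
  }

  # spike generation: per-sample Poisson counts from the field template
  dwell <- dwell_times(positions$t)
  trial_of_sample <- findInterval(positions$t, truth_trials$t_start)
  trial_of_sample[positions$t > truth_trials$t_end[pmax(trial_of_sample, 1)] |
                    trial_of_sample == 0] <- NA
  spikes <- stats::setNames(vector("list", length(fields)), ids)
  for (j in seq_along(fields)) {
    rate <- rep(fields[[j]]$baseline_rate, nrow(positions))
    for (tr in seq_len(b$n_trials)) {
      sel <- which(!is.na(trial_of_sample) & trial_of_sample == tr)
      if (!length(sel)) next
      fs <- fields[[j]]
      if (!is.null(fields_dark) && !truth_trials$light[tr]) fs <- fields_dark[[j]]
      dlt <- 0
      if (fs$kind == "lever_anchored" && !is.null(drift) && ids[j] %in% colnames(drift))
        dlt <- drift[tr, ids[j]]
      pose_tr <- as.list(truth_trials[tr, c("lever_cx", "lever_cy",
                                            "lever_dx", "lever_dy")])
      names(pose_tr) <- c("cx", "cy", "dx", "dy")
      rate[sel] <- field_rate(fs, positions$x[sel], positions$y[sel],
                              pose_tr, g, dlt)
    }
    counts <- stats::rpois(length(rate), rate * dwell)
    idx <- rep(seq_along(counts), counts)
    st <- positions$t[idx] + stats::runif(length(idx)) * dwell[idx] * 0.999
    spikes[[j]] <- sort(st)
  }

  meta <- c(metadata, list(seed = seed, n_trials = b$n_trials))
  session <- homing_session(g, positions, spikes, events, lever_poses,
                            b$sample_rate, meta)
  truth <- list(trials = truth_trials, drift = drift, fields = fields,
                fields_dark = fields_dark)
  list(session = session, truth = truth)
}

#' Generate synthetic unit features for classifier validation
#'
#' Draws per-unit mean firing rates, mean waveforms, and spike-time
#' autocorrelations for two populations: putative pyramidal cells (low rate,
#' broad waveform, bursty autocorrelation) and interneurons (high rate,
#' narrow waveform, flatter autocorrelation).
#'
#' @param n_pyramidal,n_interneuron Unit counts (>= 0).
#' @param seed Integer seed.
#' @return List with `mean_rate` (Hz), `waveform` (units x 32 matrix),
#'   `autocorrelation` (units x 50 matrix, 0.5 ms bins over 0-25 ms), and
#'   `true_class` (factor `pyramidal`/`interneuron`).
#' @export
generate_unit_features <- function(n_pyramidal, n_interneuron, seed = 1) {
  stopifnot(n_pyramidal >= 0, n_interneuron >= 0)
  set.seed(seed)
  n <- n_pyramidal + n_interneuron
  cls <- factor(rep(c("pyramidal", "interneuron"), c(n_pyramidal, n_interneuron)),
                levels = c("pyramidal", "interneuron"))
  if (n == 0)
    return(list(mean_rate = numeric(0), waveform = matrix(0, 0, 32),
                autocorrelation = matrix(0, 0, 50), true_class = cls))
  rate <- ifelse(cls == "pyramidal",
                 stats::rlnorm(n, log(1.2), 0.5),
                 stats::rlnorm(n, log(15), 0.3))
  tt <- seq(-15, 16)
  wf <- t(vapply(seq_len(n), function(i) {
    w <- if (cls[i] == "pyramidal") stats::rnorm(1, 5, 0.5) else stats::rnorm(1, 2, 0.3)
    shape <- -exp(-tt^2 / (2 * w^2)) + 0.45 * exp(-(tt - 1.8 * w)^2 / (2 * (1.6 * w)^2))
    shape + stats::rnorm(32, 0, 0.03)
  }, numeric(32)))
  lag_ms <- (seq_len(50) - 0.5) * 0.5
  ac <- t(vapply(seq_len(n), function(i) {
    base <- if (cls[i] == "pyramidal") {
      # burst peak at 3-6 ms on a refractory dip
      (1 - exp(-(lag_ms / 1.5)^2)) * (1 + 2.5 * exp(-(lag_ms - 4.5)^2 / 8))
    } else {
      (1 - exp(-(lag_ms / 1.0)^2)) * (1 + 0.3 * exp(-(lag_ms - 12)^2 / 40))
    }
    counts <- stats::rpois(50, base * 40)
    counts / max(mean(counts), 1e-9)
  }, numeric(50)))
  list(mean_rate = rate, waveform = wf, autocorrelation = ac, true_class = cls)
}
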