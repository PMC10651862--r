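# Shared synthetic fixtures, computed lazily and cached for the test run.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# 50-trial session with one lever-anchored, one place, and one
# lever-distance neuron, segmented.
fx_mixed <- function() fx_cache("mixed", {
  fl <- list(
    field_spec("lever_anchored", peak_rate = 15, preferred_direction = 45,
               concentration = 5, drift_slope = 0.5, drift_noise_sd = 5),
    field_spec("place", place_center = c(0, -15), peak_rate = 15, place_sd = 8),
    field_spec("lever_distance", preferred_distance = 15, peak_rate = 15,
               distance_sd = 4))
  g <- generate_session(behavior_spec(n_trials = 50), fl, seed = 3)
  g$trials <- segment_trials(g$session)
  g$journeys <- segment_journeys(g$session, g$trials)
  g
})

# 60-trial session without neurons, with its per-journey behavior table.
fx_behavior <- function() fx_cache("behavior", {
  g <- generate_session(behavior_spec(n_trials = 60), list(), seed = 5)
  g$trials <- segment_trials(g$session)
  g$journeys <- segment_journeys(g$session, g$trials)
  g$table <- behavior_table(g$session, g$trials, g$journeys)
  g
})

# Direction trial matrix built directly from a tuning template: rows are
# Poisson samples of a von Mises curve rotated by the given per-trial
# shifts, with constant per-bin occupancy. Used for drift/null tests that
# do not need a full session.
make_direction_matrix <- function(delta, occ = 0.12, peak = 10, kappa = 5,
                                  homing = NA_real_) {
  mids <- seq(-170, 170, by = 20)
  n <- length(delta)
  rate_raw <- t(vapply(seq_len(n), function(i) {
    lam <- 0.1 + peak * exp(kappa * (cos((mids - delta[i]) * pi / 180) - 1))
    stats::rpois(18, lam * occ) / occ
  }, numeric(18)))
  rate <- t(apply(rate_raw, 1, homingfields:::smooth_1d, sd_bins = 2,
                  circular = TRUE))
  structure(list(variable = "lever_direction", segment = "at_lever",
                 frame = "cardinal", breaks = seq(-180, 180, by = 20),
                 mids = mids, bin_size = 20, rate = rate,
                 rate_raw = rate_raw, occupancy = matrix(occ, n, 18),
                 meta = data.frame(trial_id = seq_len(n), journey_id = 1,
                                   light = FALSE, lever_y = 0,
                                   homing_direction = rep_len(homing, n)),
                 circular = TRUE, row_smoothing_sd = 2),
            class = "trial_matrix")
}

# Rigidly rotate a session and its trial table about the arena center.
rotate_session <- function(session, trials, deg) {
  rxy <- homingfields:::rotate_xy
  p <- rxy(session$positions$x, session$positions$y, deg)
  session$positions$x <- p$x; session$positions$y <- p$y
  lc <- rxy(session$lever_poses$cx, session$lever_poses$cy, deg)
  ld <- rxy(session$lever_poses$dx, session$lever_poses$dy, deg)
  session$lever_poses$cx <- lc$x; session$lever_poses$cy <- lc$y
  session$lever_poses$dx <- ld$x; session$lever_poses$dy <- ld$y
  b <- rxy(session$geometry$bridge_center[1], session$geometry$bridge_center[2], deg)
  session$geometry$bridge_center <- c(b$x, b$y)
  tc <- rxy(trials$lever_cx, trials$lever_cy, deg)
  td <- rxy(trials$lever_dx, trials$lever_dy, deg)
  trials$lever_cx <- tc$x; trials$lever_cy <- tc$y
  trials$lever_dx <- td$x; trials$lever_dy <- td$y
  list(session = session, trials = trials)
}

# Behavioral feature matrix used by the light/dark classifier.
behavior_features <- function(bt) {
  as.matrix(bt[, c("search_length", "search_duration", "search_mean_speed",
                   "search_complexity", "homing_length", "homing_duration",
                   "homing_mean_speed", "homing_complexity")])
}
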