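# Behavioral segmentation and metrics: trials, journeys, search/at-lever/
# homing paths, path complexity, homing error at the periphery, and the
# light/dark behavioral classifier.

# Subset the position table to a closed time interval.
positions_between <- function(session, t0, t1) {
  p <- session$positions
  p[p$t >= t0 & p$t <= t1, , drop = FALSE]
}

#' Segment a session into trials
#'
#' One trial per door_open/door_close pair. The light flag reflects the last
#' light_on/light_off event at or before the door opening. Trials whose
#' lever-box center is farther than `lever_center_max_radius` (30 cm for the
#' default geometry) from the arena center are flagged `excluded`.
#'
#' @param session A `homing_session`.
#' @return Data frame with one row per trial: `trial_id`, `t_start`,
#'   `t_end`, `light`, lever pose (`lever_cx`, `lever_cy`, `lever_dx`,
#'   `lever_dy`), and `excluded`.
#' @export
segment_trials <- function(session) {
  e <- session$events
  opens <- e$t[e$kind == "door_open"]
  closes <- e$t[e$kind == "door_close"]
  if (length(opens) != length(closes) || any(closes <= opens))
    stop("unpaired door events; ", length(opens), " openings vs ",
         length(closes), " closings",
         if (length(opens) > length(closes))
           paste0(" (first unmatched opening at t = ",
                  opens[length(closes) + 1], ")") else "")
  lights <- e[e$kind %in% c("light_on", "light_off"), ]
  light_at <- function(tt) {
    prior <- lights[lights$t <= tt, ]
    if (!nrow(prior)) TRUE else prior$kind[nrow(prior)] == "light_on"
  }
  pk <- lever_pose_at(session$lever_poses, opens)
  if (anyNA(pk)) stop("no lever pose covers trial starting at t = ", opens[is.na(pk)][1])
  lp <- session$lever_poses[pk, ]
  out <- data.frame(
    trial_id = seq_along(opens),
    t_start = opens, t_end = closes,
    light = vapply(opens, light_at, logical(1)),
    lever_cx = lp$cx, lever_cy = lp$cy,
    lever_dx = lp$dx, lever_dy = lp$dy)
  out$excluded <- sqrt(out$lever_cx^2 + out$lever_cy^2) >
    session$geometry$lever_center_max_radius
  out
}

#' Segment trials into journeys
#'
#' A journey starts each time the animal moves from the bridge onto the
#' arena and ends when it returns to the bridge (or at trial end, flagged
#' incomplete). The animal is on the bridge when y < -(arena_radius + 2 cm).
#' For journeys containing a lever press, the search path ends at the first
#' sample within 10 cm of the lever-box wall, the homing path starts when
#' the animal leaves that zone after the press, and ends at the first sample
#' within 3 cm of the arena edge, where the periphery arrival point is
#' recorded.
#'
#' @param session A `homing_session`.
#' @param trials Output of [segment_trials()] (or a subset of its rows).
#' @return Data frame with one row per journey: interval, `lever_pressed`,
#'   search/at-lever/homing boundary times (NA when undefined), periphery
#'   arrival coordinates, and a `complete` flag.
#' @export
segment_journeys <- function(session, trials) {
  g <- session$geometry
  bridge_y <- -(g$arena_radius + 2)
  presses <- session$events$t[session$events$kind == "lever_press"]
  res <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    p <- positions_between(session, tr$t_start, tr$t_end)
    if (!nrow(p)) stop("no position samples in trial ", tr$trial_id)
    on_bridge <- p$y < bridge_y
    on_arena <- !on_bridge
    starts <- which(diff(c(FALSE, on_arena)) == 1)
    if (!length(starts)) next
    wall_d <- lever_wall_distance(p$x, p$y, c(tr$lever_cx, tr$lever_cy),
                                  c(tr$lever_dx, tr$lever_dy))
    r <- sqrt(p$x^2 + p$y^2)
    for (jj in seq_along(starts)) {
      s0 <- starts[jj]
      later_bridge <- which(on_bridge & seq_along(on_bridge) > s0)
      s1 <- if (length(later_bridge)) later_bridge[1] - 1 else nrow(p)
      j_t0 <- p$t[s0]; j_t1 <- p$t[s1]
      pressed <- any(presses >= j_t0 & presses <= j_t1)
      row <- data.frame(trial_id = tr$trial_id, journey_id = jj,
                        t_start = j_t0, t_end = j_t1, lever_pressed = pressed,
                        search_start = NA_real_, search_end = NA_real_,
                        homing_start = NA_real_, homing_end = NA_real_,
                        periph_x = NA_real_, periph_y = NA_real_,
                        complete = !pressed)
      if (pressed) {
        t_press <- presses[presses >= j_t0 & presses <= j_t1][1]
        idx <- s0:s1
        at_lever <- idx[wall_d[idx] < g$lever_proximity_threshold]
        if (length(at_lever)) {
          row$search_start <- j_t0
          row$search_end <- p$t[at_lever[1]]
          after <- idx[p$t[idx] > t_press &
                         wall_d[idx] >= g$lever_proximity_threshold]
          if (length(after)) {
            row$homing_start <- p$t[after[1]]
            arr <- after[r[after] >= g$arena_radius - g$periphery_threshold]
            if (length(arr)) {
              row$homing_end <- p$t[arr[1]]
              row$periph_x <- p$x[arr[1]]
              row$periph_y <- p$y[arr[1]]
              row$complete <- TRUE
            }
          }
        }
      }
      res[[length(res) + 1]] <- row
    }
  }
  do.call(rbind, res)
}

#' Path metrics: length, duration, speed, complexity
#'
#' Complexity is `ln((1 - MVL) * 100)` where MVL is the mean vector length
#' of the unit movement-direction vectors between consecutive samples.
#' Straight paths have MVL near 1; MVL is clamped at 0.999 before the log,
#' giving a floor of about -2.303, and a path with uniformly distributed
#' movement directions approaches the maximum ln(100) = 4.605.
#'
#' @param positions Data frame with columns `t`, `x`, `y` (>= 3 samples).
#' @return List with `length` (cm), `duration` (s), `mean_speed` (cm/s),
#'   `complexity`, and `mvl`.
#' @export
path_metrics <- function(positions) {
  if (nrow(positions) < 3) stop("need at least 3 position samples")
  dx <- diff(positions$x); dy <- diff(positions$y)
  step <- sqrt(dx^2 + dy^2)
  len <- sum(step)
  dur <- positions$t[nrow(positions)] - positions$t[1]
  if (dur <= 0) stop("duration must be positive")
  moving <- step > 1e-9
  mvl <- if (any(moving))
    mean_vector_length(rad2deg(atan2(dy[moving], dx[moving]))) else 0
  mvl <- min(mvl, 0.999)
  list(length = len, duration = dur, mean_speed = len / dur,
       complexity = log((1 - mvl) * 100), mvl = mvl)
}

#' Homing direction and error at the periphery
#'
#' The homing direction is the signed angle at the lever-box center between
#' the vector pointing to the bridge and the vector pointing to where the
#' animal reached the periphery. The homing error at the periphery is the
#' absolute angle at the arena center between the arrival point and the
#' bridge center, folded to \[0, 180\]; uniformly random arrivals give a
#' mean error of 90 degrees (chance level).
#'
#' @param journeys Rows from [segment_journeys()] with a recorded periphery
#'   arrival.
#' @param trials Output of [segment_trials()] (for lever poses).
#' @param geometry An [arena_geometry()].
#' @return Data frame with `trial_id`, `journey_id`, `homing_direction`
#'   (deg, signed), and `error_at_periphery` (deg in \[0, 180\]).
#' @export
homing_geometry <- function(journeys, trials, geometry) {
  j <- journeys[journeys$complete & !is.na(journeys$periph_x), , drop = FALSE]
  if (!nrow(j)) stop("no journeys with a periphery arrival")
  m <- match(j$trial_id, trials$trial_id)
  br <- geometry$bridge_center
  v_bridge <- angle_from_south(br[1] - trials$lever_cx[m],
                               br[2] - trials$lever_cy[m])
  v_arr <- angle_from_south(j$periph_x - trials$lever_cx[m],
                            j$periph_y - trials$lever_cy[m])
  az_arr <- angle_from_south(j$periph_x, j$periph_y)
  az_bridge <- angle_from_south(br[1], br[2])
  data.frame(trial_id = j$trial_id, journey_id = j$journey_id,
             homing_direction = wrap180(v_arr - v_bridge),
             error_at_periphery = abs(wrap180(az_arr - az_bridge)))
}

#' Median split of trials by a score
#'
#' Partitions trials into equally sized low/high groups at the within-set
#' median; the median element goes to the low group, so group sizes differ
#' by at most one.
#'
#' @param score Per-trial scalar scores (length >= 2).
#' @return List with integer index vectors `low` and `high`.
#' @export
split_trials_by_median <- function(score) {
  if (length(score) < 2) stop("need at least 2 scored trials")
  if (diff(range(score)) == 0) stop("all scores identical; split undefined")
  ord <- order(score)
  n_low <- ceiling(length(score) / 2)
  list(low = sort(ord[seq_len(n_low)]),
       high = sort(ord[-seq_len(n_low)]))
}

#' Light/dark classification from path features
#'
#' Linear support-vector-machine classification of the light condition from
#' per-trial behavioral features (typically length, duration, speed, and
#' complexity of the search and homing paths), evaluated by stratified
#' k-fold cross-validation. Features are standardized per fold using the
#' training-fold statistics.
#'
#' @param features Numeric matrix or data frame, one row per trial.
#' @param light Logical labels, one per trial.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List with `accuracy` (mean over folds), `sd`, and per-fold
#'   accuracies.
#' @export
light_dark_classifier <- function(features, light, k = 10, seed = 1) {
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(light))
  if (nrow(x) < 20) stop("need at least 20 labeled trials")
  if (length(unique(light)) < 2) stop("both classes must be present")
  set.seed(seed)
  fold <- integer(nrow(x))
  for (cl in unique(light)) {
    idx <- sample(which(light == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f; te <- !tr
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    xs <- scale(x, center = mu, scale = sg)
    fit <- e1071::svm(xs[tr, , drop = FALSE], factor(light[tr]),
                      kernel = "linear", scale = FALSE)
    mean(stats::predict(fit, xs[te, , drop = FALSE]) == factor(light[te]))
  }, numeric(1))
  list(accuracy = mean(acc), sd = stats::sd(acc), fold_accuracy = acc)
}

#' Per-journey behavioral summary table
#'
#' Convenience wrapper producing one row per lever-pressed journey with the
#' path metrics of its search and homing segments and the homing result.
#'
#' @param session A `homing_session`.
#' @param trials,journeys Outputs of [segment_trials()] and
#'   [segment_journeys()]; computed if missing.
#' @return Data frame with per-journey search/homing metrics, light flag,
#'   homing direction, and error at the periphery.
#' @export
behavior_table <- function(session, trials = NULL, journeys = NULL) {
  if (is.null(trials)) trials <- segment_trials(session)
  if (is.null(journeys)) journeys <- segment_journeys(session, trials)
  j <- journeys[journeys$lever_pressed & journeys$complete, , drop = FALSE]
  if (!nrow(j)) stop("no complete lever-pressed journeys")
  seg <- function(t0, t1) {
    m <- tryCatch(path_metrics(positions_between(session, t0, t1)),
                  error = function(e) NULL)
    if (is.null(m)) rep(NA_real_, 4) else
      unlist(m[c("length", "duration", "mean_speed", "complexity")])
  }
  s <- t(mapply(seg, j$search_start, j$search_end))
  h <- t(mapply(seg, j$homing_start, j$homing_end))
  colnames(s) <- colnames(h) <- c("length", "duration", "mean_speed", "complexity")
  # journeys whose search or homing segment is too short for metrics
  # (e.g. lever near the periphery) are dropped
  ok <- stats::complete.cases(s) & stats::complete.cases(h)
  j <- j[ok, , drop = FALSE]; s <- s[ok, , drop = FALSE]; h <- h[ok, , drop = FALSE]
  if (!nrow(j)) stop("no journeys with measurable search and homing paths")
  hg <- homing_geometry(j, trials, session$geometry)
  colnames(s) <- paste0("search_", colnames(s))
  colnames(h) <- paste0("homing_", colnames(h))
  cbind(j[, c("trial_id", "journey_id")],
        light = trials$light[match(j$trial_id, trials$trial_id)],
        as.data.frame(s), as.data.frame(h),
        hg[match(paste(j$trial_id, j$journey_id),
                 paste(hg$trial_id, hg$journey_id)),
           c("homing_direction", "error_at_periphery")])
}
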