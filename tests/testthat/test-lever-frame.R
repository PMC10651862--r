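test_that("lever-frame transform aligns reference vectors as specified", {
  g <- arena_geometry()
  pose_s <- list(cx = 5, cy = 5, dx = 0, dy = -1)  # lever points south
  pos <- data.frame(t = 1:4 / 10,
                    x = 5 + c(0, 1, 0, -1) * 8,
                    y = 5 + c(-1, 0, 1, 0) * 8)
  fd <- to_lever_frame(pos, pose_s, g, "cardinal")
  expect_equal(fd$direction, c(0, 90, -180, -90), tolerance = 1e-9)
  # lever direction pointing south: lever frame equals cardinal frame
  fl <- to_lever_frame(pos, pose_s, g, "lever")
  expect_equal(fl$direction, fd$direction, tolerance = 1e-9)
  # lever on the bridge-center axis: bridge frame equals cardinal frame
  pose_axis <- list(cx = 0, cy = 10, dx = 1, dy = 0)
  pos2 <- data.frame(t = 1:4 / 10, x = c(0, 8, 0, -8), y = 10 + c(-8, 0, 8, 0))
  fb <- to_lever_frame(pos2, pose_axis, g, "bridge")
  fc <- to_lever_frame(pos2, pose_axis, g, "cardinal")
  expect_equal(fb$direction, fc$direction, tolerance = 1e-9)
  # samples beyond the 12-cm frame radius are dropped
  far <- data.frame(t = 1, x = 40, y = 5)
  expect_equal(nrow(to_lever_frame(far, pose_s, g, "cardinal")), 0)
})

test_that("directional tuning matches delta, antipodal, and orthogonal cases", {
  mk_fd <- function(dirs, reps) {
    d <- rep(dirs, reps)
    a <- (d - 90) * pi / 180  # math angle whose south-referenced angle is d
    data.frame(t = seq_along(d) / 50, x = 8 * cos(a), y = 8 * sin(a),
               direction = d, wall_distance = 4)
  }
  # all spikes in one bin: high MVL
  fd <- mk_fd(seq(-175, 175, by = 10), 20)
  spikes_at <- function(fd, dirs) fd$t[fd$direction %in% dirs] + 0.001
  t1 <- directional_tuning(fd, spikes_at(fd, 5))
  expect_gt(t1$mvl, 0.95)
  expect_lt(abs(t1$preferred_direction - 5), 6)
  # equal rate at 0 and 180: antipodal symmetry, MVL ~ 0
  t2 <- directional_tuning(fd, spikes_at(fd, c(5, -175)))
  expect_lt(t2$mvl, 0.05)
  # equal rate at 0 and 90 only: resultant sqrt(2)/2 (up to smoothing)
  t3 <- directional_tuning(fd, spikes_at(fd, c(5, 95)))
  expect_equal(t3$mvl, sqrt(2) / 2, tolerance = 0.05)
  expect_error(directional_tuning(fd[0, ], numeric(0)), "occupancy")
})

test_that("lever-anchored classification recovers the injected archetypes", {
  g <- fx_mixed()
  la <- classify_lever_anchored(g$session, g$trials, g$journeys, "n01",
                                n_shuffles = 200, seed = 1)
  expect_true(la$peak_near_lever)
  expect_true(la$peak_rate_ok)
  expect_true(la$split_half_stable)
  expect_true(la$anchored)
  expect_lte(la$distance_peak_location, 10)
  lp <- classify_lever_anchored(g$session, g$trials, g$journeys, "n02",
                                n_shuffles = 200, seed = 1)
  expect_false(lp$anchored)
  # scaling rates down forces the 7.5-Hz peak criterion to fail
  s_low <- g$session
  set.seed(11)
  s_low$spikes$n01 <- sort(sample(s_low$spikes$n01,
                                  round(length(s_low$spikes$n01) * 0.3)))
  ll <- classify_lever_anchored(s_low, g$trials, g$journeys, "n01",
                                n_shuffles = 200, seed = 1)
  expect_false(ll$peak_rate_ok)
  expect_false(ll$anchored)
  expect_error(classify_lever_anchored(g$session, g$trials[1:3, ],
                                       g$journeys[1:3, ], "n01"),
               "at least 10")
})

test_that("trial drift recovers constructed shifts exactly", {
  base <- 0.2 + 10 * exp(5 * (cos((seq(-170, 170, 20) - 30) * pi / 180) - 1))
  roll <- homingfields:::roll_left
  mk <- function(rowfun) {
    m <- make_direction_matrix(rep(0, 12), peak = 10)
    m$rate <- t(vapply(1:12, rowfun, numeric(18)))
    m$rate_raw <- m$rate
    m
  }
  # rows identical to the reference curve: zero drift everywhere
  d0 <- trial_drift(mk(function(i) base), reference = base)
  expect_true(all(abs(d0$delta) < 1e-6))
  # every row shifted by +40 degrees (2 bins of 20): drift +40 everywhere
  d40 <- trial_drift(mk(function(i) roll(base, -2)), reference = base)
  expect_true(all(abs(d40$delta - 40) < 1e-6))
  # under the default peak-aligned procedure a common shift is absorbed:
  # drift is measured relative to the session-average tuning
  dd <- trial_drift(mk(function(i) roll(base, -2)))
  expect_true(all(abs(dd$delta) < 1e-6))
})

test_that("drift with a fixed reference is exactly shift-equivariant", {
  set.seed(13)
  base <- 0.2 + 10 * exp(5 * (cos((seq(-170, 170, 20) - 30) * pi / 180) - 1))
  m <- make_direction_matrix(rnorm(30, 0, 15), peak = 12)
  d1 <- trial_drift(m, reference = base)
  roll <- homingfields:::roll_left
  m2 <- m
  m2$rate <- t(apply(m$rate, 1, roll, k = -3))  # +60 degrees on every row
  m2$rate_raw <- t(apply(m$rate_raw, 1, roll, k = -3))
  d2 <- trial_drift(m2, reference = base)
  expect_equal(wrap180(d2$delta - d1$delta), rep(60, 30), tolerance = 1e-6)
})

test_that("injected per-trial rotations are recovered from generated spikes", {
  g <- fx_mixed()
  dm <- build_trial_matrix(g$session, g$trials, g$journeys, "n01",
                           "lever_direction", "at_lever")
  dr <- trial_drift(dm)
  inj <- g$truth$drift[match(dm$meta$trial_id, g$truth$trials$trial_id), "n01"]
  ok <- is.finite(dr$delta)
  expect_gt(sum(ok), 40)
  expect_lt(sqrt(mean(wrap180(dr$delta[ok] - inj[ok])^2)), 20)
})

test_that("drift-homing coupling finds identity coupling and rejects nulls", {
  set.seed(14)
  homing <- homingfields:::rvonmises_deg(60, 0, 2)
  cp <- drift_homing_coupling(wrap180(homing + rnorm(60, 0, 3)), homing,
                              n_shuffles = 200, seed = 1)
  expect_gt(cp$r, 0.9)
  expect_lt(cp$p, 0.01)
  expect_equal(cp$slope, 1, tolerance = 0.1)
  indep <- drift_homing_coupling(rnorm(60, 0, 30),
                                 homingfields:::rvonmises_deg(60, 0, 2),
                                 n_shuffles = 200, seed = 1)
  expect_gt(indep$p, 0.01)
  expect_error(drift_homing_coupling(rep(5, 20), homing[1:20]), "degenerate")
})

test_that("preferred-direction split test tracks the coupling sign", {
  set.seed(15)
  homing <- homingfields:::rvonmises_deg(50, 0, 2)
  m <- make_direction_matrix(wrap180(1.0 * homing + rnorm(50, 0, 5)),
                             peak = 12, homing = homing)
  ps <- preferred_direction_split_test(m, n_shuffles = 200, seed = 1)
  expect_gt(ps$delta_pd, 0)   # high-homing group rotates with the drift
  expect_lt(ps$p, 0.05)
  # identical tuning in both groups: delta ~ 0, non-significant
  m0 <- make_direction_matrix(rep(0, 50), peak = 12, homing = homing)
  ps0 <- preferred_direction_split_test(m0, n_shuffles = 200, seed = 1)
  expect_lt(abs(ps0$delta_pd), 15)
  expect_gt(ps0$p, 0.05)
})

test_that("reference frames are equivariant under rigid rotation", {
  g <- fx_mixed()
  rot <- rotate_session(g$session, g$trials, 37)
  clf <- homingfields:::collect_lever_frame
  for (fr in c("cardinal", "bridge", "lever")) {
    t1 <- directional_tuning(clf(g$session, g$trials, g$journeys, frame = fr),
                             g$session$spikes$n01)
    t2 <- directional_tuning(clf(rot$session, rot$trials, g$journeys, frame = fr),
                             rot$session$spikes$n01)
    shift <- wrap180(t2$preferred_direction - t1$preferred_direction)
    expect_lt(abs(shift - if (fr == "cardinal") 37 else 0), 10)
  }
})
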