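test_that("trial segmentation counts trials and applies the 30-cm exclusion", {
  g <- fx_mixed()
  expect_equal(nrow(g$trials), 50)
  expect_false(any(g$trials$excluded))  # generator respects the 30-cm rule
  # move one lever beyond 30 cm from the center
  s <- g$session
  k <- 5
  s$lever_poses$cx[k] <- 31; s$lever_poses$cy[k] <- 0
  tr <- segment_trials(s)
  expect_true(tr$excluded[k])
  expect_false(tr$excluded[k + 1])
})

test_that("unpaired door events raise a segmentation error", {
  s <- fx_mixed()$session
  s$events <- s$events[-max(which(s$events$kind == "door_close")), ]
  expect_error(segment_trials(s), "unpaired door events")
})

test_that("journeys are segmented into search, at-lever, and homing", {
  g <- fx_mixed()
  j <- g$journeys
  expect_equal(nrow(j), 50)       # one clean journey per trial
  expect_true(all(j$lever_pressed))
  cmpl <- j[j$complete, ]
  expect_true(all(cmpl$search_end >= cmpl$search_start))
  expect_true(all(cmpl$homing_start >= cmpl$search_end))
  expect_true(all(cmpl$homing_end >= cmpl$homing_start))
  # periphery arrival lies in the 3-cm edge zone
  r <- sqrt(cmpl$periph_x^2 + cmpl$periph_y^2)
  expect_true(all(r >= 37 - 1e-9 & r <= 41))
  # journey durations sum to at most the trial durations
  tr <- g$trials
  expect_true(all(tapply(j$t_end - j$t_start, j$trial_id, sum) <=
                    tr$t_end - tr$t_start + 1e-9))
})

test_that("a failed excursion yields an extra journey without a press", {
  g <- generate_session(behavior_spec(n_trials = 8,
                                      multi_journey_prob_light = 1,
                                      multi_journey_prob_dark = 1),
                        list(), seed = 17)
  tr <- segment_trials(g$session)
  j <- segment_journeys(g$session, tr)
  counts <- table(j$trial_id)
  expect_true(any(counts >= 2))
  firsts <- j[j$journey_id == 1 & j$trial_id %in% names(counts[counts >= 2]), ]
  expect_true(all(!firsts$lever_pressed))
})

test_that("path complexity matches its closed-form values", {
  # straight path: MVL ~ 1 clamps at the floor ln(0.1) ~ -2.303
  straight <- data.frame(t = 1:50, x = seq(0, 49), y = rep(0, 50))
  expect_equal(path_metrics(straight)$complexity, log(0.1), tolerance = 1e-9)
  # movement directions uniform on a semicircle: MVL = 2/pi
  ang <- seq(-90, 90, length.out = 2001)[-1] * pi / 180
  semi <- data.frame(t = 0:2000, x = c(0, cumsum(cos(ang))),
                     y = c(0, cumsum(sin(ang))))
  expect_equal(path_metrics(semi)$complexity, log((1 - 2 / pi) * 100),
               tolerance = 5e-3)
  # directions uniform on the full circle: complexity -> ln(100)
  ang2 <- seq(0, 2 * pi, length.out = 1001)[-1]
  full <- data.frame(t = 0:1000, x = c(0, cumsum(cos(ang2))),
                     y = c(0, cumsum(sin(ang2))))
  expect_equal(path_metrics(full)$complexity, log(100), tolerance = 1e-6)
  expect_error(path_metrics(straight[1:2, ]), "at least 3")
})

test_that("complexity is invariant under rotation and translation", {
  set.seed(3)
  ang <- cumsum(rnorm(200, 0, 0.5))
  p <- data.frame(t = 1:200, x = cumsum(cos(ang)), y = cumsum(sin(ang)))
  c0 <- path_metrics(p)$complexity
  rot <- homingfields:::rotate_xy(p$x, p$y, 63)
  p2 <- data.frame(t = p$t, x = rot$x + 12, y = rot$y - 7)
  expect_equal(path_metrics(p2)$complexity, c0, tolerance = 1e-9)
  expect_equal(path_metrics(p2)$length, path_metrics(p)$length, tolerance = 1e-9)
})

test_that("homing geometry handles identity, opposite, and uniform arrivals", {
  g <- arena_geometry()
  # lever at the arena center: the lever-to-bridge vector points due south,
  # so the arrival nearest the bridge is exactly on it
  trials <- data.frame(trial_id = 1, t_start = 0, t_end = 1, light = TRUE,
                       lever_cx = 0, lever_cy = 0, lever_dx = 1, lever_dy = 0,
                       excluded = FALSE)
  mk_j <- function(px, py) data.frame(
    trial_id = 1, journey_id = seq_along(px), t_start = 0, t_end = 1,
    lever_pressed = TRUE, search_start = 0, search_end = 0.3,
    homing_start = 0.5, homing_end = 0.9, periph_x = px, periph_y = py,
    complete = TRUE)
  # arrival at the point nearest the bridge: direction 0, error 0
  h <- homing_geometry(mk_j(0, -40), trials, g)
  expect_equal(h$homing_direction, 0, tolerance = 1e-9)
  expect_equal(h$error_at_periphery, 0, tolerance = 1e-9)
  # arrival diametrically opposite the bridge: error 180
  expect_equal(homing_geometry(mk_j(0, 40), trials, g)$error_at_periphery, 180)
  # uniform arrivals: mean error ~ 90 (chance level)
  th <- seq(0, 2 * pi, length.out = 1441)[-1]
  hu <- homing_geometry(mk_j(40 * cos(th), 40 * sin(th)), trials, g)
  expect_equal(mean(hu$error_at_periphery), 90, tolerance = 0.5)
})

test_that("median split partitions deterministically with the tie to low", {
  s <- split_trials_by_median(1:10)
  expect_equal(s$low, 1:5); expect_equal(s$high, 6:10)
  s11 <- split_trials_by_median(1:11)
  expect_length(s11$low, 6); expect_length(s11$high, 5)
  expect_true(6 %in% s11$low)  # median element goes low
  expect_error(split_trials_by_median(rep(2, 5)), "identical")
  # generator couples search length and homing error in darkness
  bt <- fx_behavior()$table
  d <- bt[!bt$light, ]
  sp <- split_trials_by_median(d$search_length)
  expect_gt(mean(d$error_at_periphery[sp$high]),
            mean(d$error_at_periphery[sp$low]))
})

test_that("light/dark SVM separates real structure but not noise", {
  bt <- fx_behavior()$table
  X <- behavior_features(bt)
  cv <- light_dark_classifier(X, bt$light, seed = 1)
  expect_gt(cv$accuracy, 0.9)
  # shuffled labels: chance accuracy
  set.seed(4)
  null_acc <- light_dark_classifier(X, sample(bt$light), seed = 1)$accuracy
  expect_lt(abs(null_acc - 0.5), 0.2)
  # unlearnable: duplicated rows with opposite labels
  X2 <- rbind(X[1:20, ], X[1:20, ])
  lab <- c(rep(TRUE, 20), rep(FALSE, 20))
  expect_lt(abs(light_dark_classifier(X2, lab, seed = 1)$accuracy - 0.5), 0.25)
  expect_error(light_dark_classifier(X, rep(TRUE, nrow(X))), "both classes")
})
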