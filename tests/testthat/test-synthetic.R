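test_that("identical seeds give identical sessions", {
  b <- behavior_spec(n_trials = 5)
  f <- list(field_spec("place"))
  g1 <- generate_session(b, f, seed = 9)
  g2 <- generate_session(b, f, seed = 9)
  expect_identical(g1$session$positions, g2$session$positions)
  expect_identical(g1$session$spikes, g2$session$spikes)
  expect_identical(g1$truth$trials, g2$truth$trials)
})

test_that("trial sequence starts with seven light trials then alternates", {
  g <- generate_session(behavior_spec(n_trials = 15), list(), seed = 2)
  tr <- segment_trials(g$session)
  expect_true(all(tr$light[1:7]))
  expect_equal(tr$light[8:15], rep(c(FALSE, TRUE), 4))
})

test_that("lever centers stay within 75% of the arena radius", {
  g <- generate_session(behavior_spec(n_trials = 40), list(), seed = 6)
  r <- sqrt(g$truth$trials$lever_cx^2 + g$truth$trials$lever_cy^2)
  expect_true(all(r <= 30 + 1e-9))
  # placement is re-drawn every 4th trial, rotated otherwise: radii constant
  # within each block of 4 trials
  blocks <- split(r, (g$truth$trials$trial_id - 1) %/% 4)
  expect_true(all(vapply(blocks, function(b) diff(range(b)) < 1e-9, logical(1))))
})

test_that("dark search paths are more complex and slower than light ones", {
  bt <- fx_behavior()$table
  expect_gt(mean(bt$search_complexity[!bt$light]),
            mean(bt$search_complexity[bt$light]))
  expect_lt(mean(bt$search_mean_speed[!bt$light]),
            mean(bt$search_mean_speed[bt$light]))
})

test_that("homing error grows with search length when coupled, not otherwise", {
  bt <- fx_behavior()$table
  d <- !bt$light
  expect_gt(cor(bt$search_length[d], bt$error_at_periphery[d]), 0.25)
  g0 <- generate_session(behavior_spec(n_trials = 60,
                                       homing_error_length_coupling = 0),
                         list(), seed = 8)
  t0 <- segment_trials(g0$session)
  b0 <- behavior_table(g0$session, t0)
  d0 <- !b0$light
  expect_lt(abs(cor(b0$search_length[d0], b0$error_at_periphery[d0])), 0.3)
})

test_that("a place field is recovered at its injected location and rate", {
  # dense uniform arena coverage over 30 simulated minutes
  set.seed(10)
  n <- 30 * 60 * 50
  rr <- 38 * sqrt(runif(n)); aa <- runif(n, 0, 2 * pi)
  x <- rr * cos(aa); y <- rr * sin(aa)
  pos <- data.frame(t = seq_len(n) / 50, x = x, y = y)
  ctr <- c(8, -5); peak <- 10; sdc <- 8
  rate <- 0.1 + (peak - 0.1) *
    exp(-((x - ctr[1])^2 + (y - ctr[2])^2) / (2 * sdc^2))
  spk <- pos$t[rep(seq_len(n), rpois(n, rate / 50))]
  m <- rate_map_2d(pos, spk)
  pk <- which(m$rate == max(m$rate, na.rm = TRUE), arr.ind = TRUE)[1, ]
  px <- (m$x_edges[pk[1]] + m$x_edges[pk[1] + 1]) / 2
  py <- (m$y_edges[pk[2]] + m$y_edges[pk[2] + 1]) / 2
  expect_lt(sqrt((px - ctr[1])^2 + (py - ctr[2])^2), 5)
  expect_lt(abs(max(m$rate, na.rm = TRUE) - peak) / peak, 0.3)
})

test_that("injected drift tracks homing direction in the generator", {
  g <- fx_mixed()
  inj <- g$truth$drift[, "n01"]
  expect_gt(circular_correlation(inj, g$truth$trials$homing_direction), 0.6)
  g2 <- generate_session(behavior_spec(n_trials = 100),
                         list(field_spec("lever_anchored", drift_slope = 1,
                                         drift_noise_sd = 5)), seed = 12)
  expect_gt(circular_correlation(g2$truth$drift[, "n01"],
                                 g2$truth$trials$homing_direction), 0.8)
})

test_that("spike counts follow Poisson statistics given the rate", {
  # homogeneous baseline neuron: counts in disjoint windows ~ Poisson
  g <- generate_session(behavior_spec(n_trials = 10),
                        list(field_spec("place", peak_rate = 5.001,
                                        baseline_rate = 5)), seed = 13)
  st <- g$session$spikes$n01
  tmax <- max(g$session$positions$t)
  counts <- tabulate(findInterval(st, seq(0, tmax, by = 2)),
                     nbins = floor(tmax / 2))
  disp <- var(counts) / mean(counts)  # ~1 for Poisson
  expect_gt(disp, 0.75); expect_lt(disp, 1.35)
})

test_that("unit feature generation conserves counts and labels", {
  e <- generate_unit_features(0, 0)
  expect_length(e$mean_rate, 0)
  u <- generate_unit_features(50, 20, seed = 1)
  expect_length(u$mean_rate, 70)
  expect_equal(sum(u$true_class == "pyramidal"), 50)
  expect_equal(dim(u$autocorrelation), c(70, 50))
})
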