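test_that("trial matrix correlation hits its closed-form anchor cases", {
  v <- c(1, 3, 7, 2, 5)
  m_same <- rbind(v, v, v)
  expect_equal(trial_matrix_correlation(m_same)$value, 1)
  expect_equal(trial_matrix_correlation(m_same)$n_pairs, 3)
  # two rows v and -v: perfectly anticorrelated
  expect_equal(trial_matrix_correlation(rbind(v, -v))$value, -1)
  # independent white-noise rows: near zero
  set.seed(7)
  noise <- matrix(rnorm(20 * 50), 20, 50)
  expect_lt(abs(trial_matrix_correlation(noise)$value), 0.1)
  # zero-variance rows are excluded and counted
  wz <- rbind(v, v, rep(2, 5))
  r <- trial_matrix_correlation(wz)
  expect_equal(r$n_excluded, 1)
  expect_error(trial_matrix_correlation(rbind(rep(1, 5), rep(2, 5))),
               "nonzero variance")
})

test_that("trial matrix correlation is invariant to row order and rescaling", {
  set.seed(8)
  base <- matrix(rnorm(10 * 30, 5), 10, 30) + outer(rep(1, 10), sin(1:30))
  v0 <- trial_matrix_correlation(base)$value
  expect_equal(trial_matrix_correlation(base[sample(10), ])$value, v0)
  expect_equal(trial_matrix_correlation(base * 3.7 + 0)$value, v0,
               tolerance = 1e-12)
})

test_that("built matrices express the injected field archetypes", {
  g <- fx_mixed()
  # place cell: peak at a constant y-bin independent of the lever
  mp <- build_trial_matrix(g$session, g$trials, g$journeys, "n02",
                           "y_coordinate", "search", light = TRUE)
  peaks <- homingfields:::row_peak_locations(mp$rate, mp$mids, FALSE)
  # rows whose search path actually crossed the field (field expressed)
  expressed <- apply(mp$rate, 1, max, na.rm = TRUE) > 5
  expect_gt(sum(expressed), 5)
  expect_lt(mad(peaks[expressed]), 6)
  expect_lt(abs(median(peaks[expressed]) - (-15)), 4)
  # lever-distance cell: peak at a constant distance bin
  md <- build_trial_matrix(g$session, g$trials, g$journeys, "n03",
                           "lever_distance", "search", light = TRUE)
  dpeaks <- homingfields:::row_peak_locations(md$rate, md$mids, FALSE)
  expect_lt(abs(median(dpeaks) - 15), 4)
  expect_gt(trial_matrix_correlation(md)$value, 0.3)
  expect_error(build_trial_matrix(g$session, g$trials[1, ], g$journeys[1, ],
                                  "n02", "y_coordinate", "search"),
               "at least 2")
})

test_that("within-row shuffles preserve each row's multiset of rates", {
  set.seed(9)
  m <- matrix(rnorm(5 * 8), 5, 8); m[2, 3] <- NA
  sh <- homingfields:::shuffle_within_rows(m)
  for (i in 1:5)
    expect_equal(sort(sh[i, is.finite(sh[i, ])]), sort(m[i, is.finite(m[i, ])]))
})

test_that("peak-vs-lever test flags lever-distance but not place coding", {
  g <- fx_mixed()
  md <- build_trial_matrix(g$session, g$trials, g$journeys, "n03",
                           "y_coordinate", "search", light = TRUE)
  pv <- peak_location_vs_lever(md, n_shuffles = 200, seed = 1)
  expect_true(pv$significant)
  expect_gt(pv$r, 0.5)
  mp <- build_trial_matrix(g$session, g$trials, g$journeys, "n02",
                           "y_coordinate", "search", light = TRUE)
  pv2 <- peak_location_vs_lever(mp, n_shuffles = 200, seed = 1)
  expect_false(pv2$significant)
  # determinism under a fixed seed
  pv3 <- peak_location_vs_lever(md, n_shuffles = 200, seed = 1)
  expect_identical(pv3$p, pv$p)
  expect_identical(pv3$r, pv$r)
})

test_that("matrix-correlation shuffle test separates reliable from shuffled", {
  g <- fx_mixed()
  md <- build_trial_matrix(g$session, g$trials, g$journeys, "n03",
                           "lever_distance", "search", light = TRUE)
  ts <- trial_matrix_correlation_test(md, n_shuffles = 100, seed = 2)
  expect_lt(ts$p, 0.05)
})
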