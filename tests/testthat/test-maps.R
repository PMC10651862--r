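uniform_disk <- function(n, radius = 38, seed = 1, rate_hz = NULL) {
  set.seed(seed)
  r <- radius * sqrt(runif(n)); a <- runif(n, 0, 2 * pi)
  pos <- data.frame(t = seq_len(n) / 50, x = r * cos(a), y = r * sin(a))
  if (is.null(rate_hz)) return(pos)
  list(pos = pos, spikes = pos$t[rep(seq_len(n), rpois(n, rate_hz / 50))])
}

test_that("a homogeneous Poisson neuron yields a flat map at its rate", {
  d <- uniform_disk(60000, rate_hz = 5, seed = 2)
  m <- rate_map_2d(d$pos, d$spikes)
  vals <- m$rate[is.finite(m$rate) & m$occupancy > 0.5]
  expect_equal(mean(vals), 5, tolerance = 0.1)
  expect_lt(stats::sd(vals), 1)
})

test_that("zero spikes give an all-zero map and spike counts are conserved", {
  pos <- uniform_disk(5000)
  m0 <- rate_map_2d(pos, numeric(0))
  expect_true(all(m0$rate[is.finite(m0$rate)] == 0))
  d <- uniform_disk(5000, rate_hz = 8, seed = 3)
  m <- rate_map_2d(d$pos, d$spikes)
  expect_equal(sum(m$spike_count), length(d$spikes))
  # pre-smoothing rate x occupancy recovers the spike count
  expect_equal(sum(m$spike_count[m$valid] /
                     m$occupancy_raw[m$valid] * m$occupancy_raw[m$valid]),
               length(d$spikes))
  expect_error(rate_map_2d(pos[0, ], numeric(0)), "no position")
})

test_that("smoothing with SD 0 recovers the unsmoothed map", {
  d <- uniform_disk(3000, rate_hz = 6, seed = 4)
  m <- rate_map_2d(d$pos, d$spikes, smoothing_sd = 0)
  raw <- ifelse(m$occupancy_raw > 0, m$spike_count / m$occupancy_raw, NA)
  expect_equal(m$rate, raw, tolerance = 1e-12)
})

test_that("histogram range follows the smallest-90th-percentile rule", {
  set.seed(5)
  l <- runif(500, -40, 30); d <- runif(500, -40, 25)
  rg <- histogram_range(l, d, "y_coordinate")
  expect_equal(rg[1], -42.5)
  expect_equal(rg[2], min(quantile(l, 0.9), quantile(d, 0.9)),
               ignore_attr = TRUE)
  same <- histogram_range(l, l, "y_coordinate")
  expect_equal(same[2], quantile(l, 0.9), ignore_attr = TRUE)
  # lever distance: fixed minimum of 12 cm regardless of the data
  expect_equal(histogram_range(runif(100, 0, 5), runif(100, 0, 5),
                               "lever_distance")[1], 12)
})

test_that("1D histograms localize a lever-distance field and handle nulls", {
  g <- fx_mixed()
  s <- g$session; tr <- g$trials; j <- g$journeys
  jj <- j[j$lever_pressed & !is.na(j$search_end), ]
  pool <- do.call(rbind, lapply(seq_len(nrow(jj)), function(i) {
    p <- homingfields:::positions_between(s, jj$search_start[i], jj$search_end[i])
    trr <- tr[tr$trial_id == jj$trial_id[i], ]
    p$d <- lever_wall_distance(p$x, p$y, c(trr$lever_cx, trr$lever_cy),
                               c(trr$lever_dx, trr$lever_dy))
    p
  }))
  dw <- homingfields:::dwell_times(pool$t)
  sidx <- homingfields:::restrict_spikes(s$spikes$n03, pool)
  h <- rate_histogram_1d(pool$d, dw, pool$d[sidx], range = c(12, 36))
  expect_length(h$rate, 20)
  # injected field at 15 cm: peak bin within one bin of it
  expect_lt(abs(h$mids[which.max(h$rate)] - 15), 2.5)
  # no spikes: zero histogram, zero mean rate
  h0 <- rate_histogram_1d(pool$d, dw, numeric(0), range = c(12, 36))
  expect_equal(h0$mean_rate, 0)
  expect_true(all(h0$rate[is.finite(h0$rate)] == 0))
})

test_that("information score matches hand-computed and brute-force oracles", {
  mk_hist <- function(p, rate) {
    structure(list(p = p, rate_raw = rate, valid = rep(TRUE, length(p)),
                   mean_rate = sum(p * rate)), class = "rate_histogram")
  }
  # uniform rate: zero information
  expect_equal(information_score(mk_hist(rep(0.05, 20), rep(3, 20))), 0)
  # two equal-occupancy bins at (2, 0) Hz: exactly 1 bit/spike
  expect_equal(information_score(mk_hist(c(0.5, 0.5), c(2, 0))), 1)
  # brute-force oracle equivalence on 100 random 20-bin histograms
  set.seed(6)
  for (i in 1:100) {
    p <- runif(20); p <- p / sum(p)
    lam <- rexp(20, 1) * rbinom(20, 1, 0.9)
    oracle <- 0
    lbar <- sum(p * lam)
    for (b in 1:20)
      if (lam[b] > 0) oracle <- oracle + p[b] * (lam[b] / lbar) * log2(lam[b] / lbar)
    expect_equal(information_score(mk_hist(p, lam)), oracle, tolerance = 1e-12)
    # invariance under rate rescaling
    expect_equal(information_score(mk_hist(p, 7.3 * lam)), oracle,
                 tolerance = 1e-12)
  }
  expect_error(information_score(mk_hist(c(0.5, 0.5), c(0, 0))), "zero")
})

test_that("masked smoothing renormalizes at edges without bleeding", {
  v <- c(NA, NA, 4, 4, 4, NA, 4, 4)
  s <- homingfields:::smooth_1d(v, 1)
  expect_true(all(is.na(s[c(1, 2, 6)])))
  expect_equal(s[!is.na(v)], rep(4, 5), tolerance = 1e-9)
})
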