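test_that("spike detection recovers a constructed train exactly", {
  tt <- triangle_train(n = 10, period = 20, base = -60, peak = -30,
                       width = 1)
  # flat trace: no spikes
  flat <- detect_spikes(tt$time, rep(-65, length(tt$time)))
  expect_equal(nrow(flat), 0)
  tr <- detect_spikes(tt$time, tt$v, threshold = -50)
  expect_equal(nrow(tr), 10)
  expect_equal(diff(tr$t), rep(20, 9), tolerance = 1e-9)
  expect_equal(tr$peak, rep(-30, 10), tolerance = 1e-9)
})

test_that("spike detection is invariant to offset and decimation", {
  tt <- triangle_train(n = 8, period = 25, base = -70, peak = 10, width = 1.2)
  t1 <- detect_spikes(tt$time, tt$v)
  # uniform subthreshold offset
  t2 <- detect_spikes(tt$time, tt$v - 8)
  expect_equal(t2$t, t1$t, tolerance = 0.05)
  # 2x decimation
  keep <- seq(1, length(tt$time), by = 2)
  t3 <- detect_spikes(tt$time[keep], tt$v[keep])
  expect_equal(t3$t, t1$t, tolerance = 0.06)
})

test_that("refractory handling keeps one spike per window", {
  tt <- triangle_train(n = 6, period = 0.6, base = -60, peak = 0,
                       width = 0.3)
  tr <- detect_spikes(tt$time, tt$v, refractory = 1)
  expect_lt(nrow(tr), 6)
})

test_that("spike shape of a symmetric triangular spike", {
  # base -60 mV, peak +20 mV, 1 ms base width
  tt <- triangle_train(n = 6, period = 30, base = -60, peak = 20, width = 1)
  tr <- detect_spikes(tt$time, tt$v)
  sh <- spike_shape(tt$time, tt$v, tr)
  expect_equal(sh$mean_amplitude, 80, tolerance = 1e-6)
  expect_equal(sh$mean_ahp, -60, tolerance = 1e-6)
  expect_equal(sh$mean_half_width, 0.5, tolerance = 0.03)
  expect_error(spike_shape(tt$time, tt$v, tr[0, ]), "no spikes")
})

test_that("transmission reliability counts matched spikes", {
  a <- structure(data.frame(t = seq(10, 200, by = 10), peak = 0),
                 class = c("pc_spike_train", "data.frame"))
  expect_equal(transmission_reliability(a, a), 1)
  b <- a[seq(1, nrow(a), by = 2), ]
  expect_equal(transmission_reliability(a, b), 0.5)
  # symmetric when both trains are complete
  expect_equal(transmission_reliability(b, a[a$t %in% b$t, ]), 1)
  # jitter within the window still matches
  c1 <- a; c1$t <- c1$t + 0.4
  expect_equal(transmission_reliability(a, c1), 1)
  c2 <- a; c2$t <- c2$t + 1.6
  expect_equal(transmission_reliability(a, c2, window = 1), 0)
})

test_that("conduction velocity from a constructed delay", {
  a <- structure(data.frame(t = seq(10, 200, by = 10), peak = 0),
                 class = c("pc_spike_train", "data.frame"))
  b <- a; b$t <- b$t + 0.44
  v <- conduction_velocity(a, b, path_length = 322.5)
  expect_equal(v, 322.5 / 0.44 / 1000, tolerance = 1e-9)
  expect_equal(v, 0.733, tolerance = 1e-3)
  # zero delay is flagged
  expect_error(conduction_velocity(a, a, 322.5), "non-positive")
  # too few propagated spikes is flagged
  expect_error(conduction_velocity(a[1:2, ], b[1:2, ], 322.5), "too few")
})

test_that("burst segmentation recovers a constructed burst train", {
  # 6 bursts per second, 20 spikes per burst at 280 Hz
  isi <- 1000 / 280
  burst_t <- unlist(lapply(0:5, function(k) k * 1000 / 6 + (0:19) * isi))
  train <- structure(data.frame(t = burst_t, peak = 0),
                     class = c("pc_spike_train", "data.frame"))
  bm <- burst_metrics(train, duration = 1000)
  expect_equal(bm$n_bursts, 6)
  expect_equal(bm$bursts_per_s, 6, tolerance = 0.01)
  expect_equal(bm$spikes_per_burst, 20)
  expect_equal(bm$intra_burst_freq, 280, tolerance = 0.1)
  # a tonic train yields the no-burst signal
  tonic <- structure(data.frame(t = seq(20, 2000, by = 20), peak = 0),
                     class = c("pc_spike_train", "data.frame"))
  expect_error(burst_metrics(tonic), "no-burst")
  expect_equal(classify_firing(tonic), "tonic")
  expect_equal(classify_firing(train), "bursting")
})

test_that("F/I summary fits the linear range", {
  current <- seq(0, 1.6, by = 0.1)
  rate <- 30 + 180 * current
  fit <- fi_curve(current, rate)
  expect_equal(fit$slope, 180, tolerance = 1e-9)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-9)
  expect_equal(fit$linear_max_rate, max(rate))
  # saturating curve: linear range stops before the plateau
  rate2 <- pmin(30 + 180 * current, 200)
  fit2 <- fi_curve(current, rate2)
  expect_lt(fit2$linear_range[2], 1.6)
})

test_that("instantaneous rate is assigned at the second spike", {
  train <- structure(data.frame(t = c(10, 30, 40), peak = 0),
                     class = c("pc_spike_train", "data.frame"))
  ir <- instantaneous_rate(train)
  expect_equal(ir$t, c(30, 40))
  expect_equal(ir$rate, c(50, 100))
})
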