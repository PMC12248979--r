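test_that("velocity of constant and linear motion is exact", {
  n <- 500
  tr0 <- make_trace(rep(0.2, n), rep(-0.1, n))
  v0 <- compute_velocity(tr0)
  expect_true(all(abs(v0$vlx) < 1e-12, na.rm = TRUE))
  ramp <- make_trace(3 * (0:(n - 1)) / 1000, rep(0, n))
  v <- compute_velocity(ramp)
  interior <- 50:(n - 50)
  expect_equal(v$vlx[interior], rep(3, length(interior)), tolerance = 1e-9)
  expect_true(all(abs(v$vly[interior]) < 1e-9))
})

test_that("velocity matches a brute-force windowed regression oracle", {
  set.seed(21)
  n <- 400
  x <- cumsum(rnorm(n, 0.002, 0.001)) + rnorm(n, sd = 0.002)
  tr <- make_trace(x, rev(x))
  v <- compute_velocity(tr, window_ms = 31)
  half <- 15
  oracle <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    oracle[i] <- unname(coef(lm(x[idx] ~ I(idx / 1000)))[2])
  }
  ok <- !is.na(oracle)
  expect_equal(v$vlx[ok], oracle[ok], tolerance = 1e-9)
})

test_that("velocity near blinks is undefined with 150-ms padding", {
  tr <- generate_trace(3, blink_intervals = data.frame(start_s = 1,
                                                       end_s = 1.2),
                       cfg = sim_config(), seed = 22)
  v <- compute_velocity(tr)
  expect_true(all(is.na(v$vlx[tr$time_ms >= 851 & tr$time_ms <= 1349])))
  expect_false(anyNA(v$vlx[tr$time_ms > 200 & tr$time_ms < 700]))
})

test_that("robust threshold recovers the scale of Gaussian velocities", {
  set.seed(23)
  s <- 0.8
  fake <- data.frame(time_ms = 0:9999,
                     vlx = rnorm(10000, sd = s), vly = rnorm(10000, sd = s),
                     vrx = rnorm(10000, sd = s), vry = rnorm(10000, sd = s))
  th <- estimate_threshold(fake, lambda = 5)
  # sqrt(median(v^2) - median(v)^2) -> 0.6745 * s for centered Gaussians
  expect_equal(unname(th$sigma), rep(0.6745 * s, 4), tolerance = 0.05)
  expect_equal(th$eta, 5 * th$sigma)
  th6 <- estimate_threshold(fake, lambda = 6)
  expect_equal(th6$eta, 6 * th$sigma)
})

test_that("degenerate velocity input is rejected", {
  fake <- data.frame(time_ms = 0:999, vlx = numeric(1000),
                     vly = numeric(1000), vrx = numeric(1000),
                     vry = numeric(1000))
  expect_error(estimate_threshold(fake), "degenerate")
  short <- data.frame(time_ms = 0:49, vlx = rnorm(50), vly = rnorm(50),
                      vrx = rnorm(50), vry = rnorm(50))
  expect_error(estimate_threshold(short), "fewer than 100")
})

test_that("one injected 30-arcmin event is found with accurate onset", {
  cfg <- sim_config(noise_sd = 0.01) # low noise; drift sets the threshold
  tr <- generate_trace(4, one_event(2, 0.5), cfg = cfg, seed = 24)
  det <- detect_microsaccades(tr)
  expect_equal(nrow(det$events), 1)
  expect_lt(abs(det$events$onset_ms - 2000), 5)
  expect_equal(det$events$amplitude_deg, 0.5, tolerance = 0.1)
})

test_that("events separated by less than 12 ms merge into one", {
  # two ballistic displacements 10 ms apart read as a single event
  cfg <- sim_config(noise_sd = 0.01)
  wf_dur <- 2 / cfg$main_sequence_slope
  ev <- data.frame(onset_s = c(2, 2 + wf_dur + 0.010),
                   amplitude_deg = c(0.4, 0.4),
                   direction_deg = c(20, 25))
  tr <- generate_trace(5, ev, cfg = cfg, seed = 25)
  det <- detect_microsaccades(tr)
  expect_equal(nrow(det$events), 1)
})

test_that("sub-3-arcmin displacements are classed as drift, not events", {
  cfg <- sim_config()
  hits <- vapply(1:10, function(i) {
    tr <- generate_trace(4, one_event(2, 2 / 60, runif(1, 0, 360)),
                         cfg = cfg, seed = 250 + i)
    nrow(detect_microsaccades(tr)$events)
  }, numeric(1))
  expect_equal(sum(hits), 0)
})

test_that("amplitudes beyond 2 degrees go to the large-saccade list", {
  cfg <- sim_config(noise_sd = 0.01)
  tr <- generate_trace(4, one_event(2, 2.5), cfg = cfg, seed = 26)
  det <- detect_microsaccades(tr)
  expect_equal(nrow(det$events), 0)
  expect_equal(nrow(det$large_saccades), 1)
  expect_gt(det$large_saccades$amplitude_deg, 2)
})

test_that("merging is idempotent", {
  onoff <- cbind(c(10, 30, 100, 300), c(20, 45, 140, 310))
  m1 <- fixfill:::merge_events(onoff, 12)
  m2 <- fixfill:::merge_events(m1, 12)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 3) # first two runs merge (gap 10 < 12)
})

test_that("detector recall and accuracy on injected events", {
  cfg <- sim_config()
  set.seed(27)
  amps <- exp(runif(60, log(0.1), log(1)))
  found <- logical(length(amps))
  amp_err <- rep(NA_real_, length(amps))
  for (i in seq_along(amps)) {
    tr <- generate_trace(3, one_event(1.5, amps[i], runif(1, 0, 360)),
                         cfg = cfg, seed = 400 + i)
    det <- detect_microsaccades(tr)
    if (nrow(det$events) > 0) {
      j <- which.min(abs(det$events$onset_ms - 1500))
      found[i] <- TRUE
      amp_err[i] <- abs(det$events$amplitude_deg[j] / amps[i] - 1)
    }
  }
  expect_gte(mean(found), 0.9)
  expect_lt(median(amp_err, na.rm = TRUE), 0.2)
})

test_that("false-alarm rate on event-free traces is below 0.05 Hz", {
  cfg <- sim_config()
  n_ev <- 0
  total_s <- 0
  for (i in 1:6) {
    tr <- generate_trace(20, cfg = cfg, seed = 500 + i)
    n_ev <- n_ev + nrow(detect_microsaccades(tr)$events)
    total_s <- total_s + 20
  }
  expect_gte(total_s, 100)
  expect_lt(n_ev / total_s, 0.05)
})

test_that("returned events respect amplitude and duration bounds", {
  cfg <- sim_config()
  p <- detection_params()
  ex <- generate_experiment(sim_config(n_participants = 2,
                                       trials_per_block = 5),
                            ground_truth(), seed = 28, emit_traces = TRUE)
  for (tr in ex$traces) {
    det <- detect_microsaccades(tr, p)
    if (nrow(det$events) == 0) next
    expect_true(all(det$events$amplitude_deg >= p$amp_min / 60))
    expect_true(all(det$events$amplitude_deg <= p$amp_max))
    expect_true(all(det$events$duration_ms >= p$min_duration))
    expect_true(all(det$events$peak_vel_deg_s > 0))
    # no event borders within 150 ms of an invalid interval
    bl <- trace_blinks(tr)
    for (k in seq_len(nrow(bl)))
      expect_true(all(det$events$offset_ms < bl$start_ms[k] - 150 |
                        det$events$onset_ms > bl$end_ms[k] + 150))
  }
})

test_that("main-sequence fit is exact under exact proportionality", {
  ev <- data.frame(amplitude_deg = seq(0.1, 1, length.out = 12))
  ev$peak_vel_deg_s <- 60 * ev$amplitude_deg
  ms <- main_sequence(ev)
  expect_equal(ms$slope, 1, tolerance = 1e-10)
  expect_equal(ms$correlation, 1, tolerance = 1e-10)
  expect_error(main_sequence(ev[1, , drop = FALSE]), "at least 10")
})

test_that("detected events from synthetic trials follow the main sequence", {
  ex <- generate_experiment(sim_config(n_participants = 2,
                                       trials_per_block = 8),
                            ground_truth(), seed = 29, emit_traces = TRUE)
  evs <- do.call(rbind, lapply(ex$traces,
                               function(tr) detect_microsaccades(tr)$events))
  expect_gte(nrow(evs), 10)
  expect_gt(main_sequence(evs)$correlation, 0.9)
})
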