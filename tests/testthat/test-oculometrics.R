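test_that("stationary gaze has zero retinal slip", {
  tr <- make_trace(rep(0.123, 1000), rep(-0.05, 1000))
  slip <- retinal_slip(tr)
  expect_equal(as.numeric(slip), 0)
  expect_equal(attr(slip, "n_segments"), 20)
})

test_that("straight-line drift recovers its speed within one grid quantum", {
  # 1 deg/s along x: each 50-ms segment crosses ~5 squares of 0.01 deg
  n <- 2000
  x <- (0:(n - 1)) / 1000 # 1 deg/s
  tr <- make_trace(x + 0.0012, rep(0.005, n)) # offset off the grid lines
  slip <- retinal_slip(tr)
  quantum <- 0.01 / 0.05
  expect_lt(abs(as.numeric(slip) - 1), quantum + 1e-9)
})

test_that("segments near microsaccades or blinks are excluded", {
  n <- 1000
  tr <- make_trace((0:(n - 1)) / 1000, rep(0, n))
  # event at 500-520 ms: with the 10-ms guard, segments [480,500) ...
  # [520,540) are contaminated
  ev <- data.frame(onset_ms = 500, offset_ms = 520)
  slip <- retinal_slip(tr, ev)
  base <- retinal_slip(tr)
  expect_equal(attr(base, "n_segments") - attr(slip, "n_segments"), 2)
  # a fully masked trace yields the flagged undefined value
  ev_all <- data.frame(onset_ms = 0, offset_ms = 1000)
  expect_true(is.na(as.numeric(retinal_slip(tr, ev_all))))
})

test_that("retinal slip is invariant to constant offsets up to a quantum", {
  tr1 <- generate_trace(3, cfg = sim_config(), seed = 31)
  tr2 <- tr1
  for (cl in c("lx_deg", "rx_deg")) tr2[[cl]] <- tr2[[cl]] + 1.2345
  for (cl in c("ly_deg", "ry_deg")) tr2[[cl]] <- tr2[[cl]] - 0.761
  s1 <- as.numeric(retinal_slip(tr1))
  s2 <- as.numeric(retinal_slip(tr2))
  expect_lt(abs(s1 - s2), 0.01 / 0.05)
})

test_that("mean drift increases with the diffusion constant", {
  slips <- vapply(c(0.0005, 0.002, 0.008), function(D) {
    mean(vapply(1:8, function(i) {
      as.numeric(retinal_slip(generate_trace(
        4, cfg = sim_config(drift_diffusion = D), seed = 320 + i)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(slips) > 0))
})

test_that("exclusion rules fire in their stated order of precedence", {
  tr <- generate_trace(5, cfg = clean_cfg(), seed = 33)
  no_sacc <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0))

  short <- apply_exclusions(1.5, tr, no_sacc)
  expect_false(short$kept)
  expect_equal(short$reason, "short_trial")

  # displaced gaze: constant offset 1.2 deg
  tr_far <- tr
  tr_far$lx_deg <- tr_far$lx_deg + 1.2
  tr_far$rx_deg <- tr_far$rx_deg + 1.2
  far <- apply_exclusions(5, tr_far, no_sacc)
  expect_equal(far$reason, "gaze_displacement")

  # blink ending 100 ms before the press
  bl <- data.frame(start_ms = 4700, end_ms = 4900)
  blink <- apply_exclusions(5, tr, no_sacc, blinks = bl)
  expect_equal(blink$reason, "peri_press_blink")

  # large saccade in the peri-press window
  ls <- data.frame(onset_ms = 4800, offset_ms = 4830)
  sacc <- apply_exclusions(5, tr, ls)
  expect_equal(sacc$reason, "peri_press_saccade")

  # blink outranks saccade when both apply
  both <- apply_exclusions(5, tr, ls, blinks = bl)
  expect_equal(both$reason, "peri_press_blink")

  # short trial outranks everything
  all_bad <- apply_exclusions(1.5, tr_far, ls, blinks = bl)
  expect_equal(all_bad$reason, "short_trial")

  clean <- apply_exclusions(5, tr, no_sacc)
  expect_true(clean$kept)
  expect_equal(clean$reason, "none")
})

test_that("a blink just outside 300 ms of the press is harmless", {
  tr <- generate_trace(5, cfg = clean_cfg(), seed = 34)
  bl <- data.frame(start_ms = 4500, end_ms = 4699)
  expect_true(apply_exclusions(5, tr, NULL, blinks = bl)$kept)
})

test_that("immobilization time follows the 300-ms retention rule", {
  ev <- data.frame(offset_ms = c(1000, 4500))
  expect_equal(immobilization_time(5000, ev), 500)
  ev2 <- data.frame(offset_ms = 4800)
  expect_true(is.na(immobilization_time(5000, ev2)))
  expect_true(is.na(immobilization_time(5000, ev[0, , drop = FALSE])))
})

test_that("immobilization retention matches a brute-force scan", {
  ex <- generate_experiment(sim_config(n_participants = 3),
                            ground_truth(), seed = 35)
  d <- ex$trials
  imm <- vapply(seq_len(nrow(d)), function(i) {
    ev <- ex$events[[i]]
    immobilization_time(d$ft_s[i] * 1000,
                        data.frame(offset_ms = ev$onset_s * 1000 + 40))
  }, numeric(1))
  brute <- vapply(seq_len(nrow(d)), function(i) {
    ev <- ex$events[[i]]
    if (nrow(ev) == 0) return(NA_real_)
    gap <- d$ft_s[i] * 1000 - max(ev$onset_s * 1000 + 40)
    if (gap > 300) gap else NA_real_
  }, numeric(1))
  expect_identical(is.na(imm), is.na(brute))
  expect_equal(imm[!is.na(imm)], brute[!is.na(brute)])
})

test_that("summarize_trial assembles coherent metrics", {
  cfg <- sim_config(noise_sd = 0.01)
  ev <- data.frame(onset_s = c(1, 3, 5), amplitude_deg = c(0.3, 0.4, 0.5),
                   direction_deg = c(0, 120, 240))
  tr <- generate_trace(6, ev, cfg = cfg, seed = 36)
  det <- detect_microsaccades(tr)
  m <- summarize_trial(6, tr, det)
  expect_equal(m$ms_count, 3)
  expect_equal(m$ms_rate, 0.5)
  expect_equal(m$ms_presence, 1L)
  expect_equal(m$log_ft, log(6))
  expect_equal(m$num_blinks, 0)
  expect_false(m$excluded)
  expect_gt(m$immobilization_ms, 300)
  # last-event amplitude within detector accuracy
  expect_equal(m$ms_amplitude, 0.5, tolerance = 0.1)
})

test_that("event-free trials are flagged eligible for the quiet subset", {
  tr <- generate_trace(5, cfg = sim_config(), seed = 37)
  det <- detect_microsaccades(tr)
  m <- summarize_trial(5, tr, det)
  expect_equal(m$ms_presence, as.integer(m$ms_count > 0))
  if (m$ms_count == 0) {
    expect_true(is.na(m$immobilization_ms))
    expect_equal(m$ms_rate, 0)
  }
})

test_that("every trial gets exactly one exclusion reason", {
  ex <- generate_experiment(sim_config(n_participants = 2,
                                       trials_per_block = 6),
                            ground_truth(), seed = 38, emit_traces = TRUE)
  s <- summarize_trials(ex)
  expect_equal(nrow(s$metrics), nrow(ex$trials))
  expect_true(all(s$metrics$exclusion_reason %in%
                    c("none", "short_trial", "gaze_displacement",
                      "peri_press_blink", "peri_press_saccade")))
  expect_equal(s$metrics$excluded, s$metrics$exclusion_reason != "none")
})
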