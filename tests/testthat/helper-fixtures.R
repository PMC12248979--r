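# shared fixtures, built in code at test time

# a quiet configuration: no drift, no noise, no blinks
clean_cfg <- function(...) {
  sim_config(drift_diffusion = 0, noise_sd = 0, blink_rate = 0, ...)
}

# hand-built gaze trace from explicit binocular-mean coordinates
make_trace <- function(x, y, fs = 1000) {
  n <- length(x)
  tr <- data.frame(time_ms = (seq_len(n) - 1) * 1000 / fs,
                   lx_deg = x, ly_deg = y, rx_deg = x, ry_deg = y,
                   valid_l = 1L, valid_r = 1L)
  attr(tr, "sampling_rate") <- fs
  class(tr) <- c("gaze_trace", "data.frame")
  tr
}

# single-event helper
one_event <- function(onset_s, amplitude_deg, direction_deg = 30) {
  data.frame(onset_s = onset_s, amplitude_deg = amplitude_deg,
             direction_deg = direction_deg)
}

# ground truth with a single non-zero coefficient (plus intercept)
truth_only <- function(term = NULL, value = 0, intercept = 0.6,
                       residual_sd = 0.1, random_intercept_sd = 0,
                       random_slope_sd = 0) {
  fe <- default_ft_effects()
  fe[] <- 0
  fe["(Intercept)"] <- intercept
  if (!is.null(term)) fe[term] <- value
  ground_truth(fixed_effects = fe,
               random_intercept_sd = random_intercept_sd,
               random_slope_sd = random_slope_sd,
               residual_sd = residual_sd)
}
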