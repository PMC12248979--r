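#' Simulation configuration for a synthetic filling-in experiment
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design this package targets: 21 participants, 9 blocks crossing
#' three isoluminant color contrasts (DKL azimuth differences of 10, 20 and
#' 30 degrees from the central hue) with three boundary eccentricities
#' (2, 4, 6 deg), 40 main trials per block, binocular gaze sampled at
#' 1000 Hz, and a mean microsaccade rate of 0.89 Hz.
#'
#' @param n_participants Number of participants.
#' @param contrast_levels Color contrast levels (DKL azimuth difference, deg).
#' @param eccentricity_levels Boundary eccentricities (deg of visual angle).
#' @param trials_per_block Main trials per block.
#' @param sampling_rate Gaze sampling rate (Hz).
#' @param ms_rate Marginal microsaccade rate across trials (Hz).
#' @param p_no_ms Probability that a trial has suppressed microsaccades
#'   (no events at all). Kept exogenous to the outcome so that the
#'   microsaccade-presence covariate is unconfounded by construction.
#' @param drift_diffusion Ocular drift diffusion constant (deg^2/s); the
#'   drift is a conjugate two-dimensional random walk.
#' @param noise_sd Additive white positional noise per eye (arcmin/sample).
#' @param main_sequence_slope Peak velocity per unit amplitude for injected
#'   microsaccades ((deg/s)/deg).
#' @param amp_median Median injected amplitude (arcmin).
#' @param amp_sdlog Log-scale SD of the (truncated log-normal) amplitude
#'   distribution.
#' @param amp_range Truncation bounds for injected amplitudes (arcmin).
#' @param blink_rate Blink rate (Hz).
#' @param blink_duration Range of blink durations (s).
#' @param min_trial_s,max_trial_s Filling-in time bounds (s); outcomes are
#'   redrawn until they fall inside, mirroring the analysis-stage exclusion
#'   of trials shorter than 2 s.
#' @param ft_scale Scale constant (s) linking the generative log outcome to
#'   filling-in time in seconds: \code{ft_s = ft_scale * exp(log_ft)}. The
#'   default calibrates the mean filling-in time to roughly 7.5 s.
#' @param prepress_gap_s Width of the pre-report window (s) in which event
#'   placement is suppressed, emulating the microsaccade-rate dip that
#'   precedes the perceptual report. Set to 0 to disable.
#' @param seed Optional integer seed recorded in the configuration.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_participants = 21,
                       contrast_levels = c(10, 20, 30),
                       eccentricity_levels = c(2, 4, 6),
                       trials_per_block = 40,
                       sampling_rate = 1000,
                       ms_rate = 0.89,
                       p_no_ms = 0.10,
                       drift_diffusion = 0.001,
                       noise_sd = 0.05,
                       main_sequence_slope = 60,
                       amp_median = 20,
                       amp_sdlog = 0.7,
                       amp_range = c(3, 90),
                       blink_rate = 0.1,
                       blink_duration = c(0.1, 0.3),
                       min_trial_s = 2,
                       max_trial_s = 20,
                       ft_scale = 3.9,
                       prepress_gap_s = 0.6,
                       seed = NULL) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    contrast_levels = sort(contrast_levels),
    eccentricity_levels = sort(eccentricity_levels),
    trials_per_block = as.integer(trials_per_block),
    sampling_rate = sampling_rate,
    ms_rate = ms_rate,
    p_no_ms = p_no_ms,
    drift_diffusion = drift_diffusion,
    noise_sd = noise_sd,
    main_sequence_slope = main_sequence_slope,
    amp_median = amp_median,
    amp_sdlog = amp_sdlog,
    amp_range = amp_range,
    blink_rate = blink_rate,
    blink_duration = blink_duration,
    min_trial_s = min_trial_s,
    max_trial_s = max_trial_s,
    ft_scale = ft_scale,
    prepress_gap_s = prepress_gap_s,
    seed = seed
  )
  stopifnot(
    cfg$n_participants >= 1, cfg$trials_per_block >= 1,
    cfg$sampling_rate > 0, cfg$ms_rate >= 0,
    cfg$p_no_ms >= 0, cfg$p_no_ms < 1,
    cfg$drift_diffusion >= 0, cfg$noise_sd >= 0,
    cfg$main_sequence_slope > 0, cfg$blink_rate >= 0,
    cfg$min_trial_s > 0, cfg$max_trial_s > cfg$min_trial_s,
    cfg$ft_scale > 0, cfg$prepress_gap_s >= 0,
    length(cfg$amp_range) == 2, cfg$amp_range[1] < cfg$amp_range[2]
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Block design implied by a simulation configuration
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return Data frame with one row per block (block, contrast, eccentricity).
#' @export
block_design <- function(cfg) {
  g <- expand.grid(contrast = cfg$contrast_levels,
                   eccentricity = cfg$eccentricity_levels)
  data.frame(block = seq_len(nrow(g)), g)
}

#' Default fixed effects of the generative filling-in model
#'
#' Named coefficient vector (log filling-in time scale, standardized
#' predictors, microsaccade presence coded 0/1) used as the generator's
#' default ground truth for the primary outcome model. The values are the
#' published effect-size estimates this generator is calibrated to:
#' microsaccade presence and blink count delay filling-in, color contrast
#' delays it independently, and the eccentricity effect is carried almost
#' entirely by its interaction with microsaccade presence.
#'
#' @return Named numeric vector.
#' @export
default_ft_effects <- function() {
  c("(Intercept)" = 0.310,
    "contrast" = 0.115,
    "eccentricity" = -0.00939,
    "trial_num" = -0.101,
    "ms_presence" = 0.302,
    "num_blinks" = 0.265,
    "contrast:trial_num" = -0.0152,
    "contrast:ms_presence" = -0.00757,
    "eccentricity:ms_presence" = -0.0715,
    "contrast:num_blinks" = -0.0160,
    "eccentricity:num_blinks" = 0.0126)
}

#' Default fixed effects of the companion generative models
#'
#' Published effect-size estimates used as generator defaults for the
#' three companion analyses: the balanced microsaccade-trials subset model
#' of log filling-in time (\code{default_subset_ms_effects}), the log
#' microsaccade-rate model (\code{default_ms_rate_effects}) and the log
#' immobilization-time model (\code{default_immobilization_effects}).
#' All are on the standardized-predictor scale.
#'
#' @return Named numeric vector.
#' @export
default_subset_ms_effects <- function() {
  c("(Intercept)" = 0.498,
    "contrast" = 0.156,
    "eccentricity" = -0.0876,
    "trial_num" = -0.101,
    "ocular_drift" = 0.104)
}

#' @rdname default_subset_ms_effects
#' @export
default_ms_rate_effects <- function() {
  c("(Intercept)" = -0.0845,
    "contrast" = -0.000870,
    "eccentricity" = 0.0350,
    "trial_num" = 0.134)
}

#' @rdname default_subset_ms_effects
#' @export
default_immobilization_effects <- function() {
  c("(Intercept)" = -0.165,
    "contrast" = 0.0283,
    "eccentricity" = -0.0587,
    "ms_amplitude" = 0.0110,
    "trial_num" = -0.105)
}

#' Ground truth for a synthetic experiment
#'
#' Fixed-effect coefficients, per-participant random-effect SDs and the
#' residual SD that define the generative outcome model.
#'
#' @param fixed_effects Named coefficient vector; must contain
#'   \code{"(Intercept)"}. Interaction terms use the \code{"a:b"} naming of
#'   \code{\link[stats]{model.matrix}}.
#' @param random_terms Terms receiving per-participant random slopes
#'   (besides the always-present random intercept). Must be main effects
#'   named in \code{fixed_effects}.
#' @param random_intercept_sd,random_slope_sd SDs of the participant random
#'   intercept and slopes (log outcome units).
#' @param residual_sd Residual SD (log outcome units).
#' @return A list of class \code{"ground_truth"} with elements
#'   \code{fixed_effects}, \code{random_effect_sds} (named, including
#'   \code{"(Intercept)"}) and \code{residual_sd}.
#' @export
ground_truth <- function(fixed_effects = default_ft_effects(),
                         random_terms = c("contrast", "eccentricity",
                                          "trial_num", "ms_presence",
                                          "num_blinks"),
                         random_intercept_sd = 0.2,
                         random_slope_sd = 0.03,
                         residual_sd = 0.3) {
  stopifnot(residual_sd >= 0, random_intercept_sd >= 0,
            "(Intercept)" %in% names(fixed_effects))
  missing <- setdiff(random_terms, names(fixed_effects))
  if (length(missing) > 0)
    stop("random_terms not present among fixed_effects: ",
         paste(missing, collapse = ", "))
  re <- c(random_intercept_sd, rep_len(random_slope_sd, length(random_terms)))
  names(re) <- c("(Intercept)", random_terms)
  structure(list(fixed_effects = fixed_effects,
                 random_effect_sds = re,
                 residual_sd = residual_sd),
            class = "ground_truth")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic filling-in experiment configuration\n")
  cat(sprintf("  %d participants x %d blocks x %d trials, %g Hz sampling\n",
              x$n_participants,
              length(x$contrast_levels) * length(x$eccentricity_levels),
              x$trials_per_block, x$sampling_rate))
  cat(sprintf("  microsaccade rate %.3g Hz (P[no-ms trial] = %.2g), drift D = %g deg^2/s\n",
              x$ms_rate, x$p_no_ms, x$drift_diffusion))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Generative outcome model (log scale)\n  fixed effects:\n")
  print(round(x$fixed_effects, 4))
  cat("  random-effect SDs:\n")
  print(round(x$random_effect_sds, 3))
  cat(sprintf("  residual SD: %g\n", x$residual_sd))
  invisible(x)
}
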