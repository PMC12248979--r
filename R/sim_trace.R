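#' Microsaccade waveform duration and peak velocity
#'
#' For a raised-cosine velocity profile the displacement equals
#' \code{Vp * T / 2}, so requiring the main-sequence relation
#' \code{Vp = slope * A} fixes the duration at \code{T = 2 / slope}
#' independently of amplitude. A 10-ms floor is applied; when it binds
#' (slope > 200 (deg/s)/deg) the peak velocity is set by the displacement
#' integral instead.
#'
#' @param amplitude_deg Event amplitude (deg).
#' @param slope Main-sequence slope ((deg/s)/deg).
#' @return List with \code{duration_s} and \code{peak_vel} (deg/s).
#' @keywords internal
ms_waveform <- function(amplitude_deg, slope) {
  duration <- max(0.010, 2 / slope)
  list(duration_s = duration, peak_vel = 2 * amplitude_deg / duration)
}

#' Generate a binocular gaze trace for one trial
#'
#' Simulates fixational gaze as a conjugate two-dimensional random walk
#' (ocular drift) with injected ballistic microsaccades and blink gaps.
#' Each microsaccade follows a raised-cosine velocity profile whose peak
#' velocity obeys the main sequence (\code{peak = slope * amplitude});
#' both eyes receive identical drift and ballistic displacement plus
#' independent white positional noise. Samples inside blink intervals are
#' invalid and their positions undefined.
#'
#' @param duration_s Trace duration (s); must span at least one 31-ms
#'   velocity-estimation window.
#' @param ms_events \code{NULL} or a data frame with columns
#'   \code{onset_s}, \code{amplitude_deg}, \code{direction_deg}.
#' @param blink_intervals \code{NULL} or a data frame with columns
#'   \code{start_s}, \code{end_s}.
#' @param cfg A \code{\link{sim_config}} (sampling rate, drift, noise,
#'   main-sequence slope).
#' @param seed Optional integer seed; the seed and inputs fully determine
#'   the trace.
#' @return A data frame of class \code{"gaze_trace"} with columns
#'   \code{time_ms}, \code{lx_deg}, \code{ly_deg}, \code{rx_deg},
#'   \code{ry_deg}, \code{valid_l}, \code{valid_r} and attribute
#'   \code{sampling_rate}.
#' @export
generate_trace <- function(duration_s, ms_events = NULL,
                           blink_intervals = NULL,
                           cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (duration_s < 0.031) stop("trace shorter than one velocity window")
  fs <- cfg$sampling_rate
  dt <- 1 / fs
  n <- round(duration_s * fs)
  time_ms <- (seq_len(n) - 1) * 1000 / fs

  if (!is.null(ms_events) && nrow(ms_events) > 0) {
    wf <- ms_waveform(1, cfg$main_sequence_slope) # duration is amplitude-free
    ev <- ms_events[order(ms_events$onset_s), , drop = FALSE]
    if (any(ev$onset_s < 0) || any(ev$onset_s + wf$duration_s > duration_s))
      stop("injected events fall outside [0, duration_s]")
    if (nrow(ev) > 1 &&
        any(diff(ev$onset_s) < wf$duration_s))
      stop("injected events overlap")
  } else {
    ev <- NULL
  }

  # conjugate drift: Brownian increments with variance D * dt per axis
  step_sd <- sqrt(cfg$drift_diffusion * dt)
  drift_x <- cumsum(stats::rnorm(n, sd = step_sd))
  drift_y <- cumsum(stats::rnorm(n, sd = step_sd))

  sacc_x <- numeric(n)
  sacc_y <- numeric(n)
  if (!is.null(ev)) {
    t_s <- time_ms / 1000
    for (i in seq_len(nrow(ev))) {
      A <- ev$amplitude_deg[i]
      wf <- ms_waveform(A, cfg$main_sequence_slope)
      Tt <- wf$duration_s
      tau <- pmin(pmax(t_s - ev$onset_s[i], 0), Tt)
      # integral of the raised-cosine velocity profile
      d <- wf$peak_vel * (tau / 2 - Tt * sin(2 * pi * tau / Tt) / (4 * pi))
      th <- ev$direction_deg[i] * pi / 180
      sacc_x <- sacc_x + d * cos(th)
      sacc_y <- sacc_y + d * sin(th)
    }
  }

  noise_deg <- cfg$noise_sd / 60
  base_x <- drift_x + sacc_x
  base_y <- drift_y + sacc_y
  trace <- data.frame(
    time_ms = time_ms,
    lx_deg = base_x + stats::rnorm(n, sd = noise_deg),
    ly_deg = base_y + stats::rnorm(n, sd = noise_deg),
    rx_deg = base_x + stats::rnorm(n, sd = noise_deg),
    ry_deg = base_y + stats::rnorm(n, sd = noise_deg),
    valid_l = 1L,
    valid_r = 1L
  )

  if (!is.null(blink_intervals) && nrow(blink_intervals) > 0) {
    for (i in seq_len(nrow(blink_intervals))) {
      idx <- trace$time_ms >= blink_intervals$start_s[i] * 1000 &
        trace$time_ms <= blink_intervals$end_s[i] * 1000
      trace[idx, c("lx_deg", "ly_deg", "rx_deg", "ry_deg")] <- NA_real_
      trace$valid_l[idx] <- 0L
      trace$valid_r[idx] <- 0L
    }
  }

  attr(trace, "sampling_rate") <- fs
  class(trace) <- c("gaze_trace", "data.frame")
  trace
}

#' Blink intervals recorded in a gaze trace
#'
#' Reconstructs invalid-sample runs (either eye) as blink intervals.
#'
#' @param trace A \code{"gaze_trace"}.
#' @return Data frame with columns \code{start_ms}, \code{end_ms}
#'   (possibly zero rows).
#' @export
trace_blinks <- function(trace) {
  invalid <- trace$valid_l == 0L | trace$valid_r == 0L
  r <- rle(invalid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start_ms = trace$time_ms[starts[keep]],
             end_ms = trace$time_ms[ends[keep]])
}
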