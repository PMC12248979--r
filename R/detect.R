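#' Detection parameters for the velocity-threshold microsaccade detector
#'
#' @param velocity_window Sliding-window length for the velocity estimate
#'   (ms); must span an odd number (at least 3) of samples.
#' @param lambda Noise-threshold multiplier applied to the robust velocity
#'   scale (dimensionless). Participants whose noise floor blurs into the
#'   event distribution are conventionally reassigned 6.
#' @param min_duration Minimum number of consecutive suprathreshold
#'   samples forming an event.
#' @param merge_gap Events separated by less than this gap (ms) are merged.
#' @param max_direction_change Maximum movement-direction change between
#'   successive samples (deg per ms); events exceeding it are discarded as
#'   artifacts.
#' @param min_speed_for_direction Binocular speed (deg/s) below which the
#'   movement direction is treated as undefined.
#' @param amp_min Minimum amplitude (arcmin); smaller displacements count
#'   as ocular drift or noise.
#' @param amp_max Maximum amplitude (deg); larger events are classified as
#'   large saccades and returned separately.
#' @param blink_pad Samples within this margin (ms) of an invalid (blink)
#'   interval are excluded from velocity estimation and detection.
#' @return List of class \code{"detection_params"}.
#' @export
detection_params <- function(velocity_window = 31, lambda = 5,
                             min_duration = 8, merge_gap = 12,
                             max_direction_change = 15,
                             min_speed_for_direction = 0.5,
                             amp_min = 3, amp_max = 2, blink_pad = 150) {
  p <- list(velocity_window = velocity_window, lambda = lambda,
            min_duration = as.integer(min_duration), merge_gap = merge_gap,
            max_direction_change = max_direction_change,
            min_speed_for_direction = min_speed_for_direction,
            amp_min = amp_min, amp_max = amp_max, blink_pad = blink_pad)
  stopifnot(p$lambda > 0, p$min_duration >= 1, p$merge_gap >= 0,
            p$amp_min / 60 < p$amp_max, p$velocity_window > 0,
            p$blink_pad >= 0)
  class(p) <- "detection_params"
  p
}

# expand a logical mask by pad_samples on each side
expand_mask <- function(mask, pad_samples) {
  if (pad_samples <= 0 || !any(mask)) return(mask)
  idx <- which(mask)
  lo <- pmax(idx - pad_samples, 1L)
  hi <- pmin(idx + pad_samples, length(mask))
  out <- logical(length(mask))
  for (k in seq_along(idx)) out[lo[k]:hi[k]] <- TRUE
  out
}

# centered least-squares slope filter: slope at n = sum(k * x[n+k]) / (S2*dt)
regression_slope <- function(x, half, dt) {
  k <- -half:half
  s2 <- sum(k^2)
  # stats::filter computes sum(f[j] * x[i + half + 1 - j]); reversing the
  # weights yields sum(k * x[i + k])
  as.numeric(stats::filter(x, rev(k / (s2 * dt)), sides = 2))
}

#' Per-eye gaze velocity by centered windowed regression
#'
#' The velocity at each sample is the slope of a centered least-squares
#' linear fit of position over a sliding window, per eye and axis. Samples
#' whose window overlaps an invalid (blink) region, or that lie within
#' \code{blink_pad} ms of one, are undefined (\code{NA}).
#'
#' @param trace A \code{"gaze_trace"}.
#' @param window_ms Window length (ms); must span at least 3 samples.
#' @param blink_pad Margin around invalid samples (ms).
#' @return Data frame of class \code{"gaze_velocity"}: \code{time_ms},
#'   \code{vlx}, \code{vly}, \code{vrx}, \code{vry} (deg/s), with the
#'   trace's sampling rate as an attribute.
#' @export
compute_velocity <- function(trace, window_ms = 31, blink_pad = 150) {
  fs <- attr(trace, "sampling_rate")
  if (is.null(fs)) stop("trace has no sampling_rate attribute")
  w <- round(window_ms * fs / 1000)
  if (w %% 2 == 0) w <- w + 1
  if (w < 3) stop("velocity window spans fewer than 3 samples")
  if (nrow(trace) < w) stop("trace shorter than one velocity window")
  half <- (w - 1) %/% 2
  dt <- 1 / fs
  pad <- round(blink_pad * fs / 1000)

  vel <- data.frame(
    time_ms = trace$time_ms,
    vlx = regression_slope(trace$lx_deg, half, dt),
    vly = regression_slope(trace$ly_deg, half, dt),
    vrx = regression_slope(trace$rx_deg, half, dt),
    vry = regression_slope(trace$ry_deg, half, dt)
  )
  bad_l <- expand_mask(trace$valid_l == 0L, pad)
  bad_r <- expand_mask(trace$valid_r == 0L, pad)
  vel$vlx[bad_l] <- NA_real_
  vel$vly[bad_l] <- NA_real_
  vel$vrx[bad_r] <- NA_real_
  vel$vry[bad_r] <- NA_real_
  attr(vel, "sampling_rate") <- fs
  class(vel) <- c("gaze_velocity", "data.frame")
  vel
}

#' Robust per-axis velocity thresholds
#'
#' The noise scale per eye and axis is the median-based estimator
#' \code{sigma = sqrt(median(v^2) - median(v)^2)} over defined samples;
#' the detection threshold is \code{eta = lambda * sigma}.
#'
#' @param vel A \code{"gaze_velocity"}.
#' @param lambda Noise-threshold multiplier.
#' @return List with \code{sigma} and \code{eta}, each a named vector over
#'   \code{c("vlx", "vly", "vrx", "vry")}, and \code{lambda}.
#' @export
estimate_threshold <- function(vel, lambda = 5) {
  axes <- c("vlx", "vly", "vrx", "vry")
  sigma <- vapply(axes, function(a) {
    v <- vel[[a]]
    v <- v[!is.na(v)]
    if (length(v) < 100)
      stop("fewer than 100 defined velocity samples on axis ", a)
    sqrt(stats::median(v^2) - stats::median(v)^2)
  }, numeric(1))
  if (any(sigma <= 0))
    stop("degenerate velocity distribution (zero noise scale); ",
         "trace unusable for threshold estimation")
  list(sigma = sigma, eta = lambda * sigma, lambda = lambda)
}

# merge candidate events closer than gap_samples; returns matrix cols on/off
merge_events <- function(onoff, gap_samples) {
  if (nrow(onoff) <= 1) return(onoff)
  out <- onoff[1, , drop = FALSE]
  for (i in 2:nrow(onoff)) {
    if (onoff[i, 1] - out[nrow(out), 2] < gap_samples)
      out[nrow(out), 2] <- onoff[i, 2]
    else
      out <- rbind(out, onoff[i, , drop = FALSE])
  }
  out
}

#' Detect binocular microsaccades in a gaze trace
#'
#' Implements a refined velocity-threshold detector: an elliptic criterion
#' \code{(vx/eta_x)^2 + (vy/eta_y)^2 > 1} must hold simultaneously in both
#' eyes for at least \code{min_duration} consecutive samples; nearby events
#' are merged; events with erratic direction changes are discarded;
#' amplitudes outside \code{[amp_min, amp_max]} are dropped (below: drift
#' or noise) or classified as large saccades (above), which are returned
#' separately so exclusion logic can use them.
#'
#' Amplitude is the per-axis max-minus-min bounding-box norm of the
#' binocular mean trajectory within the event; peak velocity is the
#' maximum binocular mean speed; direction is the angle of the net
#' displacement.
#'
#' @param trace A \code{"gaze_trace"}.
#' @param params A \code{\link{detection_params}}.
#' @return List of class \code{"ms_detection"}: \code{events} and
#'   \code{large_saccades} (data frames with \code{onset_ms},
#'   \code{offset_ms}, \code{duration_ms}, \code{amplitude_deg},
#'   \code{peak_vel_deg_s}, \code{direction_deg}), \code{thresholds},
#'   \code{n_discarded_direction}.
#' @export
detect_microsaccades <- function(trace, params = detection_params()) {
  fs <- attr(trace, "sampling_rate")
  vel <- compute_velocity(trace, params$velocity_window, params$blink_pad)
  th <- estimate_threshold(vel, params$lambda)
  eta <- th$eta

  crit_l <- (vel$vlx / eta["vlx"])^2 + (vel$vly / eta["vly"])^2 > 1
  crit_r <- (vel$vrx / eta["vrx"])^2 + (vel$vry / eta["vry"])^2 > 1
  cand <- !is.na(crit_l) & !is.na(crit_r) & crit_l & crit_r

  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= params$min_duration
  if (!any(keep)) {
    empty <- empty_events()
    return(structure(list(events = empty, large_saccades = empty,
                          thresholds = th, n_discarded_direction = 0L),
                     class = "ms_detection"))
  }
  onoff <- cbind(starts[keep], ends[keep])
  gap_samples <- params$merge_gap * fs / 1000
  onoff <- merge_events(onoff, gap_samples)

  mx <- (trace$lx_deg + trace$rx_deg) / 2
  my <- (trace$ly_deg + trace$ry_deg) / 2
  vmx <- (vel$vlx + vel$vrx) / 2
  vmy <- (vel$vly + vel$vry) / 2
  speed <- sqrt(vmx^2 + vmy^2)

  bad_pad <- expand_mask(trace$valid_l == 0L | trace$valid_r == 0L,
                         round(params$blink_pad * fs / 1000))
  ms_per_sample <- 1000 / fs

  rows <- list()
  large <- list()
  n_dir <- 0L
  for (i in seq_len(nrow(onoff))) {
    i1 <- onoff[i, 1]
    i2 <- onoff[i, 2]
    if (any(bad_pad[i1:i2])) next
    # direction-change artifact test on the binocular mean velocity
    sp <- speed[i1:i2]
    dir <- atan2(vmy[i1:i2], vmx[i1:i2]) * 180 / pi
    defined <- !is.na(sp) & sp >= params$min_speed_for_direction
    if (sum(defined) >= 2) {
      dd <- diff(dir[defined])
      dd <- (dd + 180) %% 360 - 180
      # successive defined samples only
      gap1 <- diff(which(defined)) == 1
      if (any(abs(dd[gap1]) / ms_per_sample > params$max_direction_change)) {
        n_dir <- n_dir + 1L
        next
      }
    }
    # refine onset/offset: the smoothed velocity exceeds threshold ahead of
    # the movement, so trim the run to where the binocular speed reaches a
    # fixed fraction of the event peak (unbiased for the ballistic profile);
    # never shrink below the minimum duration
    pk_sp <- max(sp, na.rm = TRUE)
    above <- which(!is.na(sp) & sp >= 0.2 * pk_sp)
    if (length(above) > 0 &&
        above[length(above)] - above[1] + 1 >= params$min_duration) {
      i2 <- i1 + above[length(above)] - 1
      i1 <- i1 + above[1] - 1
    }
    amp <- sqrt(diff(range(mx[i1:i2]))^2 + diff(range(my[i1:i2]))^2)
    if (amp < params$amp_min / 60) next
    row <- data.frame(
      onset_ms = trace$time_ms[i1],
      offset_ms = trace$time_ms[i2],
      duration_ms = trace$time_ms[i2] - trace$time_ms[i1] + ms_per_sample,
      amplitude_deg = amp,
      peak_vel_deg_s = max(sp, na.rm = TRUE),
      direction_deg = atan2(my[i2] - my[i1], mx[i2] - mx[i1]) * 180 / pi
    )
    if (amp > params$amp_max) large[[length(large) + 1]] <- row
    else rows[[length(rows) + 1]] <- row
  }
  bind_or_empty <- function(lst)
    if (length(lst) > 0) do.call(rbind, lst) else empty_events()
  structure(list(events = bind_or_empty(rows),
                 large_saccades = bind_or_empty(large),
                 thresholds = th,
                 n_discarded_direction = n_dir),
            class = "ms_detection")
}

empty_events <- function() {
  data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
             duration_ms = numeric(0), amplitude_deg = numeric(0),
             peak_vel_deg_s = numeric(0), direction_deg = numeric(0))
}

#' Main-sequence fit of detected microsaccades
#'
#' Least-squares fit of log peak velocity against log amplitude, the
#' classic amplitude--peak-velocity relationship of saccadic events.
#'
#' @param events Event data frame with \code{amplitude_deg} and
#'   \code{peak_vel_deg_s}; at least 10 events required.
#' @return List with \code{slope}, \code{intercept} (log-log scale) and
#'   Pearson \code{correlation}.
#' @export
main_sequence <- function(events) {
  if (nrow(events) < 10)
    stop("main_sequence requires at least 10 events")
  la <- log(events$amplitude_deg)
  lv <- log(events$peak_vel_deg_s)
  fit <- stats::lm(lv ~ la)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       correlation = stats::cor(la, lv))
}
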