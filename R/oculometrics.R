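#' Ocular drift speed by the retinal-slip grid method
#'
#' Divides visual space into a fine grid (default 0.01 deg, roughly one
#' cone receptive field) and, for each 50-ms segment free of microsaccades
#' (with a 10-ms guard margin) and invalid samples, counts the distinct
#' grid squares entered by the binocular mean gaze path. The count is
#' converted to a traversal speed as \code{(count - 1) * grid_deg /
#' segment duration}, so a stationary eye scores exactly 0; the trial
#' value is the mean over valid segments.
#'
#' @param trace A \code{"gaze_trace"}.
#' @param events Detected (or true) event table with \code{onset_ms},
#'   \code{offset_ms}; used to mask microsaccadic motion.
#' @param grid_deg Grid square side (deg).
#' @param segment_ms Segment length (ms).
#' @param pad_ms Guard margin around each event (ms).
#' @return Mean drift speed (deg/s), \code{NA} if no valid segment; the
#'   number of valid segments is attached as attribute
#'   \code{"n_segments"}.
#' @export
retinal_slip <- function(trace, events = NULL, grid_deg = 0.01,
                         segment_ms = 50, pad_ms = 10) {
  fs <- attr(trace, "sampling_rate")
  n <- nrow(trace)
  seg_len <- round(segment_ms * fs / 1000)

  masked <- trace$valid_l == 0L | trace$valid_r == 0L
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      idx <- trace$time_ms >= events$onset_ms[i] - pad_ms &
        trace$time_ms <= events$offset_ms[i] + pad_ms
      masked[idx] <- TRUE
    }
  }
  mx <- (trace$lx_deg + trace$rx_deg) / 2
  my <- (trace$ly_deg + trace$ry_deg) / 2
  gx <- floor(mx / grid_deg)
  gy <- floor(my / grid_deg)

  n_seg <- n %/% seg_len
  speeds <- rep(NA_real_, n_seg)
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1) * seg_len + 1):(s * seg_len)
    if (any(masked[idx])) next
    squares <- length(unique(paste(gx[idx], gy[idx])))
    speeds[s] <- (squares - 1) * grid_deg / (seg_len / fs)
  }
  ok <- !is.na(speeds)
  out <- if (any(ok)) mean(speeds[ok]) else NA_real_
  attr(out, "n_segments") <- sum(ok)
  out
}

#' Trial exclusion rules
#'
#' A trial is excluded if (in this fixed order of precedence) its
#' filling-in time is below 2 s, its median binocular gaze displacement
#' from the fixation point exceeds 1 deg, a blink overlaps the 300 ms
#' before the report, or a large saccade does. Exactly one reason (or
#' \code{"none"}) is assigned.
#'
#' @param ft_s Filling-in time (s); the report occurs at the trace end.
#' @param trace A \code{"gaze_trace"}.
#' @param large_saccades Large-saccade table (\code{onset_ms},
#'   \code{offset_ms}); may have zero rows.
#' @param blinks Blink table (\code{start_ms}, \code{end_ms}); defaults to
#'   the intervals recorded in the trace.
#' @param min_ft_s Minimum filling-in time (s).
#' @param max_displacement Median-displacement limit (deg).
#' @param peri_press_ms Pre-report window checked for blinks and large
#'   saccades (ms).
#' @param fixation Fixation-point coordinates (deg).
#' @return List with \code{kept} (logical) and \code{reason} (one of
#'   \code{"none"}, \code{"short_trial"}, \code{"gaze_displacement"},
#'   \code{"peri_press_blink"}, \code{"peri_press_saccade"}).
#' @export
apply_exclusions <- function(ft_s, trace, large_saccades = NULL,
                             blinks = NULL, min_ft_s = 2,
                             max_displacement = 1, peri_press_ms = 300,
                             fixation = c(0, 0)) {
  if (is.null(trace)) stop("trace required for exclusion evaluation")
  if (is.null(blinks)) blinks <- trace_blinks(trace)
  press_ms <- ft_s * 1000
  win_lo <- press_ms - peri_press_ms

  reason <- "none"
  if (ft_s < min_ft_s) {
    reason <- "short_trial"
  } else {
    mx <- (trace$lx_deg + trace$rx_deg) / 2
    my <- (trace$ly_deg + trace$ry_deg) / 2
    disp <- sqrt((mx - fixation[1])^2 + (my - fixation[2])^2)
    med <- stats::median(disp, na.rm = TRUE)
    overlaps <- function(a_start, a_end)
      length(a_start) > 0 && any(a_end >= win_lo & a_start <= press_ms)
    if (is.finite(med) && med > max_displacement)
      reason <- "gaze_displacement"
    else if (overlaps(blinks$start_ms, blinks$end_ms))
      reason <- "peri_press_blink"
    else if (!is.null(large_saccades) &&
             overlaps(large_saccades$onset_ms, large_saccades$offset_ms))
      reason <- "peri_press_saccade"
  }
  list(kept = reason == "none", reason = reason)
}

#' Immobilization time of a trial
#'
#' Time from the offset of the last microsaccade to the perceptual report,
#' retained only when it exceeds 300 ms (shorter gaps may reflect eye
#' movements tied to the motor response rather than perception).
#'
#' @param press_ms Report time (ms from trial onset).
#' @param events Event table with \code{offset_ms}; may have zero rows.
#' @param min_gap_ms Retention threshold (ms).
#' @return Immobilization time (ms) or \code{NA} if no events occurred or
#'   the last event ended within \code{min_gap_ms} of the report.
#' @export
immobilization_time <- function(press_ms, events, min_gap_ms = 300) {
  if (is.null(events) || nrow(events) == 0) return(NA_real_)
  gap <- press_ms - max(events$offset_ms)
  if (gap > min_gap_ms) gap else NA_real_
}

#' Assemble trial-level metrics
#'
#' Combines a trial's filling-in time, detected events, large saccades and
#' blinks into the per-trial quantities the statistical models consume.
#'
#' @param ft_s Filling-in time (s).
#' @param trace A \code{"gaze_trace"}.
#' @param detection A \code{"ms_detection"} (or a list with \code{events}
#'   and \code{large_saccades} tables).
#' @param blinks Optional blink table; defaults to the trace's invalid
#'   intervals.
#' @return One-row data frame: \code{ft_s}, \code{log_ft},
#'   \code{ms_presence}, \code{ms_count}, \code{ms_rate},
#'   \code{ms_amplitude} (last event, deg), \code{num_blinks},
#'   \code{ocular_drift} (deg/s), \code{immobilization_ms},
#'   \code{excluded}, \code{exclusion_reason}.
#' @export
summarize_trial <- function(ft_s, trace, detection, blinks = NULL) {
  if (is.null(blinks)) blinks <- trace_blinks(trace)
  ev <- detection$events
  excl <- apply_exclusions(ft_s, trace, detection$large_saccades, blinks)
  drift <- retinal_slip(trace, ev)
  data.frame(
    ft_s = ft_s,
    log_ft = log(ft_s),
    ms_presence = as.integer(nrow(ev) > 0),
    ms_count = nrow(ev),
    ms_rate = nrow(ev) / ft_s,
    ms_amplitude = if (nrow(ev) > 0) ev$amplitude_deg[nrow(ev)] else NA_real_,
    num_blinks = nrow(blinks),
    ocular_drift = as.numeric(drift),
    immobilization_ms = immobilization_time(ft_s * 1000, ev),
    excluded = !excl$kept,
    exclusion_reason = excl$reason,
    stringsAsFactors = FALSE
  )
}

#' Trial metrics for a whole (synthetic or imported) experiment
#'
#' Runs detection and \code{\link{summarize_trial}} over every trial of an
#' experiment with traces, carrying the trial identifiers along.
#'
#' @param experiment An \code{"ff_experiment"} with traces, or a list with
#'   \code{trials} (data frame) and \code{traces} (list).
#' @param params A \code{\link{detection_params}}.
#' @param lambda_overrides Optional named vector of per-participant noise
#'   multipliers overriding \code{params$lambda}.
#' @return List with \code{metrics} (one row per trial: identifiers,
#'   condition columns and the \code{\link{summarize_trial}} fields) and
#'   \code{events} (detected events of all trials with identifiers).
#' @export
summarize_trials <- function(experiment, params = detection_params(),
                             lambda_overrides = NULL) {
  trials <- experiment$trials
  traces <- experiment$traces
  if (is.null(traces)) stop("experiment carries no traces")
  met <- vector("list", nrow(trials))
  evs <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    p <- params
    pid <- as.character(trials$participant[i])
    if (!is.null(lambda_overrides) && pid %in% names(lambda_overrides))
      p$lambda <- lambda_overrides[[pid]]
    det <- detect_microsaccades(traces[[i]], p)
    m <- summarize_trial(trials$ft_s[i], traces[[i]], det)
    id <- trials[i, intersect(c("participant", "block", "trial_num",
                                "contrast", "eccentricity", "trial_type"),
                              names(trials)), drop = FALSE]
    met[[i]] <- cbind(id, m, row.names = NULL)
    if (nrow(det$events) > 0)
      evs[[i]] <- cbind(id[rep(1, nrow(det$events)),
                           c("participant", "block", "trial_num"),
                           drop = FALSE],
                        det$events, row.names = NULL)
  }
  list(metrics = do.call(rbind, met),
       events = if (length(ev <- Filter(Negate(is.null), evs)) > 0)
         do.call(rbind, ev) else NULL)
}
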