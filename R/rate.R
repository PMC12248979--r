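#' Causal rate kernel
#'
#' One-sided smoothing kernel \code{w(tau) = alpha^2 * tau * exp(-alpha *
#' tau)} evaluated on a 1-ms grid over \code{[0, window_ms)}, normalized
#' so its discrete integral equals 1. Because the kernel is zero for
#' negative lags, the rate estimate at time t depends only on events at or
#' before t.
#'
#' @param window_ms Kernel support (ms).
#' @param alpha Decay parameter (per ms).
#' @return Numeric vector of length \code{window_ms}, per-ms units.
#' @export
causal_kernel <- function(window_ms = 1001, alpha = 1 / 100) {
  stopifnot(window_ms > 0, alpha > 0)
  tau <- seq_len(window_ms) - 1
  w <- alpha^2 * tau * exp(-alpha * tau)
  w / sum(w)
}

#' Report-aligned microsaccade rate with a causal kernel
#'
#' Convolves report-aligned event onsets with the causal kernel and
#' normalizes at each time point by the number of trials long enough to
#' cover that point, so short trials do not bias the curve edges.
#' The baseline is the mean rate over \code{[-5000, -3000]} ms before the
#' report.
#'
#' @param onsets_by_trial List (one element per trial) of event onset
#'   times in ms relative to the report (report = 0, onsets are
#'   non-positive for events before it). Trials with peri-report blinks or
#'   large saccades should be removed beforehand.
#' @param durations_ms Trial durations (ms); a trial contributes to the
#'   denominator at time t only if \code{t >= -duration}.
#' @param window_ms,alpha Kernel parameters.
#' @param t_min,t_max Grid limits (ms relative to report), 1-ms steps.
#' @return Data frame of class \code{"rate_curve"}: \code{time_ms},
#'   \code{rate_hz}, \code{n_trials}; baseline rate (Hz) as attribute
#'   \code{"baseline"}.
#' @export
causal_rate <- function(onsets_by_trial, durations_ms,
                        window_ms = 1001, alpha = 1 / 100,
                        t_min = -7000, t_max = 0) {
  n_trials <- length(onsets_by_trial)
  if (n_trials == 0) stop("empty trial set")
  stopifnot(length(durations_ms) == n_trials)
  kern <- causal_kernel(window_ms, alpha)
  grid <- seq(t_min, t_max)
  num <- numeric(length(grid))
  for (i in seq_len(n_trials)) {
    for (o in onsets_by_trial[[i]]) {
      # kernel support: t in [o, o + window_ms)
      j0 <- max(ceiling(o), t_min)
      j1 <- min(floor(o) + window_ms - 1, t_max)
      if (j1 < j0) next
      idx <- (j0 - t_min + 1):(j1 - t_min + 1)
      num[idx] <- num[idx] + kern[(j0 - floor(o) + 1):(j1 - floor(o) + 1)]
    }
  }
  denom <- vapply(grid, function(t) sum(durations_ms >= -t), numeric(1))
  rate <- ifelse(denom > 0, 1000 * num / denom, NA_real_)
  out <- data.frame(time_ms = grid, rate_hz = rate, n_trials = denom)
  base_idx <- grid >= -5000 & grid <= -3000
  attr(out, "baseline") <- mean(rate[base_idx], na.rm = TRUE)
  class(out) <- c("rate_curve", "data.frame")
  out
}

#' Normalize rate curves to a common baseline
#'
#' Scales each participant's curve multiplicatively so its baseline rate
#' (mean over the -5 to -3 s pre-report window) equals the grand mean
#' baseline across participants; the grand mean of the scaled baselines
#' equals the original grand mean. Participants with an undefined or zero
#' baseline are omitted (with a warning) since no multiplicative scale can
#' place them on the common baseline.
#'
#' @param curves Named list of \code{"rate_curve"} objects, one per
#'   participant.
#' @return List with \code{curves} (scaled), \code{grand_baseline} (Hz)
#'   and \code{omitted} (participant names).
#' @export
baseline_normalize <- function(curves) {
  base <- vapply(curves, function(cv) attr(cv, "baseline"), numeric(1))
  usable <- is.finite(base) & base > 0
  if (!any(usable)) stop("no participant has a positive baseline")
  if (any(!usable))
    warning("omitting participants with zero/undefined baseline: ",
            paste(names(curves)[!usable], collapse = ", "))
  grand <- mean(base[usable])
  scaled <- curves[usable]
  for (k in seq_along(scaled)) {
    f <- grand / base[usable][k]
    scaled[[k]]$rate_hz <- scaled[[k]]$rate_hz * f
    attr(scaled[[k]], "baseline") <- grand
  }
  list(curves = scaled, grand_baseline = grand,
       omitted = names(curves)[!usable])
}

#' Pool trial event onsets relative to the report
#'
#' Convenience helper turning an experiment's event lists (onsets in
#' seconds from trial start) into report-aligned onset vectors in ms.
#'
#' @param events_by_trial List of event tables with \code{onset_s}.
#' @param ft_s Filling-in times (s), one per trial.
#' @return List of numeric vectors (ms relative to the report).
#' @export
align_onsets_to_press <- function(events_by_trial, ft_s) {
  stopifnot(length(events_by_trial) == length(ft_s))
  lapply(seq_along(ft_s), function(i) {
    ev <- events_by_trial[[i]]
    if (is.null(ev) || nrow(ev) == 0) numeric(0)
    else (ev$onset_s - ft_s[i]) * 1000
  })
}
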