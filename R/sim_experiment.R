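#' Trial design skeleton for direct outcome simulation
#'
#' Builds the crossed participant x block x trial design and draws the
#' trial-level covariates that are measured (rather than manipulated) in a
#' real experiment: ocular drift, last-microsaccade amplitude, blink count
#' and microsaccade presence. Used by the parameter-recovery simulations
#' that generate model outcomes directly from a coefficient vector without
#' synthesizing gaze traces.
#'
#' @param n_participants Number of participants.
#' @param trials_per_participant Trials kept per participant; when smaller
#'   than the full design (9 blocks x \code{trials_per_block}) a random
#'   subset of rows is kept.
#' @param cfg A \code{\link{sim_config}} providing design levels and rates.
#' @param seed Optional integer seed.
#' @return Data frame with columns \code{participant}, \code{block},
#'   \code{trial_num}, \code{contrast}, \code{eccentricity},
#'   \code{ms_presence}, \code{num_blinks}, \code{ocular_drift},
#'   \code{ms_amplitude}.
#' @export
simulate_design <- function(n_participants = 21,
                            trials_per_participant = NULL,
                            cfg = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- block_design(cfg)
  one <- merge(blocks, data.frame(trial_num = seq_len(cfg$trials_per_block)))
  ids <- sprintf("P%02d", seq_len(n_participants))
  design <- do.call(rbind, lapply(ids, function(id) {
    d <- one
    if (!is.null(trials_per_participant) &&
        trials_per_participant < nrow(one))
      d <- d[sort(sample.int(nrow(one), trials_per_participant)), ,
             drop = FALSE]
    d$participant <- id
    d
  }))
  rownames(design) <- NULL
  n <- nrow(design)
  design$ms_presence <- as.integer(stats::runif(n) >= cfg$p_no_ms)
  design$num_blinks <- stats::rpois(n, cfg$blink_rate * 7)
  design$ocular_drift <- pmax(0.1, stats::rnorm(n, 0.75, 0.15))
  design$ms_amplitude <- draw_amplitudes(n, cfg)
  design[c("participant", "block", "trial_num", "contrast", "eccentricity",
           "ms_presence", "num_blinks", "ocular_drift", "ms_amplitude")]
}

# truncated log-normal microsaccade amplitudes, in degrees
draw_amplitudes <- function(n, cfg) {
  a <- stats::rlnorm(n, meanlog = log(cfg$amp_median), sdlog = cfg$amp_sdlog)
  bad <- a < cfg$amp_range[1] | a > cfg$amp_range[2]
  while (any(bad)) {
    a[bad] <- stats::rlnorm(sum(bad), meanlog = log(cfg$amp_median),
                            sdlog = cfg$amp_sdlog)
    bad <- a < cfg$amp_range[1] | a > cfg$amp_range[2]
  }
  a / 60
}

# continuous covariates eligible for standardization
continuous_predictors <- function() {
  c("contrast", "eccentricity", "trial_num", "num_blinks",
    "ocular_drift", "ms_amplitude")
}

# variables appearing in a vector of term labels ("a", "a:b", ...)
term_variables <- function(terms) {
  unique(unlist(strsplit(setdiff(terms, "(Intercept)"), ":", fixed = TRUE)))
}

# fixed-effects design matrix for named coefficients; errors name any
# coefficient without a matching column. Interaction labels match on the
# unordered variable set ("a:b" == "b:a") since model.matrix canonicalizes
# interaction column names.
truth_design_matrix <- function(data, fixed_effects) {
  terms <- setdiff(names(fixed_effects), "(Intercept)")
  X <- stats::model.matrix(stats::reformulate(terms, intercept = TRUE), data)
  pos <- match_terms(names(fixed_effects), colnames(X))
  if (anyNA(pos))
    stop("ground-truth coefficients without a design column: ",
         paste(names(fixed_effects)[is.na(pos)], collapse = ", "))
  X <- X[, pos, drop = FALSE]
  colnames(X) <- names(fixed_effects)
  X
}

# match term labels against a vector of labels, order-insensitively for
# interaction components
match_terms <- function(wanted, have) {
  key <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                            function(p) paste(sort(p), collapse = ":"),
                            character(1))
  match(key(wanted), key(have))
}

#' Look up a coefficient by term label
#'
#' Interaction labels match irrespective of component order
#' (\code{"a:b"} finds \code{"b:a"}).
#'
#' @param estimates Named coefficient vector.
#' @param term Term label.
#' @return The coefficient value.
#' @export
coef_lookup <- function(estimates, term) {
  pos <- match_terms(term, names(estimates))
  if (anyNA(pos)) stop("term not found: ", term)
  unname(estimates[pos])
}

#' Simulate a mixed-model outcome from known coefficients
#'
#' Draws \code{response = X beta + Z b + e} on a supplied trial design:
#' continuous predictors are standardized (the same convention the model
#' fitters use), the fixed-effect part is formed from the named
#' ground-truth coefficients, per-participant random effects are drawn
#' with the ground-truth SDs on the standardized scale, and Gaussian
#' residual noise is added.
#'
#' @param design Trial design (see \code{\link{simulate_design}}).
#' @param truth A \code{\link{ground_truth}}.
#' @param response Name of the response column to create.
#' @param seed Optional integer seed.
#' @return The design with the response column appended; the standardized
#'   design used internally is discarded (fitters re-standardize), keeping
#'   generator and fitter conventions identical.
#' @export
simulate_outcome <- function(design, truth, response = "y", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  terms <- names(truth$fixed_effects)
  vars <- term_variables(terms)
  cols <- intersect(continuous_predictors(), vars)
  std <- standardize_predictors(design, cols = cols)
  X <- truth_design_matrix(std, truth$fixed_effects)
  eta <- drop(X %*% truth$fixed_effects)

  ids <- unique(design$participant)
  re_terms <- names(truth$random_effect_sds)
  b <- matrix(stats::rnorm(length(ids) * length(re_terms)),
              nrow = length(ids),
              dimnames = list(ids, re_terms))
  b <- sweep(b, 2, truth$random_effect_sds, `*`)
  Z <- X[, re_terms, drop = FALSE]
  idx <- match(design$participant, ids)
  eta <- eta + rowSums(Z * b[idx, , drop = FALSE])

  design[[response]] <- eta + stats::rnorm(nrow(design),
                                           sd = truth$residual_sd)
  design
}

#' Generate a complete synthetic filling-in experiment
#'
#' Produces a trial table whose log filling-in times follow the
#' ground-truth mixed model, with microsaccade and blink event streams
#' consistent with each trial's covariates, and (optionally) binocular
#' gaze traces realizing those events.
#'
#' The generative order keeps every model covariate exogenous to the
#' outcome residual: microsaccade presence is a per-trial suppression draw
#' (probability \code{cfg$p_no_ms} of a no-microsaccade trial) and the
#' blink count is drawn from the nominal blink rate at the typical trial
#' duration, both \emph{before} the outcome. Event times are then realized
#' over the drawn filling-in time -- at rate
#' \code{ms_rate / (1 - p_no_ms)} on microsaccade trials, so the marginal
#' event rate stays at \code{cfg$ms_rate} -- with placement suppressed in
#' the final \code{cfg$prepress_gap_s} seconds before the report,
#' emulating the pre-report microsaccade-rate dip. Filling-in times below
#' \code{min_trial_s} (the short-trial exclusion bound) are redrawn; times
#' beyond the session timeout \code{max_trial_s} are kept but flagged
#' (\code{over_timeout}), since censoring them would distort the
#' generative law that parameter-recovery analyses invert.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param truth A \code{\link{ground_truth}} whose coefficients cover the
#'   primary-model terms.
#' @param seed Optional integer seed; fully determines the output.
#' @param emit_traces Generate gaze traces for every trial (memory-heavy
#'   at the full design size; intended for reduced configurations).
#' @return List of class \code{"ff_experiment"}: \code{trials} (one row
#'   per trial: design, covariates, \code{ft_s}, \code{log_ft}),
#'   \code{events} and \code{blinks} (per-trial lists of true event tables,
#'   seconds), \code{traces} (per-trial \code{"gaze_trace"} list or
#'   \code{NULL}), \code{truth}, \code{cfg}.
#' @export
generate_experiment <- function(cfg = sim_config(),
                                truth = ground_truth(),
                                seed = NULL,
                                emit_traces = FALSE) {
  if (!is.null(seed)) set.seed(seed)

  design <- simulate_design(cfg$n_participants, NULL, cfg)
  # randomize block order within participant (block label keeps condition)
  n <- nrow(design)

  terms <- names(truth$fixed_effects)
  vars <- term_variables(terms)
  cols <- intersect(continuous_predictors(), vars)
  std <- standardize_predictors(design, cols = cols)
  X <- truth_design_matrix(std, truth$fixed_effects)
  eta <- drop(X %*% truth$fixed_effects)

  ids <- unique(design$participant)
  re_terms <- names(truth$random_effect_sds)
  b <- matrix(stats::rnorm(length(ids) * length(re_terms)),
              nrow = length(ids), dimnames = list(ids, re_terms))
  b <- sweep(b, 2, truth$random_effect_sds, `*`)
  Z <- X[, re_terms, drop = FALSE]
  eta <- eta + rowSums(Z * b[match(design$participant, ids), , drop = FALSE])

  # draw the log outcome subject to the 2-s floor, by redraw from a
  # *symmetric* truncation: every trial's residual is resampled until
  # |eps| <= |a|, where a = floor deficit of its linear predictor. The
  # support [a, -a] respects the floor by construction and is symmetric
  # about zero, so E[log FT | x] equals the linear predictor exactly --
  # the naive redraw-if-below-floor scheme samples kept trials from a
  # left-truncated normal and measurably attenuates the coefficients the
  # recovery analyses are meant to return. Trials whose linear predictor
  # itself sits at or below the floor (absent at default settings) fall
  # back to the one-sided redraw. The session timeout (max_trial_s) is
  # not imposed on the outcome either: timeout censoring would distort
  # the generative law; over-long trials are flagged instead.
  floor_log <- log(cfg$min_trial_s / cfg$ft_scale)
  a <- floor_log - eta
  eps <- stats::rnorm(n, sd = truth$residual_sd)
  need <- which(a < 0 & abs(eps) > -a)
  tries <- 0
  while (length(need) > 0 && tries < 10000) {
    eps[need] <- stats::rnorm(length(need), sd = truth$residual_sd)
    need <- need[abs(eps[need]) > -a[need]]
    tries <- tries + 1
  }
  for (i in which(a >= 0)) { # degenerate: predictor at/below the floor
    for (try in 1:1000) {
      cand <- stats::rnorm(1, sd = truth$residual_sd)
      if (cand >= a[i]) {
        eps[i] <- cand
        break
      }
      eps[i] <- a[i]
    }
  }
  log_ft <- eta + eps
  ft <- cfg$ft_scale * exp(log_ft)

  trials <- design
  trials$ft_s <- ft
  trials$log_ft <- log(ft)
  trials$over_timeout <- ft > cfg$max_trial_s

  events <- vector("list", n)
  blinks <- vector("list", n)
  ms_count <- integer(n)
  ms_amplitude <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ev <- draw_trial_events(ft[i], trials$ms_presence[i] == 1L, cfg)
    bl <- draw_trial_blinks(ft[i], trials$num_blinks[i], ev, cfg)
    events[[i]] <- ev
    blinks[[i]] <- bl
    ms_count[i] <- nrow(ev)
    if (nrow(ev) > 0)
      ms_amplitude[i] <- ev$amplitude_deg[nrow(ev)]
  }
  trials$ms_count <- ms_count
  trials$ms_amplitude <- ms_amplitude
  trials$trial_type <- "main"

  traces <- NULL
  if (emit_traces) {
    traces <- vector("list", n)
    for (i in seq_len(n))
      traces[[i]] <- generate_trace(ft[i], events[[i]], blinks[[i]], cfg)
  }

  structure(list(trials = trials, events = events, blinks = blinks,
                 traces = traces, truth = truth, cfg = cfg),
            class = "ff_experiment")
}

# realize microsaccade event times/amplitudes/directions for one trial
draw_trial_events <- function(ft_s, ms_present, cfg) {
  empty <- data.frame(onset_s = numeric(0), amplitude_deg = numeric(0),
                      direction_deg = numeric(0))
  if (!ms_present || cfg$ms_rate <= 0) return(empty)
  rate <- cfg$ms_rate / (1 - cfg$p_no_ms)
  k <- stats::rpois(1, rate * ft_s)
  if (k < 1) k <- 1L # presence implies at least one event
  dur <- ms_waveform(1, cfg$main_sequence_slope)$duration_s
  sep <- dur + 0.05
  lo <- 0.05
  hi <- ft_s - cfg$prepress_gap_s - dur - 0.05
  if (hi <= lo) hi <- ft_s - dur - 0.05
  k <- min(k, max(1L, floor((hi - lo) / sep)))
  onsets <- NULL
  for (try in 1:100) {
    cand <- sort(stats::runif(k, lo, hi))
    if (k == 1 || all(diff(cand) >= sep)) {
      onsets <- cand
      break
    }
  }
  if (is.null(onsets)) { # greedy thinning fallback
    cand <- sort(stats::runif(k, lo, hi))
    onsets <- cand[1]
    for (o in cand[-1]) if (o - onsets[length(onsets)] >= sep)
      onsets <- c(onsets, o)
  }
  amps <- draw_amplitudes(length(onsets), cfg)
  # microsaccades are error-correcting in real fixation: once gaze has
  # strayed, directions are biased back toward the fixation point, so the
  # event-displacement walk stays bounded and trials survive the 1-deg
  # gaze-displacement exclusion
  dirs <- numeric(length(onsets))
  px <- 0
  py <- 0
  for (i in seq_along(onsets)) {
    if (sqrt(px^2 + py^2) < 0.2) {
      dirs[i] <- stats::runif(1, 0, 360)
    } else {
      back <- atan2(-py, -px) * 180 / pi
      dirs[i] <- back + stats::rnorm(1, 0, 30)
    }
    th <- dirs[i] * pi / 180
    px <- px + amps[i] * cos(th)
    py <- py + amps[i] * sin(th)
  }
  data.frame(onset_s = onsets,
             amplitude_deg = amps,
             direction_deg = dirs %% 360)
}

# place blink intervals avoiding injected events (padded so detection is
# not disturbed); drops blinks that cannot be placed in a short trial
draw_trial_blinks <- function(ft_s, n_blinks, events, cfg) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (n_blinks < 1) return(empty)
  dur_ev <- ms_waveform(1, cfg$main_sequence_slope)$duration_s
  placed <- empty
  for (b in seq_len(n_blinks)) {
    len <- stats::runif(1, cfg$blink_duration[1], cfg$blink_duration[2])
    ok <- FALSE
    for (try in 1:50) {
      s <- stats::runif(1, 0, max(ft_s - len - 0.35, 0.001))
      e <- s + len
      clash_ev <- nrow(events) > 0 &&
        any(events$onset_s - 0.2 < e & events$onset_s + dur_ev + 0.2 > s)
      clash_bl <- nrow(placed) > 0 &&
        any(placed$start_s - 0.05 < e & placed$end_s + 0.05 > s)
      if (!clash_ev && !clash_bl) {
        placed <- rbind(placed, data.frame(start_s = s, end_s = e))
        ok <- TRUE
        break
      }
    }
    if (!ok) break
  }
  placed[order(placed$start_s), , drop = FALSE]
}
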