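#' Standardize continuous predictors
#'
#' Zero-centers and unit-scales continuous predictors, leaving binary
#' indicators (e.g. microsaccade presence) untouched; the centering and
#' scaling constants are recorded for back-transformation.
#'
#' @param data Trial metrics or design table.
#' @param cols Columns to standardize; defaults to the continuous
#'   predictors present in the table (\code{contrast},
#'   \code{eccentricity}, \code{trial_num}, \code{num_blinks},
#'   \code{ocular_drift}, \code{ms_amplitude}).
#' @return The table with the named columns standardized and an attribute
#'   \code{"scaling"} holding named \code{center} and \code{scale}
#'   vectors.
#' @export
standardize_predictors <- function(data, cols = NULL) {
  if (is.null(cols)) cols <- intersect(continuous_predictors(), names(data))
  center <- numeric(0)
  scl <- numeric(0)
  for (cl in cols) {
    x <- data[[cl]]
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("predictor has zero variance: ", cl)
    data[[cl]] <- (x - m) / s
    center[cl] <- m
    scl[cl] <- s
  }
  attr(data, "scaling") <- list(center = center, scale = scl)
  data
}

#' Specification of a linear mixed model
#'
#' @param response Response column name (e.g. \code{"log_ft"},
#'   \code{"log_ms_rate"}, \code{"log_immobilization"}).
#' @param fixed Fixed-effect term labels (main effects and \code{"a:b"}
#'   interactions); every interaction's parents must appear as main
#'   effects.
#' @param random Per-participant random-slope terms (the random intercept
#'   is always included); must be a subset of the fixed main effects.
#' @param correlated Fit the random-effect covariance as fully correlated
#'   (\code{TRUE}) or as independent variance components (default; a
#'   high-dimensional correlated structure is fragile with few
#'   participants).
#' @param group Grouping factor column.
#' @return List of class \code{"model_spec"}.
#' @export
model_spec <- function(response, fixed, random = character(0),
                       correlated = FALSE, group = "participant") {
  inter <- grep(":", fixed, fixed = TRUE, value = TRUE)
  parents <- unique(unlist(strsplit(inter, ":", fixed = TRUE)))
  missing <- setdiff(parents, fixed)
  if (length(missing) > 0)
    stop("interaction parents missing from fixed terms: ",
         paste(missing, collapse = ", "))
  bad <- setdiff(random, setdiff(fixed, inter))
  if (length(bad) > 0)
    stop("random terms must be fixed main effects: ",
         paste(bad, collapse = ", "))
  structure(list(response = response, fixed = fixed, random = random,
                 correlated = correlated, group = group),
            class = "model_spec")
}

# lme4 formula for a model_spec
spec_formula <- function(spec) {
  fixed_part <- if (length(spec$fixed) > 0)
    paste(spec$fixed, collapse = " + ") else "1"
  bar <- if (spec$correlated || length(spec$random) == 0) "|" else "||"
  re_inner <- if (length(spec$random) > 0)
    paste(c("1", spec$random), collapse = " + ") else "1"
  stats::as.formula(paste0(
    spec$response, " ~ ", fixed_part,
    " + (", re_inner, " ", bar, " ", spec$group, ")"))
}

#' The primary filling-in time model specification
#'
#' Log filling-in time regressed on color contrast, boundary eccentricity,
#' trial number, microsaccade presence and blink count, the
#' contrast-by-trial interaction, and the interactions of microsaccade
#' presence and blink count with the two stimulus properties; random
#' intercept and slopes for the five main effects by participant.
#'
#' @param correlated Passed to \code{\link{model_spec}}.
#' @return A \code{"model_spec"}.
#' @export
primary_ft_spec <- function(correlated = FALSE) {
  model_spec(
    response = "log_ft",
    fixed = c("contrast", "eccentricity", "trial_num", "ms_presence",
              "num_blinks", "contrast:trial_num", "ms_presence:contrast",
              "ms_presence:eccentricity", "num_blinks:contrast",
              "num_blinks:eccentricity"),
    random = c("contrast", "eccentricity", "trial_num", "ms_presence",
               "num_blinks"),
    correlated = correlated)
}

#' Microsaccade-rate model specification
#'
#' Log trial-wise microsaccade rate regressed on contrast, eccentricity
#' and trial number with matching random slopes. Zero-event trials carry
#' no defined log rate and are excluded before fitting.
#'
#' @param correlated Passed to \code{\link{model_spec}}.
#' @return A \code{"model_spec"}.
#' @export
ms_rate_spec <- function(correlated = FALSE) {
  model_spec("log_ms_rate",
             fixed = c("contrast", "eccentricity", "trial_num"),
             random = c("contrast", "eccentricity", "trial_num"),
             correlated = correlated)
}

#' Immobilization-time model specification
#'
#' Log immobilization time regressed on contrast, eccentricity, the
#' amplitude of the last microsaccade, and trial number, with matching
#' random slopes.
#'
#' @param correlated Passed to \code{\link{model_spec}}.
#' @return A \code{"model_spec"}.
#' @export
immobilization_spec <- function(correlated = FALSE) {
  model_spec("log_immobilization",
             fixed = c("contrast", "eccentricity", "ms_amplitude",
                       "trial_num"),
             random = c("contrast", "eccentricity", "ms_amplitude",
                        "trial_num"),
             correlated = correlated)
}

#' Subset (microsaccade- vs no-microsaccade-trial) model specification
#'
#' Random-intercept-only model of log filling-in time on contrast,
#' eccentricity, trial number and ocular drift, used for the balanced
#' trial subsets.
#'
#' @return A \code{"model_spec"}.
#' @export
subset_ft_spec <- function() {
  model_spec("log_ft",
             fixed = c("contrast", "eccentricity", "trial_num",
                       "ocular_drift"),
             random = character(0))
}

#' Fit a linear mixed model
#'
#' REML fit via \pkg{lme4} (BOBYQA optimizer) of a
#' \code{\link{model_spec}}; non-convergence is flagged, never silently
#' accepted.
#'
#' @param spec A \code{"model_spec"}.
#' @param data Design table with the response and (already standardized)
#'   predictors.
#' @param reml Use REML (default) or ML.
#' @return List of class \code{"ff_fit"}: \code{estimates} (fixed
#'   effects), \code{se}, \code{random_sd} (including
#'   \code{"residual"}), \code{loglik}, \code{bic}, \code{n_obs},
#'   \code{n_groups}, \code{converged}, \code{singular}, \code{spec} and
#'   the underlying \code{fit}.
#' @export
fit_lmm <- function(spec, data, reml = TRUE) {
  if (length(unique(data[[spec$group]])) < 2)
    stop("at least 2 participants required")
  y <- data[[spec$response]]
  if (is.null(y)) stop("response column not found: ", spec$response)
  if (any(!is.finite(y))) stop("non-finite response values")
  fit <- suppressMessages(lme4::lmer(
    spec_formula(spec), data = data, REML = reml,
    control = lme4::lmerControl(optimizer = "bobyqa",
                                calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs %||% character(0)))
  vc <- lme4::VarCorr(fit)
  rsd <- unlist(lapply(vc, function(m) attr(m, "stddev")))
  rsd <- c(rsd, residual = stats::sigma(fit))
  structure(list(
    estimates = lme4::fixef(fit),
    se = sqrt(diag(as.matrix(stats::vcov(fit)))),
    random_sd = rsd,
    loglik = as.numeric(stats::logLik(fit)),
    bic = stats::BIC(fit),
    n_obs = stats::nobs(fit),
    n_groups = lme4::ngrps(fit)[[1]],
    converged = converged,
    singular = lme4::isSingular(fit),
    spec = spec,
    fit = fit), class = "ff_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ff_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s (%d obs, %d participants)%s\n",
              deparse(spec_formula(x$spec)), x$n_obs, x$n_groups,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(estimate = round(x$estimates, 4),
                   se = round(x$se, 4)))
  cat(sprintf("BIC %.1f, residual SD %.3f\n", x$bic,
              x$random_sd[["residual"]]))
  invisible(x)
}

#' Participant-level case bootstrap of a mixed model
#'
#' Resamples whole participants with replacement (relabeling duplicates so
#' the grouping structure keeps its size), refits the model on each
#' resample, and forms percentile confidence intervals at the
#' Bonferroni-corrected level \code{alpha / k}, where k is the number of
#' non-intercept fixed effects. A term is flagged significant when its
#' corrected CI excludes 0; the intercept is reported but not evaluated.
#'
#' @param spec A \code{"model_spec"}.
#' @param data Design table.
#' @param n_boot Bootstrap iterations (10,000 in a full analysis; a few
#'   hundred suffice at desk scale).
#' @param alpha Family-wise level before correction.
#' @param seed Optional integer seed (reproducible resampling).
#' @return List of class \code{"ff_boot"}: \code{estimates} (full-data
#'   fit), \code{ci} (matrix with lower/upper), \code{significant},
#'   \code{level} (per-term CI level), \code{alpha},
#'   \code{alpha_corrected}, \code{replicates} (n_boot x terms),
#'   \code{n_failed}.
#' @export
case_bootstrap <- function(spec, data, n_boot = 500, alpha = 0.05,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  full <- fit_lmm(spec, data)
  if (!full$converged) stop("full-data fit did not converge")
  ids <- unique(data[[spec$group]])
  rows_by_id <- split(seq_len(nrow(data)), data[[spec$group]])

  reps <- matrix(NA_real_, n_boot, length(full$estimates),
                 dimnames = list(NULL, names(full$estimates)))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(j) {
      d <- data[rows_by_id[[as.character(take[j])]], , drop = FALSE]
      d[[spec$group]] <- sprintf("B%03d", j) # unique relabeling
      d
    })
    bd <- do.call(rbind, pieces)
    est <- tryCatch({
      f <- fit_lmm(spec, bd)
      if (!f$converged) NULL else f$estimates
    }, error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L
    else reps[b, names(est)] <- est
  }
  if (n_failed > 0.2 * n_boot)
    stop(sprintf("case bootstrap aborted: %d of %d refits failed",
                 n_failed, n_boot))
  k <- sum(names(full$estimates) != "(Intercept)")
  alpha_corr <- alpha / max(k, 1)
  ci <- boot_ci_matrix(reps, alpha_corr)
  sig <- ci[, 1] > 0 | ci[, 2] < 0
  sig["(Intercept)"] <- NA
  structure(list(estimates = full$estimates, ci = ci, significant = sig,
                 level = 1 - alpha_corr, alpha = alpha,
                 alpha_corrected = alpha_corr, replicates = reps,
                 n_boot = n_boot, n_failed = n_failed, full_fit = full),
            class = "ff_boot")
}

#' Percentile CIs from stored bootstrap replicates
#'
#' @param replicates Matrix of bootstrap fixed-effect estimates
#'   (iterations x terms), as stored in an \code{"ff_boot"}.
#' @param alpha Per-term alpha (already corrected if desired).
#' @return Matrix with columns \code{lower}, \code{upper}.
#' @export
boot_ci_matrix <- function(replicates, alpha) {
  t(apply(replicates, 2, stats::quantile,
          probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)) |>
    `colnames<-`(c("lower", "upper"))
}

#' @export
print.ff_boot <- function(x, ...) {
  cat(sprintf(
    "Case bootstrap: %d iterations (%d failed), %.4g%% percentile CIs\n",
    x$n_boot, x$n_failed, 100 * x$level))
  out <- data.frame(estimate = round(x$estimates, 4),
                    lower = round(x$ci[, "lower"], 4),
                    upper = round(x$ci[, "upper"], 4),
                    significant = x$significant)
  print(out)
  invisible(x)
}

#' BIC-guided term retention
#'
#' For each candidate term (interactions considered before main effects,
#' and a main effect never while one of its interactions is retained),
#' compares the BIC of the current model with and without the term, using
#' ML refits since likelihoods under different fixed-effect structures are
#' only comparable without REML. A term is removed only if removal lowers
#' the BIC; otherwise it is retained.
#'
#' @param spec A \code{"model_spec"}.
#' @param data Design table.
#' @param candidates Terms eligible for removal (default: all fixed
#'   terms).
#' @return List with \code{spec} (pruned), \code{log} (data frame of
#'   per-term BIC comparisons).
#' @export
select_terms_by_bic <- function(spec, data, candidates = spec$fixed) {
  inter <- grep(":", candidates, fixed = TRUE, value = TRUE)
  mains <- setdiff(candidates, inter)
  ordered <- c(inter, mains)
  log <- list()
  current <- spec
  for (term in ordered) {
    if (!(term %in% current$fixed)) next
    if (!grepl(":", term)) {
      kept_inter <- grep(":", current$fixed, fixed = TRUE, value = TRUE)
      if (any(vapply(strsplit(kept_inter, ":", fixed = TRUE),
                     function(p) term %in% p, logical(1))))
        next # parent of a retained interaction
    }
    with_fit <- fit_lmm(current, data, reml = FALSE)
    reduced <- current
    reduced$fixed <- setdiff(reduced$fixed, term)
    reduced$random <- intersect(reduced$random, reduced$fixed)
    without_fit <- fit_lmm(reduced, data, reml = FALSE)
    removed <- without_fit$bic < with_fit$bic
    log[[term]] <- data.frame(term = term, bic_with = with_fit$bic,
                              bic_without = without_fit$bic,
                              removed = removed)
    if (removed) current <- reduced
  }
  list(spec = current,
       log = if (length(log) > 0) do.call(rbind, c(log, make.row.names = FALSE))
       else data.frame(term = character(0), bic_with = numeric(0),
                       bic_without = numeric(0), removed = logical(0)))
}

#' Balanced subset models: microsaccade vs no-microsaccade trials
#'
#' Splits retained trials into (a) trials with at least one microsaccade
#' and no blinks and (b) trials with neither, balances the two subsets
#' within each participant by randomly downsampling the larger one (the
#' smaller subset is never altered), and fits the random-intercept model
#' \code{log_ft ~ contrast + eccentricity + trial_num + ocular_drift} to
#' each. Inference on these reduced sets conventionally uses uncorrected
#' 95\% CIs.
#'
#' @param metrics Retained trial metrics (needs \code{ms_presence},
#'   \code{num_blinks}, \code{log_ft}, the predictors and
#'   \code{participant}).
#' @param seed Optional integer seed for the downsampling.
#' @param n_boot If positive, also run \code{\link{case_bootstrap}} with
#'   uncorrected \code{alpha = 0.05} on each subset.
#' @return List of class \code{"ff_subsets"}: \code{ms_fit},
#'   \code{no_ms_fit}, \code{ms_boot}, \code{no_ms_boot} (or NULL),
#'   \code{counts} (per-participant balanced n), \code{dropped}
#'   (participants lacking one subset), \code{ms_data}, \code{no_ms_data}.
#' @export
subset_models <- function(metrics, seed = NULL, n_boot = 0) {
  if (!is.null(seed)) set.seed(seed)
  ms_all <- metrics[metrics$ms_presence == 1 & metrics$num_blinks == 0, ,
                    drop = FALSE]
  no_all <- metrics[metrics$ms_presence == 0 & metrics$num_blinks == 0, ,
                    drop = FALSE]
  ids <- unique(as.character(metrics$participant))
  keep_ms <- list()
  keep_no <- list()
  counts <- integer(0)
  dropped <- character(0)
  for (id in ids) {
    a <- ms_all[ms_all$participant == id, , drop = FALSE]
    b <- no_all[no_all$participant == id, , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) {
      dropped <- c(dropped, id)
      next
    }
    n <- min(nrow(a), nrow(b))
    if (nrow(a) > n) a <- a[sample.int(nrow(a), n), , drop = FALSE]
    if (nrow(b) > n) b <- b[sample.int(nrow(b), n), , drop = FALSE]
    keep_ms[[id]] <- a
    keep_no[[id]] <- b
    counts[id] <- n
  }
  if (length(keep_ms) < 2)
    stop("fewer than 2 participants with both subsets non-empty")
  spec <- subset_ft_spec()
  ms_data <- standardize_predictors(do.call(rbind, keep_ms),
                                    cols = c("contrast", "eccentricity",
                                             "trial_num", "ocular_drift"))
  no_data <- standardize_predictors(do.call(rbind, keep_no),
                                    cols = c("contrast", "eccentricity",
                                             "trial_num", "ocular_drift"))
  res <- list(ms_fit = fit_lmm(spec, ms_data),
              no_ms_fit = fit_lmm(spec, no_data),
              ms_boot = NULL, no_ms_boot = NULL,
              counts = counts, dropped = dropped,
              ms_data = ms_data, no_ms_data = no_data)
  if (n_boot > 0) {
    res$ms_boot <- case_bootstrap(spec, ms_data, n_boot, alpha = 0.05)
    res$no_ms_boot <- case_bootstrap(spec, no_data, n_boot, alpha = 0.05)
  }
  class(res) <- "ff_subsets"
  res
}

#' Cortical distance of a visual-field eccentricity
#'
#' Maps eccentricity E (deg) to cortical distance (mm) from the
#' retinotopic representation of 10 deg, via the magnification rule
#' \code{d = ln(E) / 0.063 - 36.54}; E = 10 deg maps to approximately
#' 0 mm. Used to re-fit eccentricity effects on a cortically scaled axis.
#'
#' @param E Eccentricity (deg), strictly positive.
#' @return Cortical distance (mm).
#' @export
cortical_distance <- function(E) {
  if (any(E <= 0)) stop("eccentricity must be positive")
  log(E) / 0.063 - 36.54
}

#' Back-transform standardized-model coefficients to raw predictor scale
#'
#' Given coefficients estimated on zero-centered, unit-scaled predictors
#' and the recorded centering/scaling constants, returns the equivalent
#' coefficients on the raw predictor scale (handling two-way
#' interactions), so that predictions from either parameterization agree
#' identically.
#'
#' @param estimates Named coefficient vector (with \code{"(Intercept)"}).
#' @param scaling The \code{"scaling"} attribute produced by
#'   \code{\link{standardize_predictors}}.
#' @return Named coefficient vector on the raw scale.
#' @export
coef_unstandardize <- function(estimates, scaling) {
  cn <- function(v) if (v %in% names(scaling$center))
    scaling$center[[v]] else 0
  sn <- function(v) if (v %in% names(scaling$scale))
    scaling$scale[[v]] else 1
  out <- estimates
  terms <- setdiff(names(estimates), "(Intercept)")
  inter <- grep(":", terms, fixed = TRUE, value = TRUE)
  mains <- setdiff(terms, inter)
  # interactions: beta_jk / (s_j * s_k)
  for (t in inter) {
    p <- strsplit(t, ":", fixed = TRUE)[[1]]
    out[t] <- estimates[t] / (sn(p[1]) * sn(p[2]))
  }
  # main effects: beta_j / s_j - sum_k gamma_jk * c_k
  for (v in mains) {
    g <- estimates[v] / sn(v)
    for (t in inter) {
      p <- strsplit(t, ":", fixed = TRUE)[[1]]
      if (v %in% p) {
        other <- setdiff(p, v)
        g <- g - out[t] * cn(other)
      }
    }
    out[v] <- g
  }
  # intercept: absorb all centering shifts
  ic <- estimates[["(Intercept)"]]
  for (v in mains) ic <- ic - (estimates[v] / sn(v)) * cn(v)
  for (t in inter) {
    p <- strsplit(t, ":", fixed = TRUE)[[1]]
    ic <- ic + out[t] * cn(p[1]) * cn(p[2])
  }
  out["(Intercept)"] <- ic
  out
}
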