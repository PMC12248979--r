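test_that("standardization maps balanced three-level designs to z-scores", {
  d <- data.frame(eccentricity = rep(c(2, 4, 6), 1000),
                  ms_presence = rep(c(0, 1), 1500))
  std <- standardize_predictors(d, cols = "eccentricity")
  # balanced 3-level design: z-scores -1.2247, 0, +1.2247
  expect_equal(sort(unique(std$eccentricity)), c(-1.2247, 0, 1.2247),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(std$ms_presence, d$ms_presence) # binary left alone
  sc <- attr(std, "scaling")
  expect_equal(unname(sc$center["eccentricity"]), 4)
  d$flat <- 1
  expect_error(standardize_predictors(d, cols = "flat"), "zero variance")
})

test_that("model specs validate marginality and random-term containment", {
  expect_error(model_spec("y", c("a", "a:b")), "parents")
  expect_error(model_spec("y", c("a", "b"), random = "c"), "random terms")
  s <- primary_ft_spec()
  expect_length(s$fixed, 10)
  expect_length(s$random, 5)
})

test_that("noiseless simulation is recovered to numerical precision", {
  truth <- ground_truth(
    fixed_effects = c("(Intercept)" = 0.5, "contrast" = 0.2,
                      "eccentricity" = -0.1, "contrast:eccentricity" = 0.05),
    random_terms = character(0), random_intercept_sd = 0, residual_sd = 0)
  d <- simulate_design(4, 60, seed = 51)
  d <- simulate_outcome(d, truth, response = "log_ft", seed = 52)
  std <- standardize_predictors(d, cols = c("contrast", "eccentricity"))
  fit <- fit_lmm(model_spec("log_ft",
                            c("contrast", "eccentricity",
                              "contrast:eccentricity")), std)
  expect_equal(coef_lookup(fit$estimates, "(Intercept)"), 0.5,
               tolerance = 1e-6)
  expect_equal(coef_lookup(fit$estimates, "contrast"), 0.2,
               tolerance = 1e-6)
  expect_equal(coef_lookup(fit$estimates, "contrast:eccentricity"), 0.05,
               tolerance = 1e-6)
})

test_that("intercept-only fit of a constant response returns the constant", {
  d <- data.frame(participant = rep(c("a", "b", "c"), each = 10),
                  y = 2.5)
  # jitter-free response: lmer degenerates gracefully to the mean
  fit <- fit_lmm(model_spec("y", character(0)), d)
  expect_equal(unname(fit$estimates[["(Intercept)"]]), 2.5,
               tolerance = 1e-8)
})

test_that("mixed-model recovery on one simulated replicate is unbiased", {
  truth <- ground_truth(fixed_effects = default_ms_rate_effects(),
                        random_terms = c("contrast", "eccentricity",
                                         "trial_num"),
                        random_intercept_sd = 0.2, random_slope_sd = 0.03,
                        residual_sd = 0.3)
  d <- simulate_design(21, NULL, seed = 53)
  d <- simulate_outcome(d, truth, response = "log_ms_rate", seed = 54)
  std <- standardize_predictors(d, cols = c("contrast", "eccentricity",
                                            "trial_num"))
  fit <- fit_lmm(ms_rate_spec(), std)
  expect_true(fit$converged)
  for (term in names(truth$fixed_effects)) {
    se <- fit$se[[term]]
    expect_lt(abs(coef_lookup(fit$estimates, term) -
                    truth$fixed_effects[[term]]), 4 * se)
  }
})

test_that("case bootstrap gives ordered, level-monotone, seeded CIs", {
  truth <- ground_truth(
    fixed_effects = c("(Intercept)" = 0.4, "contrast" = 0.15,
                      "eccentricity" = 0),
    random_terms = character(0), random_intercept_sd = 0.15,
    residual_sd = 0.3)
  d <- simulate_design(8, 40, seed = 55)
  d <- simulate_outcome(d, truth, response = "log_ft", seed = 56)
  std <- standardize_predictors(d, cols = c("contrast", "eccentricity"))
  spec <- model_spec("log_ft", c("contrast", "eccentricity"))
  b1 <- case_bootstrap(spec, std, n_boot = 120, alpha = 0.05, seed = 57)
  expect_true(all(b1$ci[, "lower"] <= b1$ci[, "upper"]))
  expect_equal(b1$alpha_corrected, 0.05 / 2)
  # CIs widen monotonically as alpha decreases, on the same resamples
  wide <- boot_ci_matrix(b1$replicates, 0.005)
  narrow <- boot_ci_matrix(b1$replicates, 0.10)
  expect_true(all(wide[, "lower"] <= narrow[, "lower"]))
  expect_true(all(wide[, "upper"] >= narrow[, "upper"]))
  # a strong simulated effect is flagged, the intercept never evaluated
  expect_true(b1$significant[["contrast"]])
  expect_true(is.na(b1$significant[["(Intercept)"]]))
  # reproducible under the seed
  b2 <- case_bootstrap(spec, std, n_boot = 120, alpha = 0.05, seed = 57)
  expect_identical(b1$ci, b2$ci)
})

test_that("Bonferroni correction sets the per-term CI level", {
  # 10 non-intercept terms at alpha 0.05 -> 99.5% CIs; 3 -> 98.33%
  expect_equal(1 - 0.05 / 10, 0.995)
  reps <- matrix(rnorm(2000), 1000, 2,
                 dimnames = list(NULL, c("(Intercept)", "x")))
  ci <- boot_ci_matrix(reps, 0.05 / 3)
  q <- quantile(reps[, "x"], c(0.05 / 6, 1 - 0.05 / 6))
  expect_equal(unname(ci["x", ]), unname(q))
})

test_that("BIC pruning drops noise terms and keeps real ones", {
  truth <- ground_truth(
    fixed_effects = c("(Intercept)" = 0.4, "contrast" = 0.3,
                      "eccentricity" = 0),
    random_terms = character(0), random_intercept_sd = 0.1,
    residual_sd = 0.3)
  d <- simulate_design(12, 120, seed = 58)
  d <- simulate_outcome(d, truth, response = "log_ft", seed = 59)
  std <- standardize_predictors(d, cols = c("contrast", "eccentricity"))
  spec <- model_spec("log_ft", c("contrast", "eccentricity"))
  sel <- select_terms_by_bic(spec, std)
  expect_true("contrast" %in% sel$spec$fixed)
  expect_false("eccentricity" %in% sel$spec$fixed)
  # empty candidate list leaves the model specification unchanged
  sel0 <- select_terms_by_bic(spec, std, candidates = character(0))
  expect_identical(sel0$spec$fixed, spec$fixed)
  # a parent is never removed while its interaction is retained
  spec2 <- model_spec("log_ft", c("contrast", "eccentricity",
                                  "contrast:eccentricity"))
  sel2 <- select_terms_by_bic(spec2, std, candidates = "contrast")
  expect_true("contrast" %in% sel2$spec$fixed)
})

test_that("subset balancing equalizes counts and fixes the smaller side", {
  set.seed(60)
  n <- 400
  metrics <- data.frame(
    participant = rep(sprintf("P%02d", 1:8), each = n / 8),
    contrast = sample(c(10, 20, 30), n, TRUE),
    eccentricity = sample(c(2, 4, 6), n, TRUE),
    trial_num = sample(1:40, n, TRUE),
    ocular_drift = rnorm(n, 0.75, 0.15),
    ms_presence = rbinom(n, 1, 0.6),
    num_blinks = rpois(n, 0.3),
    log_ft = rnorm(n, 0.6, 0.4))
  metrics$row_id <- seq_len(n)
  sub <- subset_models(metrics, seed = 61)
  for (id in names(sub$counts)) {
    expect_equal(sum(sub$ms_data$participant == id), sub$counts[[id]])
    expect_equal(sum(sub$no_ms_data$participant == id), sub$counts[[id]])
    a <- metrics[metrics$participant == id & metrics$ms_presence == 1 &
                   metrics$num_blinks == 0, ]
    b <- metrics[metrics$participant == id & metrics$ms_presence == 0 &
                   metrics$num_blinks == 0, ]
    smaller <- if (nrow(a) <= nrow(b)) a else b
    kept <- if (nrow(a) <= nrow(b)) sub$ms_data else sub$no_ms_data
    expect_setequal(intersect(smaller$row_id, kept$row_id), smaller$row_id)
  }
  expect_true(sub$ms_fit$converged)
  # deterministic under the seed
  sub2 <- subset_models(metrics, seed = 61)
  expect_equal(sort(sub2$ms_data$row_id), sort(sub$ms_data$row_id))
})

test_that("cortical magnification transform matches its closed form", {
  expect_equal(cortical_distance(10), log(10) / 0.063 - 36.54)
  expect_lt(abs(cortical_distance(10)), 0.02) # ~0 mm at 10 deg
  e <- c(0.5, 1, 2, 4, 6, 10)
  expect_true(all(diff(cortical_distance(e)) > 0))
  expect_error(cortical_distance(0), "positive")
  expect_error(cortical_distance(-2), "positive")
})

test_that("back-transformed coefficients reproduce predictions exactly", {
  set.seed(62)
  d <- data.frame(contrast = sample(c(10, 20, 30), 200, TRUE),
                  eccentricity = sample(c(2, 4, 6), 200, TRUE),
                  ms_presence = rbinom(200, 1, 0.5))
  d$y <- 0.3 + 0.1 * d$contrast - 0.05 * d$eccentricity +
    0.2 * d$ms_presence - 0.01 * d$contrast * d$ms_presence + rnorm(200, 0, 0.1)
  std <- standardize_predictors(d, cols = c("contrast", "eccentricity"))
  f <- y ~ contrast + eccentricity + ms_presence + contrast:ms_presence
  beta <- coef(lm(f, std))
  gamma <- coef_unstandardize(beta, attr(std, "scaling"))
  pred_std <- drop(model.matrix(f, std) %*% beta)
  pred_raw <- drop(model.matrix(f, d) %*% gamma[colnames(model.matrix(f, d))])
  expect_equal(pred_raw, pred_std, tolerance = 1e-8)
  # and they agree with a direct raw-scale fit
  expect_equal(unname(gamma[names(beta)]), unname(coef(lm(f, d))),
               tolerance = 1e-8)
})
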