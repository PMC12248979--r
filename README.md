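# fixfill

Analysis chain for perceptual filling-in experiments with binocular eye
tracking.

When gaze is held still, visual boundaries adapt and fade, and adjacent
surfaces perceptually merge — the filling-in illusion behind Troxler
fading. Microsaccades (small involuntary saccades during fixation)
counteract this fading. Experiments probing that interaction record
1-kHz binocular gaze while observers fixate until they report that a
color boundary has vanished, and ask how the *filling-in time* (FT)
depends on boundary contrast, boundary eccentricity, and the eye
movements that occurred. This package implements every computational
stage of such a study, for psychophysicists who want a tested,
reproducible pipeline:

* **Synthetic experiments** with known ground truth: conjugate
  random-walk drift, main-sequence ballistic microsaccades, blinks, and
  trial outcomes drawn from a known linear mixed model
  (`generate_experiment()`, `generate_trace()`).
* **Binocular microsaccade detection** by velocity threshold: windowed
  regression velocity, robust per-axis noise scale
  `sigma = sqrt(median(v^2) - median(v)^2)`, elliptic criterion
  `(vx/eta_x)^2 + (vy/eta_y)^2 > 1` required in both eyes for >= 8 ms,
  12-ms merging, direction-change and amplitude filters
  (`detect_microsaccades()`).
* **Trial metrics**: retinal-slip ocular drift on a 0.01 deg grid,
  exclusion rules with a fixed precedence, immobilization time
  (`retinal_slip()`, `apply_exclusions()`, `summarize_trials()`).
* **Rate dynamics**: report-aligned microsaccade rate with the causal
  kernel `w(tau) = alpha^2 tau exp(-alpha tau)` and cross-participant
  baseline normalization (`causal_rate()`, `baseline_normalize()`).
* **Inference**: lme4 REML mixed models of log FT
  (`FT ~ contrast + eccentricity + trial_num + ms_presence + num_blinks`
  plus stimulus-by-oculomotor interactions, random intercept and slopes
  by participant), participant-level case bootstrap with
  Bonferroni-corrected percentile CIs, BIC-guided term retention,
  balanced microsaccade/no-microsaccade subset models, and the cortical
  magnification transform `d = ln(E)/0.063 - 36.54`
  (`fit_lmm()`, `case_bootstrap()`, `subset_models()`,
  `cortical_distance()`).

The methods vignette (`vignettes/filling-in-analysis.Rmd`) documents the
model, every tunable parameter, and the design decisions.

## Worked example

Simulate a small experiment, detect microsaccades, build trial metrics,
and fit the primary model:

```r
library(fixfill)
cfg <- sim_config(n_participants = 4, trials_per_block = 6, seed = 42)
ex  <- generate_experiment(cfg, ground_truth(), seed = 42,
                           emit_traces = TRUE)

det <- detect_microsaccades(ex$traces[[1]])
head(det$events[c("onset_ms", "offset_ms", "amplitude_deg",
                  "peak_vel_deg_s")], 3)
#>   onset_ms offset_ms amplitude_deg peak_vel_deg_s
#> 1      262       295     0.3530773       14.41292
#> 2     1347      1381     0.6430411       26.35670
#> 3     4564      4596     0.2815889       11.58311

s <- summarize_trials(ex)
table(s$metrics$exclusion_reason)
#> gaze_displacement              none
#>                 1               215

std <- standardize_predictors(s$metrics[!s$metrics$excluded, ])
fit <- fit_lmm(primary_ft_spec(), std)
round(fit$estimates[c("(Intercept)", "contrast", "ms_presence")], 3)
#> (Intercept)    contrast ms_presence
#>       1.605       0.113       0.339
```

The detected events sit on the main sequence (peak velocity about 60
deg/s per degree of amplitude, log-log correlation ~1). The fitted
coefficients are on the standardized log-FT scale: here one SD of color
contrast lengthens FT by ~11% and trials containing microsaccades have
~40% longer FTs (exp(0.339)), in line with the generative coefficients
(0.115 and 0.302) at this small demonstration size. The intercept
includes the FT scale constant, `log(3.9) = 1.36`.

The numbered scripts under `analysis/` run the same chain as a
file-based workflow (simulate → detect → metrics → rates → models),
writing tables under `results/analysis/`.

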