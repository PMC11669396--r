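# bioscore

Biosecurity scoring and benchmarking for pasture-based dairy herds.

`bioscore` implements a complete farm biosecurity audit pipeline of the kind
used for Irish seasonal, pasture-based dairying, where a farm's biosecurity
status is assessed from (a) a structured questionnaire whose answer options
carry expert-elicited risk weights and (b) the herd's recorded cattle
introductions from a national movement register. It is written for
veterinary epidemiologists and animal-health programme developers who want
to build, calibrate or audit such a scoring tool end to end — including on
fully synthetic data, since the original expert panels, farmer responses and
national movement databases are not generally redistributable.

## What the package does

1. **Questionnaire model** — a four-section instrument (risk of disease
   entry, speed of disease spread, diagnosis of infection, and an *unscored*
   resilience/vaccination section). Every answer option of the scored
   sections is rendered as a standalone practice statement, the *attribute*
   that expert weights attach to.

2. **Best-worst scaling (MaxDiff) elicitation** — balanced, randomised
   choice-set designs (sets of four attributes; 12–16 tasks per respondent;
   pooled appearances equal within one) and two estimators of the attribute
   utilities from the panel's best/worst picks:

   * a count score per attribute *i*,
     `s_i = (B_i − W_i) / A_i` — times chosen best minus times chosen worst,
     over appearances; and
   * the maximum-likelihood **sequential best-worst logit**: within a task
     with choice set *C*,
     `P(best = b) = exp(u_b) / Σ_{j∈C} exp(u_j)`, then
     `P(worst = w | b) = exp(−u_w) / Σ_{j∈C∖{b}} exp(−u_j)`,
     identified by `Σ u = 0`.

   90% confidence intervals come from a percentile bootstrap over
   respondents; a completion-speed screen flags low-quality responses.

3. **Plausibility correction** — weights that rank a question's options
   against biological plausibility are corrected by one of four audited
   rules (pair averaging, clamping to the question extreme, zeroing out, or
   re-assignment in plausible risk order), driven by an explicit per-question
   policy file and recorded in a replayable JSON-lines log.

4. **Scoring** — a farm's selected options are matched to the corrected
   weights and each section is scored as a percentage of the maximum
   attainable weighted score (higher = lower risk), with subcategory
   breakdowns (e.g. spread between sick and healthy stock, adult-to-young,
   young-to-young, adult-to-adult) and a verbatim record of the unscored
   resilience answers by cattle age category.

5. **Cattle-introduction indicators** — over a rolling 3-year window:
   *in degree* (cattle moved onto the farm), *inward strength* (distinct
   source herds) and *secondary inward degree* (distinct herds supplying
   those sources), benchmarked against 50 same-enterprise-category herds at
   the 10th/50th/90th percentiles.

6. **Traffic-light reports** — section scores classified against a
   comparator score distribution at the 33rd/67th percentiles (green = best
   third, amber = middle, red = bottom), assembled with the movement
   benchmark and resilience record into a versioned JSON/markdown/HTML
   report.

7. **Synthetic-data suite** — generators for questionnaire fixtures with
   the published instrument's shape (70 questions split 28/21/12/9 yielding
   101/96/22 attributes), expert panels with known utilities, farm
   populations with latent quality, and toy movement networks — so the whole
   pipeline is testable from a single seed.

## Worked example

```r
library(bioscore)

qn     <- make_questionnaire_fixture(seed = 1)   # 70-question synthetic fixture
att    <- derive_attributes(qn, "diagnosis")     # 22 practice statements
design <- generate_design(att, n_respondents = 20, seed = 1,
                          section_id = "diagnosis")
u         <- setNames(seq(-1.5, 1.5, length.out = nrow(att)), att$id)
responses <- simulate_experts(design, u, seed = 2)   # known-utility panel
fit       <- bws_fit(responses, design, method = "logit")
fit
#> Best-worst scaling fit (logit): 22 attributes, 20 respondents, 240 answered tasks
#>   logit: nll 481.946, gradient max-norm 1.18e-11

fit <- bootstrap_ci(fit, n_boot = 500, seed = 3)     # 90% percentile CIs
head(summary(fit)$table[, c("attribute_id", "score", "ci_lo", "ci_hi")], 3)
#>       attribute_id    score     ci_lo    ci_hi
#> 1 diagnosis_q10:o2 1.575687 1.1682204 2.129772
#> 2 diagnosis_q11:o1 1.384399 0.9592838 1.964532
#> 3 diagnosis_q11:o2 1.232078 0.9254038 1.632517

weights <- rescale_weights(fit, att)             # utilities -> 0..100 weights
farms   <- simulate_farms(qn, weights, n_farms = 50, seed = 4)
score_section(farms, weights, qn, "diagnosis", farm_id = "farm0001")
#> Section 'diagnosis', farm farm0001: 91.77% (570 of max 621; 11 answered, 0 skipped)

all_pct <- vapply(sprintf("farm%04d", 2:50), function(f)
  score_section(farms, weights, qn, "diagnosis", farm_id = f)$pct, numeric(1))
dist <- build_distribution(all_pct, "diagnosis")
classify(91.77, dist)
#> [1] "red"     # p33 = 94.3, p67 = 97.9: a 91.8% farm sits in the bottom third
```

The utilities recovered by the fit track the simulation's true utilities
(highest-utility attributes rank first); the 91.8% section score says the
farm attained 92% of the best attainable weighted answers, yet it is coded
red because this simulated comparator population scores even higher —
traffic lights are relative, not absolute.

The plausibility-correction, movement-benchmark and report stages follow the
same pattern; see `?correct_weights`, `?compute_profile`,
`?benchmark_profile`, `?build_farm_report`, and the methods vignette
(`vignettes/bioscore-methods.Rmd`) for the model details and design
rationale.

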