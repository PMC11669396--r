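---
title: "Methods behind bioscore: weight elicitation, scoring and benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind bioscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioscore)
```

`bioscore` turns a farm biosecurity questionnaire for pasture-based dairy
herds into a weighted, benchmarked audit. This vignette explains the models
and procedures in each stage, the tunable parameters and why their defaults
are what they are, the numerical choices, and what the synthetic-data suite
does and does not demonstrate about real data.

## 1. The questionnaire and its attributes

The instrument has four fixed sections: risk of disease **entry**, speed of
disease **spread** within the herd, **diagnosis** of infection, and a
**resilience**/vaccination section that is recorded but never scored — its
questions are qualitative or disease-specific and do not directly bear on
generic entry or spread risk. Every answer option of a scored question is
rendered as a standalone practice statement (an *attribute*); the attribute
is the unit the expert weights attach to. A question can opt out of
statement derivation (`bws = FALSE`) when its options do not describe a
gradable practice (e.g. a descriptive tick-box); such questions are recorded
but carry no weights and do not enter the scoring sums. This flag is also
how the package's reference-shaped fixture reconciles a 12-question
diagnosis section with 22 derived statements while every question still
offers at least two answer options.

Subcategory tags partition the spread section into sick-to-healthy,
adult-to-young, young-to-young and adult-to-adult contact, and the entry
section into numbers introduced, sources, and practices; tags are assigned
in the questionnaire file, never inferred from wording. The file format is a
single YAML or JSON document (`id`, `sections[]`, `questions[]`,
`options[]`); statements default to "question text — option text" and can be
overridden per option.

## 2. Best-worst scaling designs

Experts see repeated *tasks* of `set_size = 4` attributes and pick the best
(lowest-risk) and worst (highest-risk) practice in each. The design
generator balances pooled appearances across the panel: the attribute list
is replicated to fill all `respondents × tasks × 4` slots, shuffled within
each replicate block, truncated to the exact slot count, and cut into
consecutive tasks; truncating whole shuffled blocks bounds the pooled
appearance spread by one deterministically, and a local repair swaps any
within-task duplicate into another task that accepts it. Task compositions
are shuffled independently per respondent, which makes identical task sets
across respondents improbable without claiming impossible exact
disjointness for small attribute pools. Balance is enforced pooled over the
panel (not per respondent), which is what "appearing an equal number of
times throughout the exercise" operationally requires.

`tasks_per_respondent` defaults to 12 for sections of at most 30 attributes
and 16 for larger ones, matching the 12–16 range used for sections of these
sizes in practice.

## 3. Estimating attribute utilities

Two estimators are deliberately kept side by side, because commercial
MaxDiff platforms rarely disclose theirs:

* **Count scores** (default, transparent): for attribute *i*,
  `s_i = (B_i − W_i) / A_i ∈ [−1, 1]` with `A_i` its appearances in
  answered tasks. Attributes never shown are `NA`-flagged, not scored zero.
  Over a complete response set the best and worst tallies cancel:
  `Σ_i (B_i − W_i) = 0`.
* **Sequential best-worst logit** (MLE): best chosen by a logit over the
  four-item set, then worst by a logit with negated utilities over the
  remaining three; identification by `Σ u = 0`. The likelihood is maximised
  by BFGS followed by analytic-Hessian Newton steps, stopping when the
  gradient max-norm is at or below `1e-8` (the Hessian is ridge-regularised
  along the unidentified location direction; steps are halved if the
  objective would rise). Under complete separation — an attribute best (or
  worst) at every appearance — no finite maximiser exists and the fit falls
  back to count scores with a warning. Ranking ties are broken by attribute
  id for reproducibility.

The two agree in rank order on large balanced panels (Spearman ρ above 0.95
at 200 respondents in the test suite), and both recover a simulated panel's
true ranking exactly at that size.

**Confidence intervals.** The 90% level is the tool's convention. The
interval method is a percentile bootstrap over *respondents* (resampling
whole respondents preserves the panel's clustering), 500 replicates by
default, 5th/95th bootstrap percentiles; intervals are widened where needed
to contain the point estimate so `ci_lo ≤ score ≤ ci_hi` holds by
construction. In a 100-panel simulation the intervals cover the exact
design-conditional expectation of the count score about 90% of the time.

**Quality screen.** Mirroring platforms' "answered too fast" warnings, a
task faster than `min_task_seconds = 2` or a respondent whose median task
time is under `min_median_seconds = 3` can be excluded. The platform's
actual thresholds are not public; both are configurable and the filter is
off unless requested.

## 4. Weight polarity and plausibility correction

Utilities are mapped affinely onto weights in `[0, 100]` per section
(minimum score → 0, maximum → 100). Weights encode **goodness** — a higher
weight is a lower biosecurity risk — so section scores read "higher =
better". Stating all downstream rules under one polarity avoids the
ambiguity that arises when percentile bands are described sometimes over
risk and sometimes over score.

Expert panels occasionally rank a question's options against biological
plausibility. Correction is policy-driven: a YAML file maps each reviewed
question to its plausible order (options lowest-risk first, so weights along
it must be non-increasing) and one of four rules:

* `mean_pair` — an adjacent inverted pair judged similar-risk: both options
  receive the pair mean (question weight sum conserved);
* `clamp_extreme` — a single out-of-place option judged clinically
  distinct: set to the question's current maximum or minimum weight;
* `zero_out` — minor multi-option misordering: the options get weight zero
  and stop contributing to the risk score (the question stays in the
  denominator through its remaining maximum);
* `reorder` — significant multi-option misordering: the question's weight
  *multiset* is re-assigned so the k-th lowest-risk option gets the k-th
  largest weight. Re-assigning the existing values, rather than inventing
  new ones, changes no magnitudes — only positions — which is the least
  interventionist reading of "re-assigned according to the plausible
  ordering".

Rule choice is expert judgement, so the package takes it as input rather
than automating it; `mean_pair` is applied to successive detected inversions
without cascading beyond what the policy asks. With `fallback_reorder =
TRUE` a full pass ends with zero remaining violations. Every action is
logged (rule, options, before/after, parameters) as JSON lines; replaying
the log on the raw table reproduces the corrected table bit-exactly, which
is the audit guarantee.

## 5. Scoring farms

For each answered question the farm's selected options are matched to their
weights; the section score is `100 × raw / max_possible`, the percentage of
the maximum attainable weighted score. Choices the model had to make:

* **Multi-select questions**: contribution is the sum of selected option
  weights, capped at the question's maximum single-option weight, so no
  question can exceed the ceiling its best answer defines and the
  percentage stays well-defined.
* **Skipped questions**: excluded from numerator *and* denominator (and
  counted in `skipped`) by default — scoring non-response as worst practice
  is a policy decision the formula should not smuggle in. The literal
  "maximum possible from all questions" reading is available as
  `denominator = "all"`.
* **Zero-maximum questions** (fully zeroed out in correction) contribute to
  neither sum.

Scores are clamped to `[0, 100]` against floating-point accumulation error.
Subcategory scores apply the same formula restricted to tagged questions;
with disjoint tags their raw/max sums recombine exactly to the section's.
Resilience answers are recorded verbatim by cattle age category (pre-weaned
calves, weaned calves, yearlings, adults), with no numeric field attached.

## 6. Cattle-introduction indicators

Over the half-open window `(reference − 3 years, reference]`:

* **in degree** — movement records onto the farm (each record is one animal
  introduction; repeat moves of one animal count each time, since each
  introduction event is a risk event — `distinct_animals = TRUE` offers the
  alternative reading);
* **inward strength** — distinct source herds;
* **secondary inward degree** — distinct herds moving cattle into those
  source herds within the *same* window, excluding the focal herd,
  deduplicated.

The field's naming is kept in all outputs even though it inverts standard
network usage (this "in degree" is the network in-strength; this "inward
strength" the network in-degree). The second hop uses the same window as the
first because no separate window is defined for it. The implementation is
vectorised subsetting; the test suite checks it for exact agreement against
an independent loop-based two-hop oracle on random networks, plus
window-length monotonicity and record-order invariance.

Benchmarking samples 50 comparator herds (seeded, without replacement) from
the focal herd's enterprise category — category labels are taken as given
input, their derivation being a separate classification problem — and
reports each indicator's 10th/50th/90th percentiles plus the focal herd's
mid-rank percentile position. `comparator_n = "all"` benchmarks against the
whole category instead, since a fixed sample and a full-category summary are
both defensible readings of a 50-herd comparison figure.

## 7. Traffic lights and the report

Section scores are classified against a comparator score distribution at
the 33rd and 67th percentiles: **green** at or above the 67th (best-scoring,
lowest-risk third), **red** at or below the 33rd, **amber** between. Because
weights encode goodness, percentiles are over *scores* and green is the top
third — where a low-risk band is described as "below the 33rd percentile",
that is the same rule stated on the risk scale, and this package documents
the score-scale form as canonical. Boundary scores resolve to red at the
33rd and green at the 67th; in the degenerate case `p33 = p67` (all
comparator scores equal) scores at that value are amber. On distinct scores
this rule is exactly the rank rule "red iff `(rank−1)/(n−1) ≤ 0.33`", so
class shares stay within one farm of a third and classification is
invariant under order-preserving rescaling.

All percentiles in the package (p10/p50/p90, p33/p67) use linear
interpolation between order statistics (`quantile` type 7). The comparator
distribution excludes the focal farm; with fewer than three comparators the
report falls back to score-only mode. The report is a versioned structure
(canonical JSON with stable key order; markdown/HTML renderings; bar-chart
data as plain arrays) whose rendering is byte-deterministic.

## 8. The synthetic-data suite

The generators define the study conditions the tests run under:

* **Questionnaire fixture** — default shape 28/21/12/9 questions yielding
  101/96/22 attributes, a synthetic stand-in for the published instrument
  (texts are placeholders; tags cycle through each section's tag set).
* **Expert panels** — sequential best-then-worst logit choices from known
  utilities (the standard MaxDiff generating assumption; a worst-first flag
  exists for robustness checks), `noise_scale` scaling the choice noise
  (0 = deterministic limit) and log-normal task times (median 8 s).
* **Farm populations** — latent quality θ ∈ [0, 1]; option *i* of a
  question selected with probability ∝ `exp(θ · κ · w̃_i)` with the
  question's weights standardised and sharpness κ = 2, which yields a
  realistic score spread (roughly 20–90%) in the default fixture; θ = 0 is
  uniform answering.
* **Movement networks** — negative-binomial introduction counts per
  herd-year (default mean 5, dispersion 1 — overdispersed trading at toy
  scale), uniform sources, uniform dates, categories by given proportions.

What passing tests show — and do not. The suite demonstrates internal
correctness: estimator consistency and coverage *under the generating
model*, algebraic guarantees of correction and scoring, exactness of the
network metrics, and the benchmarking contracts. It does not validate the
elicitation against real expert behaviour (context effects, attention,
heterogeneous expertise), does not reproduce real herd-size or trade
distributions, and says nothing about the criterion validity of the scores
for actual disease outcomes.

## 9. Problem sizes and reproducibility

Defaults used by the test suite and the acceptance script: rank-recovery
panels of 200 respondents × 12 tasks; coverage studies of 100 panels of 30
respondents with 200 bootstrap replicates; 50 seeded designs and 50 random
networks (up to 200 herds) for the property checks — sizes at which the
stochastic checks are stable across seeds while the whole suite runs in a
few minutes on one CPU. Every stochastic component takes an explicit integer
seed, restores the caller's RNG state, and reproduces byte-identical output
for identical seeds.

## 10. Known limitations

* Expert utilities are pooled panel-level; no hierarchical-Bayes
  individual-level estimates.
* Balanced random subsets only; no D-optimal or Bayesian-efficient choice
  designs.
* No imputation of missing farmer answers, and no disease-specific scoring
  — the tool is deliberately pathogen-agnostic.
* The platform-specific meaning of the original elicitation's "90%
  confidence interval" and speed thresholds is not recoverable; this
  package's bootstrap-over-respondents definition and configurable
  thresholds are its own, documented choices.
* Enterprise categories and movement records are trusted inputs; no access
  layer for a live national register is provided.
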