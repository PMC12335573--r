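---
title: "Methods: simulating and analyzing human-AI confidence alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing human-AI confidence alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`humalign`, in the spirit of a methods section: what each component assumes,
which parameters matter, and what conclusions the synthetic pipeline can and
cannot support.

## The game and its calibration-by-design

The decision task is a card game. Each round has a pile of `pile_size = 65`
cards, a fraction `r` of them red; the participant sees `n_shown = 21`
cards, states a confidence (0–100) that a randomly picked card is red and an
initial guess, then sees the AI confidence and makes a final guess. A
correct final guess wins a point, an incorrect one loses a point, and each
point pays `bonus_per_point = 0.12` GBP (floored at zero).

The AI confidence grid is `a = k/13`, `k = 1..12`. Each level has exactly
two pile types, `r = a − var_a` and `r = a + var_a`, so the 24 pile types
satisfy `P(red | A = a) = a` *exactly* — the picked card is drawn uniformly
from the full 65-card pile, independent of which 21 were shown, which is
precisely what makes the identity hold (`design_calibration_check()` verifies
it in integer arithmetic). Had the pick been restricted to the unshown
remainder, the identity would break under biased display; the full-pile
convention is therefore part of the design, not an implementation detail.

`var_a` must keep `65·r` integral at every level, which confines it to
`{1, 2, 3, 4}/65`. The package defaults to `var_a = 2/65`: the smallest
offset that leaves slack at the extreme levels (`a = 1/13` gives piles with
3 and 7 red cards) while keeping the two piles per level distinguishable
from the shown cards. All quantitative defaults of the design are exposed in
`design_config()`.

## Steering alignment with biased display

The 21 shown cards are drawn sequentially without replacement, each
remaining red card's odds multiplied by a group-specific odds ratio
`ω_g(r, a)`:

* **toward**: `ω = 1/4` if `r > a`, `4` if `r < a` — the shown fraction `z`
  is displaced across `r` in the direction of `a` (and, because the odds are
  strong relative to the small `r − a` offset, well past it);
* **away**: the mirror image, `4` if `r > a`, `1/4` if `r < a`;
* **unbiased**: `ω = 1`, so `z` centers on `r`.

Since participants' confidence tracks `z`, the toward condition makes the
human-confidence signal *anti*-monotone in the true red fraction within each
AI level — conditioned on `a`, a higher-confidence participant is more
likely to be playing the lower-`r` pile — which is what degrades the
alignment of `P(Y = 1 | A, H)`. The away and unbiased conditions leave it
monotone.

The Wallenius distribution is computed two ways that check each other: an
exact `O(n_draws²)` dynamic program over the sequential draw states
(`wallenius_pmf()`, exact for these small piles, no integral approximation)
and a generative sampler that simulates the draws (`wallenius_sample()`).
At `ω = 1` the pmf reduces to the central hypergeometric, which the tests
assert to `1e-10`.

## Synthetic participants

`simulate_cohort()` generates behavior with the statistical structure the
analysis relies on, with all parameters in `behavior_params()`:

* **Initial confidence**: normal around the shown red percentage,
  `round(clip(N(100·z, sigma_initial), 0, 100))`, with
  `sigma_initial = 12` points. The value is chosen so that, per AI level,
  confidence typically spans two of the four confidence bins — enough
  spread to populate the `(a, h)` lattice without decoupling confidence
  from the shown cards. No quantitative claim in the package depends on
  this default.
* **Initial guess**: red above 50, black below, fair coin at exactly 50
  (binning of *recorded* confidences at 50 is resolved by the guess, see
  below; generation and binning are distinct steps).
* **Final guess**: with probability `lapse = 0.02` a uniform coin,
  otherwise red with probability
  `plogis(w_h·(conf − 50) + w_a·(a_shown − 50))`, `w_h = w_a = 0.08` logit
  units per confidence point. This is the simplest form that is monotone in
  both inputs with interior noise; the equal default weights encode no
  prior preference between own and AI confidence.
* **Attention checks**: three trivially answerable rounds (red fractions 0,
  3/4, 1, shown without bias, identical across groups, appended after the
  24 scored rounds at fixed positions). A fraction
  `inattentive_rate = 0.05` of participants answers them with uniform
  confidence; these are the participants the exclusion rule is designed to
  catch. Checks never enter any scored statistic.
* **Cohort structure**: participants are assigned round-robin to batches,
  five per batch at the default sizes (100 participants over 20 batches);
  each batch fixes one game instance `(r, a, z)` per pile type, the
  realigned group reusing the toward group's `z` draws verbatim so the two
  conditions differ only in the displayed confidence.

### What the generator does and does not emulate

The generator reproduces: confidence distributed around the shown
percentage; decisions monotone on average in both confidences; group
differences in the *information structure* (which `(conf, a_shown)` pairs
occur, with which true `r`). It deliberately does **not** model: learning or
adaptation across rounds; individual differences beyond a random level of
attentiveness; asymmetries in how people weigh their own versus AI
confidence; or any dependence of the *decision rule* on the group
condition.

That last omission has a concrete consequence worth being explicit about.
Because the toward and away conditions displace the shown fraction by
mirror-image odds, the joint distribution of (own confidence, displayed
confidence) among initially sub-optimal games is nearly identical in the
two groups — only which pile produced them differs. Any memoryless decision
rule applied identically across groups therefore yields
`θ₀(away) ≈ θ₀(toward)`, and the experimentally observed large advantage of
the away group on initially sub-optimal games can only arise if human
behavior itself differs by group (e.g. participants in better-aligned
conditions learning, within the session, when to defer). Similarly, the
observed small improvement in `θ₁` after realignment is not reproduced by
fixed-weight agents, for whom realignment slightly blurs the
extreme-confidence games that dominate initially optimal play. The
directional checks in the test suite reflect this honestly: alignment-error
orderings and the `θ₀` gains of the unbiased and realigned conditions
emerge from the synthetic model; the away-group `θ₀` gap and the realigned
`θ₁` gain are properties of human cohorts that a memoryless simulator
cannot manufacture, and their checks are expected to fail on synthetic
data. Passing synthetic tests consequently validate the *pipeline* —
metrics, realignment, inference — not the behavioral findings themselves.

## Alignment metrics

Recorded confidence is discretized into four equal regions, very_low
`[0, 25]`, low `[26, 49]`, high `[51, 75]`, very_high `[76, 100]`; exactly
50 goes to high when the initial guess is red and to low otherwise. (The
printed region bounds `[26, 50]`/`[50, 75]` overlap at 50; the tie rule is
what disambiguates it, so internally 50 belongs to neither closed region.)

`outcome_table()` estimates `P(Y = 1 | A = a, H = h)` cellwise on the
(displayed AI confidence) × (confidence bin) lattice. The displayed integer
confidence is used as the AI level for *every* group, including the
realigned one — participants respond to what they see, and it keeps the
groups commensurate. MAE is the largest violation
`P(Y|a,h) − P(Y|a',h')` over comparable ordered pairs (`a ≤ a'`, `h ≤ h'`),
floored at zero; EAE averages the positive parts over all `N` comparable
pairs among included cells, identical pairs included. Both are verified
against exhaustive pair enumeration in the tests.

Two conventions are configurable because the underlying analysis choice is
genuinely open:

* `min_count` for cell inclusion defaults to 1 in `outcome_table()`. For
  study-level comparisons (`analyze_alignment()` in the acceptance checks)
  the package applies `min_count = 10`, extending the sparse-bin omission
  rule used for the heatmap displays ("bins with 10 or less data points")
  to the metric cells: MAE is a maximum statistic, and singleton cells with
  estimates of exactly 0 or 1 otherwise dominate it with pure noise in
  *every* group. Even so, at ~100 participants per group MAE remains a
  noisy maximum; EAE, an average, is the more stable ordering statistic —
  consistent with the EAE gap between conditions being far larger in
  relative terms than the MAE gap.
* Filtering: alignment metrics are computed on attention-check-filtered
  records, mirroring the utility analysis.

## Realignment by uniform-mass multicalibration

`fit_realignment()` post-processes the AI confidence to be calibrated
within every human-confidence subgroup. Per confidence bin `h`: add uniform
noise in `[0, 1e-10/(1+1e-10)]` to the discrete AI confidence values (the
noise exists solely to break ties on the 12-level grid; it is added at both
fit and deployment time), place bin edges at the empirical `k/5` quantiles
(`k = 1..4`, type-7 quantiles; 5 uniform-mass bins), and store as the bin
output the mean *true* red fraction of the calibration games in the bin —
the true fraction rather than the binary outcome, because it is the
conditional mean of the outcome and so estimates the same quantity with
strictly smaller variance. Deployment (`apply_realignment()`) locates the
noised confidence in left-closed, right-open bins (last bin closed);
out-of-range values clamp to the extreme bins, a safety convention only,
since the deployed grid equals the training grid. Realigned values shown to
synthetic participants pass through the same integer display rounding as
the original confidence.

The calibration cohort (302 participants on 60 toward-bias batches by
default) is filtered by the attention-check rule using its own check
statistics before fitting, and the fit pools all calibration batches — the
finest stratification the held-out sample supports at five bins per
subspace.

## Utility analysis

The optimal guess depends only on the pile: `π*(r) = red ⇔ r > 0.5` (no
design pile sits at 1/2; by construction the displayed AI confidence always
leans toward `π*`). `Q` and `Q′` indicate whether the initial and final
guess match `π*`, and the conditional matching rates `θ₀ = E[Q′ | Q = 0]`,
`θ₁ = E[Q′ | Q = 1]` are estimated from per-participant binomial counts by

```
Q′ | trials(Q′) ~ 0 + g * Q + (1 | participant)
```

with a logit link: one fixed effect per (group, Q) cell — no global
intercept, so no reference group is privileged — and a participant random
intercept. Priors are standard normal on the fixed effects and half-normal(1)
on the random-intercept SD (the closest faithful truncation of "standard
normal for all parameters" to the SD's support). Sampling is by Gibbs/JAGS,
4 chains, 1000 adaptation + 2000 burn-in + 2500 retained iterations per
chain (10,000 draws). Convergence requires split-R̂ < 1.01 on all fixed
effects; the sampler extends the chains up to twice before raising a
diagnostic error. `θ_{g,q} = plogis(β_{g,q})` is reported at random
intercept 0 — the population-median participant — which is the quantity the
no-intercept fixed-effect parameterization makes directly recoverable.

`hypothesis_evidence()` computes one-sided posterior evidence: the estimate
is the posterior mean difference in `θ`, the evidence ratio the posterior
odds `p/(1 − p)`; when every draw satisfies the hypothesis the ratio is
reported as exceeding the draw count rather than as a sharp number.

Two models are fitted, mirroring the two-part comparison structure: one for
toward/away/unbiased and one for toward/realigned. `boschloo_test()`
provides the matching frequentist exact analysis: Boschloo's unconditional
test with Fisher's one-sided p as ordering statistic, the supremum over the
common success probability taken on a fixed 1001-point uniform grid (a
deterministic, reproducible stand-in for nuisance optimization; accurate to
~1e-4, and validated against an independent implementation).

The attention-check exclusion rule flags a participant on a check when
their confidence is more than one SD from that check's mean over the
reference population (all deployed groups pooled, or the calibration cohort
alone when filtering it), and excludes on more than one flag. A zero-SD
check degenerates — any deviation then flags — and triggers a warning.

## Problem sizes and runtime choices

The packaged study conditions are 100 participants per deployed group
(24 scored games plus 3 checks each) and 302 calibration participants,
matching the experimental cohort sizes; simulation takes ~1 s and each
MCMC fit a few seconds on one core. Distributional checks of the Wallenius
sampler use 1e5 draws (total-variation tolerance 0.01, which is ~6 SEs at
that size); behavioral monotonicity checks use cohorts of ~1e4 records,
where the isotonic violation mass of the decision heatmap stays below 0.02.

## Known limitations

* The behavior model is memoryless and group-invariant; see above for which
  experimental effects this excludes by construction.
* MAE on ~2000-game groups is a maximum of noisy cell estimates; orderings
  based on it are seed-sensitive even with the sparse-cell rule. Prefer EAE
  when ranking conditions.
* The Bayesian model conditions on the median participant (random intercept
  0) rather than marginalizing over the intercept distribution; with the
  logit link the two differ slightly for extreme rates.
* `boschloo_test()` enumerates the full outcome grid; it is intended for
  the per-participant-scale counts that arise here, not for trials in the
  thousands.
* Realigned-group alignment tables have at most 20 AI levels (4 bins × 5
  outputs, before display rounding), so their pair lattice `N` is smaller
  than in the other groups; `n_pairs` is reported alongside every summary
  for that reason.
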