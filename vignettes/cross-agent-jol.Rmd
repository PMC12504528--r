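---
title: "Cross-agent prediction of recognition memory from judgments of learning"
author: "jolcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-agent prediction of recognition memory from judgments of learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jolcross)
```

## The question

A judgment of learning (JOL) is a prospective rating of how likely a
just-studied item is to be remembered later. Under the cue-utilization view,
JOLs are inferences from cues — here, chiefly the semantic relatedness between
a garden-path sentence and the context sentence that precedes it — rather than
direct readouts of memory strength. `jolcross` implements a *cross-agent
prediction* analysis: do an agent's per-item JOLs predict *human* recognition
memory, where the agent is either the humans themselves or a stochastic large
language model queried repeatedly about the same sentence pairs?

The pipeline mirrors a within-subject study design: participants study 22
context/garden-path sentence pairs (half in a fitting context, half in an
unfitting one), give relatedness and JOL ratings on 1–10 scales, and then take
a 44-item old/new recognition test (22 targets, 22 distractors). Machine
raters answer the same two prompts for every sentence pair in both contexts,
100 stochastic replicates per pair at sampling temperature 1.

## Design construction

`build_item_bank()` generates placeholder garden-path materials from templates
("Because *name* *verb*s *noun* is never kept in the house."); real materials
can be substituted via any data frame with the same four columns. The
counterbalancing in `assign_counterbalance()` is a 4-group Latin-square
rotation: after omitting one item (id 8 by default for human designs, whose
structure duplicates another item's), the remaining 44 items form four fixed
groups of 11; condition *c* studies group *c* in the fitting context and the
next group cyclically in the unfitting context, leaving two groups as
distractors. Participants cycle through conditions in recruitment order
(index mod 4). This is the simplest scheme that makes every item a fitting
target once, an unfitting target once, and a distractor twice across the four
conditions; the 11 + 11 per-participant split follows from the rotation's
symmetry. The rotation itself is not uniquely determined by the balance
requirement — any Latin square over the four groups would do — and sequential
condition assignment is an assumption.

`apply_exclusions()` reproduces a recruitment cascade (incomplete sessions,
vision screening, other reasons) with removals attributed to the first
applicable reason; the retained *set* is order-invariant, only the
per-reason attribution depends on the fixed order.

## The synthetic cohort generator

`simulate_human_cohort()` is a first-class module, not a test fixture: it
defines the statistical structure every downstream stage is validated
against. For each studied trial of subject *s*, item *i*, context *c*:

1. a latent relatedness cue `r` is drawn, with a higher mean in the fitting
   context (defaults 7.2 vs 4.8 on the 1–10 scale, SD 1.6);
2. a latent memory strength `m = logit(base[c]) + (u_s + w_i) * k + e` is
   drawn, where `u_s, w_i` are subject and item intercepts on the accuracy
   scale (SDs 0.06 and 0.05) rescaled to logits by `k = 1/(p(1-p))` at the
   grand mean accuracy, and `e` is trial noise (SD 1 logit);
3. the JOL is a convex combination of the standardized cue and standardized
   memory signal with weight `jol_relatedness_weight` (default 0.85) on the
   cue, mapped to the 1–10 scale (context means 6.4 / 5.2, SD 1.7) and
   discretized by round-half-up-then-clamp;
4. recognition correctness is Bernoulli with probability
   `base[c] + slope[c] * z(JOL) + u_s + w_i`, clamped to [0.01, 0.99], with
   `z()` standardizing within context; distractors are correct rejections
   with probability 0.75 (distractor trials never enter JOL models, since
   JOLs exist only for studied items).

Two generator decisions deserve emphasis.

**Slopes are injected per SD of JOL, on the linear probability scale.**
Slopes of order 0.1–0.17 per *raw* scale point would be impossible for a 0/1
outcome across nine scale points, so all slope parameters, estimates and
recovery targets in this package are defined on the standardized-JOL scale,
with JOLs z-scored within agent × context. Injection on the probability
scale (rather than the logit scale) makes the linear slope model used inside
the bootstrap recover the injected value exactly, up to clamping.

**Base accuracies default to 0.66 (fitting) and 0.56 (unfitting).** The
context effect on recognition accuracy is a core feature being emulated, and
the default fitting-context slope is 0.167 per SD of JOL. A higher fitting
base accuracy (say 0.80) would push `0.167 * z(JOL)` against the 0.99 ceiling
for a substantial share of trials and attenuate the realized slope by ~0.015;
at 0.66 the attenuation is ≈0.005 with about 4% of fitting trials touching
the ceiling, while both accuracies stay in the range typical of old/new
recognition with a 10-point context advantage. This is a deliberate
trade-off: a small amount of ceiling clamping is accepted to keep the
accuracies realistic and ordered (fitting above unfitting).

With the default mnemonic weight 0.15, JOLs carry a weak *structural* link to
accuracy through the shared intercepts even when all slope parameters are
zero; the pure null used in calibration tests sets
`jol_relatedness_weight = 1`, making JOLs cue-only and outcome-independent by
construction.

`sample_agent_ratings()` emulates the stochastic machine rater: each item ×
context gets a latent mean rating (relatedness higher in the fitting
context), and each replicate adds noise with SD `temperature *
within_item_sd` before round-half-up discretization, so temperature 0
collapses replicates to a point. By default `link_slope = 0`: machine rating
means carry no item-level information about human outcomes, which is the
null the cross-agent comparison should detect. The two prompt templates are
shipped as text assets with `{sentence1}`/`{sentence2}` slots so a live API
adapter could replace the mock backend unchanged; how a real backend should
parse free-text replies (first integer token in 1–10, otherwise resample) is
an explicit extension point, since the mock backend always emits integers.

## The confirmatory mixed model

`fit_binomial_glmm()` fits the logistic crossed random-intercept model

```
correct ~ z(jol) * context + (1 | subject) + (1 | item)
```

on target trials, by Laplace-approximated maximum likelihood (lme4). Context
is coded sum-to-zero (fitting = +1, unfitting = −1) and JOL standardized
within context, so the JOL and context main effects remain interpretable in
the presence of the interaction. `type2_anova()` tests each term after all
others except those containing it; under this orthogonal coding that is a
Wald chi-square on the term's own coefficients, `b' V⁻¹ b`, with df equal to
the term's coefficient count. The test suite pins the estimation through
independent oracles rather than a specific optimizer: exact Gauss–Hermite
quadrature over both random effects on tiny fixtures (agreement within 0.1
on the log-likelihood — the Laplace approximation's honest error on small
clusters, orders of magnitude above machine precision), reduction to plain
logistic regression when both variances are pinned to zero, and car's Wald
table as a cross-check.

## The cross-agent bootstrap

`pair_agent_with_human()` builds the analysis substrate per agent × context.
Human rows pair each subject's JOL with *that subject's own* binary
correctness for the item. Machine rows pair each replicate's JOL with the
human cohort's per-item accuracy proportion — the question is prediction on
a per-item basis, and pairing replicates with individual human trials would
only replicate those proportions with inflated row counts.

`run_bootstrap()` implements a structured (cluster) bootstrap: each of the
1,000 default iterations resamples units (subjects or replicates) with
replacement and items with replacement, assembles the surviving crossed
rows with fresh cluster identities, and refits the Gaussian crossed
random-intercept slope model `y ~ z(jol) + (1|unit) + (1|item)` by REML
(`fit_slope_lmm()`). A linear model is used even for the binary human
outcome so that slopes are comparable across the human (binary) and machine
(proportion) outcome scales. The point estimate *B* is the mean of the slope
draws; the interval is the percentile interval (no bias correction — the
plain percentile interval matches the summary being emulated), and an agent
"predicts" when the interval excludes zero. Iterations whose fit fails or
does not converge are dropped and counted, never imputed. In practice a few
percent of machine-agent iterations fail when an item resample makes the
residual variance collapse.

`resample_mode = "permute_null"` is a diagnostic, not an interval method: it
shuffles JOLs within each unit and refits on the intact design, yielding a
null distribution for the *within-unit* association. Because within-unit
shuffling preserves each unit's mean JOL, any unit-level JOL–outcome
association survives permutation — including the finite-cohort accident of
one, even when the generating process has none — so the permutation
distribution centers on the realised between-unit component rather than
exactly on zero; on data with a trial-level slope it removes most, but not
all, of the association. Cluster resampling is the
default and the only mode used for confidence intervals.

Sub-seeds for each agent × context cell are derived from the master seed by
hashing a label ("bootstrap:agent:context") into a 31-bit integer
(`derive_seed()`), so `compare_agents()` is reproducible end to end while
cells get distinct RNG streams.

### A known degeneracy of the machine pairing

Because every replicate of an item shares the item's outcome, the item
random intercept absorbs *all* outcome variance in machine-agent fits; the
within-iteration slope is exactly zero up to solver precision, and the
machine slope distributions are near point masses at zero rather than wide
null distributions. The qualitative contrast (humans predict, unlinked
machine raters do not) is unaffected, but interval *widths* for machine
agents are not comparable to those from analyses that pair machine JOLs with
trial-level outcomes. Relatedly, the zero-inclusion decision treats interval
endpoints within `sqrt(.Machine$double.eps)` of zero as including zero, so
solver noise of order 1e-14 cannot masquerade as a significant effect.

## Power analysis

`required_n()`/`achieved_power()` implement the a-priori planning step: the
smallest *n* for which a two-tailed matched-pairs t-test (the within-subject
context manipulation reduces to a one-sample test on paired differences) at
α = 0.001 reaches power 0.95 for Cohen's d = 0.62, using the exact
noncentral-t distribution with noncentrality `d√n` and df `n − 1` — no
normal approximation. The defaults give n = 69. The test family is an
assumption; the original planning tool is not specified beyond its inputs,
and a different family could shift n by a couple of participants.

## Numerical choices

- Rating discretization uses round-half-up (`floor(x + 0.5)`), not banker's
  rounding, then clamps to 1–10.
- All generators and the bootstrap restore the caller's RNG state; a given
  seed reproduces byte-identical tables and draws.
- Constant-outcome inputs to `fit_slope_lmm()` return a degenerate fit
  (slope 0, zero variances, flagged) rather than an error, so bootstrap
  iterations on pathological resamples are counted, not fatal; a constant
  JOL predictor is refused outright.
- Groupings with a single level have their variance fixed at zero (the
  random term is dropped); with both dropped the fit is OLS, and pinning
  variances explicitly reproduces OLS / plain logistic regression exactly.
- lme4 is run with derivative-free convergence checking inside the
  bootstrap's inner loop; convergence warnings mark the iteration as failed.

## Validation scale

The simulation-based checks in the test suite run at deliberately chosen
sizes: recovery of the injected human slopes uses study-sized cohorts (78
subjects × 22 items) with 200 bootstrap iterations; the coverage study uses
200 cohorts of 32 subjects over a 20-item bank with 100 iterations each; the
end-to-end human-vs-machine contrast uses four full replications of the
whole pipeline at 40 iterations per agent × context. The acceptance script
(`scripts/acceptance.R`) runs the slope recovery at the full 1,000
iterations. These sizes keep Monte-Carlo error well inside the tolerances
being asserted (±0.03 on recovered slopes) without burning time on
precision the assertions do not need.

## What passing tests do and do not show

The generator emulates the *structure* the analysis assumes: a context
effect on accuracy, a positive within-person JOL–accuracy slope on the
standardized scale, crossed subject/item heterogeneity, and machine raters
with context-sensitive relatedness but no item-level link to human outcomes.
It does not emulate real garden-path materials, item-specific semantics,
response times, serial-position or fatigue effects, or any dependence
between a machine model's rating distribution and human memorability beyond
the optional `link_slope` hook. Passing recovery and contrast tests
therefore show the estimators and decision rules behave correctly under the
assumed structure — not that the substantive findings would replicate on new
human data.
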