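---
title: "Methods: models, gates and design choices in zfetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, gates and design choices in zfetr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfetr)
```

This vignette explains the statistical machinery of the package, the
assumptions behind it, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

A ZFET experiment exposes zebrafish embryos to a chemical dilution series
and scores each embryo at fixed times (hours post fertilization, hpf)
against a controlled vocabulary of 52 morphological effects. Observations
are stored long: one row per embryo × time × effect, with a single
"normal" row when no abnormality is seen. Two structural rules are
enforced at validation time because every downstream denominator relies on
them: "normal" excludes any concurrent effect for the same embryo and
time, and "coagulated" (the dead, opaque embryo — the sole lethal
endpoint) is absorbing, so only "coagulated" or "no embryo" may follow it.
"no embryo" terminates an embryo's record; such embryos leave all later
denominators. Each vocabulary term also carries the developmental window
in which it is observable (inclusive on both ends, e.g. hatching-related
terms only from 48 hpf); observations outside a term's window are
rejected (strict mode) or dropped with a count (lenient mode).

Category semantics follow the term identities of the packaged vocabulary:
id 2 ("coagulated") is lethal, id 3 ("normal") normal, ids 1 and 16
("no embryo", "miscellaneous") uninformative, ids 26 and 41 ("hours post
fertilization", "beats per minute") quantitative, everything else
sublethal. User-extended vocabularies must declare categories explicitly,
because nothing about a new term's name tells the code its role. Effects
are never rolled up from child to parent terms: observations are analysed
at the granularity recorded, since real fingerprints mix parent-level and
child-level annotations.

## Control quality gating

Unexposed embryos show background abnormalities, so experiments whose
controls look unusually bad must be excluded. A fixed percentage cutoff
treats a 9-embryo control group and a 60-embryo one identically; the
binomial gate does not. With `p_normal = 0.936` (the pooled fraction of
control embryos "normal" at their experiment's final observation; the
pooled survival analogue is 0.959), the number of normal controls k among
n is tested one-sided against X ~ Binomial(n, 0.936) via the exact lower
tail P(X ≤ k). Experiments with p < 0.05 are removed, as are experiments
with fewer than 9 control embryos (too little power to detect bad
controls at all). P-values are deliberately **not** multiplicity-adjusted:
the analysis keeps experiments for which the null is *not* rejected, so
adjustment would admit more marginal experiments and inflate the type II
error; `adjust_pvalues = TRUE` exists but logs its use as a deviation.
Solvent controls and plain controls are pooled — both are unexposed in
the relevant sense. "Final time point" means each experiment's latest
time with any control records, because experiment durations differ; only
the final observation enters the test. The classical 90 %-survival rule
is available behind `survival_gate = TRUE` for comparison, not as the
default. Before any of this, experiments with fewer than 15 embryos or
only one experimental condition are dropped outright.

## Dose–response models

Responses are grouped binomial counts per concentration: under the
*lethal* endpoint an embryo is affected iff coagulated; under the
*cumulative* endpoint iff it shows anything but "normal". Three
two-parameter families are fitted to p(c) with slope b and location e
(µmol/L): log-logistic `LL2`, and the two Weibull forms `W12`/`W22`
(asymmetric around their inflection in opposite directions). Monotone
increase with concentration is imposed by the sign of b (negative for
LL2/W12, positive for W22), since an effective concentration is only
interpretable for an increasing response.

Controls are excluded from the likelihood: the two-parameter curves force
p(0) = 0, so control-level background abnormality would degenerate the
fit — control quality is handled by the gate above instead. Replicate
experiments with identical design (substance, endpoint, exposure start,
observation time) are pooled without random effects.

Numerics: optimisation runs in (b, ln e) via Nelder–Mead with multiple
starts (ln e at the concentration bracketing 50 % observed response and
at the log-midpoint of the range; |b| over 0.5, 1, 2, 4), keeping the
best; probabilities are clamped to [1e−12, 1 − 1e−12] inside the
log-likelihood; the (b, ln e) covariance is the inverse observed
information (`stats::optimHess`) at the optimum. All-affected or
none-affected data are flagged degenerate and not fitted. A fit whose
optimiser did not formally converge can still enter AIC comparison (its
likelihood is what it is) but carries "no convergence" as an invalidity
reason — on exactly flat data the sigmoid optimum lies at the b → 0
boundary, and the informative verdict is the flat-null gate below, not a
bare convergence failure.

The lowest-AIC family wins, with ties below 1e−6 broken in the fixed
order LL2, W12, W22 for determinism. The grouped binomial likelihood
includes the binomial coefficients; AIC *differences* between families
are invariant to that constant, which the tests assert. A selected model
is **valid** only if (i) its AIC is below that of a constant-probability
(slope-0) null, (ii) the predicted EC50 is below the highest tested
concentration (no extrapolated potency claims), and (iii) SE(EC50) <
EC50. ECx values invert the curve in closed form,
ln ECx = ln e + g(p)/b with the family-specific g, and get delta-method
standard errors from the (b, ln e) covariance. The sensitivity ratio
SR = LC50/EC50 is reported only when both component fits are valid —
absent otherwise, never zero.

## Phenotypic fingerprints

A substance's fingerprint is the vector of effect prevalences among
affected embryos. To blunt the influence of each study's arbitrary
concentration choice, only embryos exposed between the EC5 of the
cumulative fit and the LC99 of the lethal fit enter (inclusive bounds);
when no valid lethal model exists the window is open above. Windows are
computed per exposure-start design and the windowed embryos pooled across
designs for the substance. Normal embryos are excluded, and each
qualitative effect's proportion is computed among the rest — proportions
do not sum to one because embryos carry multiple effects. Quantitative
and uninformative terms never appear in the vector. Fingerprints from
fewer than 30 embryos are dropped first; then effects with mean
prevalence below 1 % across the remaining substances are dropped
(row filter before column filter — the order matters and is asserted by a
test fixture). Substances are clustered with Ward's minimum-variance
criterion on Euclidean distances (`hclust(method = "ward.D2")`, the Ward
criterion on untransformed Euclidean distances), default k = 6.

Effect importance comes from a PCA of the fingerprint matrix, centred but
**not** scaled to unit variance — all columns are already proportions on
a common scale, and scaling would inflate rare effects. An effect's
importance is the Euclidean norm of its contributions to the first five
components. "Contribution" is ambiguous between raw loadings and
variance-weighted loadings; both are implemented
(`method = "loadings"` / `"variance"`), defaulting to variance-weighted
(loading × component standard deviation) because raw rotation rows all
have unit norm at full rank, which makes the unweighted variant
discriminating only when fewer components than the rank are used.
Importance is invariant to component sign flips by construction.

## Effect propagation

How effects at 48 hpf relate to effects at 96 hpf in the *same* embryos
is read off a paired indicator table: only well-plate experiments
(24/48/96-well) allow tracking individuals across observations, so only
they enter; control embryos are excluded; embryos must be present (not
"no embryo") at both times and carry consistent well coordinates
(mismatches are dropped with a count). Pearson correlations are computed
between every qualitative 48-hpf indicator and every 96-hpf indicator,
with two-sided p-values from the t statistic on n − 2 degrees of freedom
and a significance mask at p < 0.01, unadjusted (sidedness is a design
choice here; two-sided is the conservative default). Zero-variance
columns yield flagged undefined entries, never a silent zero. The heatmap
ordering uses complete-linkage hierarchical clustering on Euclidean
distances — display machinery only, not analysis, with undefined entries
imputed as zero for ordering alone.

## The synthetic-study generator

`simulate_study()` produces studies in the package's own data model with
full ground truth, emulating the archive-scale designs the methods were
built for: by default 7 log-spaced concentrations spanning the true
curves, 12 embryos per concentration plus 11 controls (95 embryos per
experiment), exposure from 0 hpf, observations at 48 and 96 hpf in
96-well plates, and a control normal probability of 0.936 (survival
0.959 when control mortality is modelled). Four effect archetypes — a
coagulant, a hatching/cardiovascular profile with a planted "decreased
heartbeat" → "no heartbeat" worsening, a hypopigmentation profile and a
behavioural one — supply true lethal and cumulative curves, conditional
effect profiles and transition rules.

Per embryo, a single latent uniform drives both endpoints: coagulated if
it falls below the lethal curve value scaled by the fraction of exposure
time elapsed (1 at the final observation), affected if below the
corresponding cumulative value (taken at least as large as the lethal
one). This makes lethality imply affectedness and both absorbing over
time by construction, and leaves the *marginal* response at the final
observation exactly the planted curve — which is what the recovery tests
measure. Effects are drawn once per embryo from the archetype profile and
shown wherever their vocabulary window allows; a planted worsening
replaces its precursor at the final observation only if the precursor was
actually shown earlier in that embryo, keeping the planted 48 → 96
correlation specific. Control abnormalities never include coagulation
unless control mortality is explicitly modelled. Experiments planted with
degraded controls use a normal probability of 0.2, low enough that the
binomial gate fails them with near certainty at typical control counts,
so planted-failure bookkeeping is deterministic in effect.

What the generator does **not** emulate: toxicokinetics (uptake,
metabolism — the time ramp is a linear stand-in, not a hazard model),
inter-clutch random effects on control quality, scorer disagreement,
mixture effects, or continuous-time death. Passing tests therefore show
that the pipeline recovers what it assumes, under clean binomial
sampling; they do not certify behaviour under model misspecification
found in real archives.

## Problem sizes and tolerances

The test suite and acceptance script work at sizes chosen to make the
statistical assertions sharp while keeping a full run in minutes: EC50
recovery uses 200 simulated studies per family at 50 embryos per
concentration over 7 concentrations spanning e/30–30e (asserting ≤ 10 %
median relative error and 0.85–0.99 CI coverage); gate calibration uses
10,000 simulated control groups; pooled-rate convergence uses ≥ 10,000
control embryos; archetype recovery uses 4 archetypes × 5 substances × 3
replicate experiments — mirroring the ~3 experiments per substance and
~130 embryos per fingerprint that archive-scale pooling provides — and
asserts adjusted Rand index ≥ 0.9; transition recovery uses 100 seeded
single-substance studies. Exact quantities (binomial CDF, ECx inversion,
correlation entries) are checked against independent brute-force oracles
at 1e−12–1e−10.

## Known limitations

* Pooling replicate experiments ignores between-experiment
  heterogeneity; a random-effects dose–response model is out of scope.
* The EC5–LC99 window is estimated, not known, so fingerprint windows
  inherit fit uncertainty; steep, data-poor fits can collapse the window
  and exclude a substance.
* The Weibull families are asymmetric: model selection on small samples
  can pick a family whose EC50 is mildly biased relative to the
  generating one — the validity gates bound, but do not remove, this.
* Only cross-time correlations are produced by the propagation module;
  within-time co-occurrence is visible in fingerprints instead.
* Concentration units are fixed at µmol/L; molar-mass conversion belongs
  to data preparation, not to this package.
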