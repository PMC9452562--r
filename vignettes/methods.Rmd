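---
title: "Methods: preclinical response calling and CDK4/6-inhibitor resistance biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preclinical response calling and CDK4/6-inhibitor resistance biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdkresist)
library(dplyr)
```

`cdkresist` implements the computational layer of a preclinical
drug-response study in breast-cancer patient-derived xenografts (PDX):
tumor-volume response calling, a composite immunohistochemistry (IHC)
resistance classifier, ex vivo readouts, biallelic gene-inactivation
("double hit") calling with exposure-association models, and qPCR
normalization. Every stage consumes and produces plain tibbles, so the
whole pipeline is scriptable with dplyr verbs; seedable generators emulate
each input, which is what makes the package testable without animals,
slides, or controlled-access genomes.

## Tumor growth and mRECIST-like response calling

Caliper measurements (length, width, in mm) are converted to volumes with
the ellipsoid approximation \(V = (L \times W^2)\,\pi/6\); the smaller
dimension is squared, and ingest enforces \(W \le L\) by swapping. The
percent volume change of a tumor at day \(t\) is
\(100\,(V_t - V_0)/V_0\) against its day-0 baseline.

Responses are banded like clinical RECIST, on the best (most negative)
percent change: CR at \(\le -95\%\), PR in \((-95, -30]\), SD in
\((-30, +20]\), PD above \(+20\%\). Boundaries are closed on the
sensitive side. Two choices here were genuinely open:

* **Best-response window.** The best response is taken over measurements
  from day 10 onward (`min_day = 10`, configurable). With twice-weekly
  measurements starting at day 0, a whole-window minimum is degenerate:
  even a briskly progressing tumor has barely moved from baseline at its
  first post-baseline measurement (~day 3), so its "best" change would sit
  near zero and everything would classify as SD. Restricting to
  \(\ge 10\) days matches how preclinical mRECIST analyses define best
  response. The day-35 change is always reported separately, since cohort
  waterfalls plot that value.
* **Missed measurement days.** An exact-day measurement is preferred;
  otherwise the nearest within \(\pm 3\) days is used; otherwise the tumor
  is not evaluable for that endpoint.

Relative tumor volume (RTV \(= V_t/V_0\)) is banded PD \(> 1.2\),
SD \(0.7\)–\(1.2\), PR/CR \(< 0.7\) for longitudinal plots. A printed
source for these bands gives the lower bound as "−0.7"; since an RTV is a
ratio of volumes and cannot be negative, the band is read as 0.7.

Cohort summaries count classes over evaluable calls and report the
preclinical response rate pRR \(= 100\,(CR+PR)/n\) and benefit rate
pCB \(= 100\,(CR+PR+SD)/n\), both exact and rounded half-away-from-zero
to integers for report parity. The standard error of a mean percent
change is a bootstrap SE: the SD of 2000 resampled means, deterministic
given a seed. Model-level calls (`model_response_calls()`) average the
per-day percent change across a model's tumors before banding, mirroring
how replicate tumors are aggregated in waterfall plots.

```{r growth-example}
g <- sim_growth_cohort(synthetic_config(seed = 1))
calls <- model_response_calls(g$measurements, arms = "treated")
glance(cohort_summary(calls))
```

## The composite IHC resistance classifier

Panels carry p16 and total pRb as semiquantitative 0–4 scores, cyclin E1
and cyclin D1 as Allred 0–8 scores (proportion bin 0–5 plus intensity
0–3), the PAM50 intrinsic subtype label, and optionally KI67. The
composite rule predicts CDK4/6-inhibitor resistance when any of the
following fires, in order: Basal-like subtype; p16 \(\ge 2\);
pRb \(\le 2\); cyclin E1 \(> 4\) or cyclin D1 \(> 6\). The order only
determines which rule is recorded as having fired — the binary call is
order-invariant. The cyclin cutoff pair "4/6" is assigned E1 → 4,
D1 → 6, following the marker order in which the cutoffs are stated. A
missing score cannot fire its rule; a panel is unclassifiable only when
all four scores are missing. "Normal-like" subtype never fires the basal
rule.

Cutoffs are the defaults of `default_cutoffs()` and were originally
selected by the Youden index \(J = \text{sens} + \text{spec} - 1\).
`youden_cutoff()` maximizes \(J\) over all achievable thresholds; ties
are broken toward the highest sensitivity, then the lowest threshold —
the screening-oriented convention, since the classifier's purpose is to
catch resistant tumors. Concordance against observed response reports
sensitivity, specificity, accuracy, PPV and NPV from the 2×2 table with
"resistant" as the positive class.

Two KI67 rules from the neoadjuvant setting are included: the Luminal
A/B split at KI67 < 15%, and the antiproliferative response rule
"ln KI67 < 1 at day 15" (sensitive below, i.e. on-treatment KI67 under
\(e \approx 2.72\%\)). The log is taken of the percentage as printed,
not of a fraction — ln 15 ≈ 2.7 must classify a typical Luminal B
baseline as non-responding. A KI67 of exactly 0 (log undefined) is
clamped and flagged, and called sensitive.

Continuous H-scores (0–300) from clinical cohorts are analyzed with
`or_per_sd()`: a univariate logistic regression on the z-scored marker,
reporting the odds ratio per SD with a Wald CI. H-scores and ordinal
scores are distinct types; nothing converts implicitly between them.

## Ex vivo readouts

Spheroid areas are aggregated per model and condition (mean by default,
median optional) and normalized to the vehicle mean; the response value
is the percent change from 100%. EdU incorporation is the percentage of
EdU-positive nuclei, relativized to vehicle the same way. Cultures are
called sensitive at a change \(\le -25\%\); the boundary is inclusive,
a choice the source statement of the cutoff leaves open. ROC analysis of
the area change uses the low-is-positive direction (sensitive cultures
shrink more) and the same Youden machinery; the AUC is trapezoidal and
equals the Mann–Whitney statistic by construction.

Dose plates are normalized day-6-over-day-0 first, then to vehicle
growth, in that order. The four-parameter logistic fit runs on
\(\log_{10}\) dose by Levenberg–Marquardt least squares on the percent
scale, with starts from data quantiles and a sign-free hill slope. Tiny
(\(<10^{-8}\)) start values are snapped to zero — a relative-step
numerical gradient degenerates at such values — and a short deterministic
cascade of perturbed starts guards against rank-deficient solutions on
noiseless or rising curves. The IC50 is defined as the dose where the
fitted curve crosses 50% of control growth; if the curve never crosses
50% within the dose range, the fit carries `not_reached = TRUE` and no
extrapolated IC50 is ever reported.

## Variant, copy-number and double-hit calling

Mutation status comes from a controlled consequence vocabulary. The
`hmf_coding` rule set accepts nine coding classes (frameshift, stop
gained, splice acceptor/donor, start lost, stop lost, missense, inframe
deletion/insertion); `deleterious_truncating` keeps only the clearly
truncating subset. When no consequence term is present,
`parse_protein_change()` infers one from the HGVS-protein string with
minimal pattern rules (`fs*N` → frameshift, trailing `*` → stop gained,
`_splice` → splice variant, simple substitution → missense); it never
errors, returning "unknown" for anything else. A generic splice variant
(acceptor vs donor unrecoverable from the string) counts as splice under
both rule sets.

Deletion status prefers allele-specific copy number: homozygous deletion
when minor and major allele CN are both below 0.01, heterozygous when
only the minor is. When only a log-ratio is available the bands are
deep deletion \(< -1\), shallow \([-1, -0.4)\), unaltered \(\ge -0.4\)
(gains collapse into "unaltered"). When both representations are present
the allele CN wins — the two encodings come from different data dialects
and the allele-specific one is the more direct zygosity measurement.

A **double hit** is a qualifying mutation on top of a heterozygous
deletion — biallelic inactivation. Any qualifying variant sets the
mutation flag (presence, not burden). The association with treatment
exposure is fitted two ways, since the exact model pair used upstream is
not printed: M1, `exposed ~ mutation * deletion`, whose interaction term
is the headline statistic (the excess exposure-association of the joint
state beyond the single alterations); and M2, `exposed ~ double_hit`,
with one indicator. On cohorts generated without marginal effects both
agree in the sign of the double-hit effect.

Logistic fits use IRLS with tolerance \(10^{-8}\) and at most 100
iterations; inference is Wald throughout (z from the normal
approximation, CI = estimate ± 1.96 SE), matching how such models are
conventionally reported in this setting. Separation is detected after
fitting (non-convergence at boundary, exploding coefficients or SEs) and
estimates are withheld rather than reported at a divergence point.

## qPCR normalization

Reference genes are ranked by the geNorm stability measure M: with
amplification efficiency fixed at 2 (comparative Ct without efficiency
correction), the log2 expression ratio of genes \(j,k\) in a sample is
\(Ct_k - Ct_j\), and \(M_j\) is the mean SD of those ratios across
samples over all partners \(k\). The iterative variant repeatedly drops
the worst gene; the pairwise-variation statistic V for "how many
references" is provided but not required — two references suffice in the
intended panels. Normalized expression is
\(2^{-(Ct_{target} - \overline{Ct}_{HK})}\), i.e. the comparative Ct
method against the geometric mean of the housekeeping relative
quantities. Samples missing any housekeeping Ct are excluded and
flagged. Group comparisons delegate to the Wilcoxon rank-sum test by
default (Welch's t on request) and adjust across genes by
Benjamini–Hochberg.

## Synthetic generators: what they emulate, and what they do not

Every generator is a pure function of a `synthetic_config()`, whose seed
feeds one fixed-offset RNG stream per generator — adding a generator can
never shift another's draws, and regeneration is byte-identical. Truth
keys are returned separately and never embedded in the analysis tables.
The defaults are the study conditions the package targets:

* **Growth screen**: 21 evaluable models (1 CR, 2 PR, 2 SD, 16 PD by
  true class), 3 treated + 3 vehicle tumors each, measured twice weekly
  to day 35. Volumes follow \(V_0 e^{rt}\) with class rates
  \(r\) giving −97%, −60%, −5% and +300% at day 35 (PD quadruples — a
  realistic pace that keeps the day-10 change above the +20% band under
  noise); vehicles triple, so control arms always satisfy the >20%
  growth validity condition. Dimensions are back-solved from volume at a
  fixed 1.25 aspect ratio and multiplicative lognormal noise (SD 0.05 on
  the log scale) is applied per measurement.
* **Biomarker panels**: balanced resistant/sensitive truth; with
  probability `label_noise` (default 0.15) a panel's scores are drawn
  consistent with the opposite class, so the composite classifier's
  expected accuracy is exactly \(1 - \varepsilon\) — which is what the
  fidelity tests check against binomial error.
* **Exposure cohort**: n = 582 with exposure prevalence 71/582. Given
  exposure, the joint mutation/deletion state comes from a log-linear
  model whose exposure interaction equals the configured log odds ratio;
  by Bayes' rule the interaction coefficient of
  `exposed ~ mutation * deletion` then equals that log-OR exactly, with
  null main effects — the basis of the calibration and coverage checks.
  At these sizes roughly 17% of *null* replicates contain no exposed
  double-hit patient at all, so their interaction term is
  quasi-separated; such fits are flagged and excluded, not forced.
* **Ex vivo**: sensitive cultures center at −50% area change, resistant
  at 0%, common SD 10 — well-separated classes as in the intended assay;
  dose plates come from a known 4PL curve with multiplicative noise.
* **qPCR**: per-sample offsets shared by all genes; two stable
  references (residual SD 0.05), one unstable candidate (SD 1.5), and
  target genes carrying a one-cycle group effect.

What the generators do *not* emulate: inter-tumor growth-rate
heterogeneity within a class, welfare censoring (beyond what a user
truncates), batch effects in IHC scoring, dependence between panel
markers beyond the rule structure, genomic coordinates or subclonality,
and qPCR efficiency drift. Passing tests therefore demonstrate that the
*procedures* are correct and calibrated under their stated assumptions —
not that real cohorts will reach the same operating characteristics.

## Numerical and reporting choices

* Percentages are rounded half-away-from-zero for display parity with
  integer-printed reports; exact values are always retained alongside.
* Band classifiers are closed on the sensitive side (−95 → CR,
  −30 → PR, +20 → SD; RTV 1.2 → SD) and exhaustive over the real line.
* The bootstrap SE uses 2000 resamples by convention; tests accept 15%
  relative error against \(\sigma/\sqrt{n}\) at n = 100.
* Problem sizes in the test and acceptance runs — 200 replicate panels
  of n = 200, 500 null and 200 signal cohorts, 100 noisy plates — were
  chosen as the smallest sizes at which the binomial/KS/coverage checks
  are stable; they run in well under a minute each on one core.
* Fisher's exact test reports the conditional hypergeometric two-sided
  p-value with the sample cross-product odds ratio (0.5 continuity
  option for zero cells), not the conditional-MLE odds ratio.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes every desk
worked example (cohort rates, engraftment, the derivative-tumor mutation
count, copy-number band calls) and the synthetic-cohort calibration
quantities from scratch against the installed package, writing one flat
JSON object. The README shows a worked end-to-end example with the
numbers it prints.
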