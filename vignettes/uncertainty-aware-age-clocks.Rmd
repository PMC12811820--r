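---
title: "Uncertainty-aware epigenetic age clocks from bisulfite amplicon data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware epigenetic age clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methclock)
```

## The problem

Methylation-based age prediction ("epigenetic clocks") conventionally
requires a training set of known-age animals, which most wild populations —
especially long-lived, endangered ones — cannot provide. What such
populations often do have is a photo-identification catalogue from which
each individual's age can be estimated *with quantified uncertainty*: a
best estimate, hard minimum and maximum bounds, and an ordinal confidence
rating (CR, 2–5 here). `methclock` implements a complete clock-building
framework that treats both the age labels and the methylation measurements
as distributions rather than numbers: ages enter as confidence-weighted
skew-normal priors, methylation as binomial read-count distributions, and
predictions leave as per-sample distributions summarised by 95%
highest-density intervals (HDIs).

## Methylation quantification

Input is a per-sample, per-site nucleotide count table from targeted
bisulfite amplicon sequencing (the upstream trimming/alignment/pileup steps
are out of scope; any standard bisulfite pipeline produces these counts).
For a cytosine site, reads carrying A or G are treated as sequencing errors
and discarded, giving the *corrected coverage* \(K_m = n_C + n_T\). At CpG
sites the C reads are the methylated reads \(n_m\); at non-CpG cytosines —
assumed unmethylated — a C read is a bisulfite conversion failure. Pooling
all non-CpG cytosines of a sample (conversion failure rates are consistent
across amplicons) gives the per-sample conversion efficiency
\(P_v = \sum n_T / \sum K_m\).

The observed methylation proportion \(P_m = n_m / K_m\) is inflated by
conversion failures; the corrected estimate is

\[\hat P_m = 1 - \frac{1 - P_m}{P_v}.\]

When \(P_v \le 1 - P_m\) this is non-positive; such cells are set to one
half of the smallest strictly positive corrected value at the same locus.
Symmetrically — a boundary case the published rule leaves open — a cell at 1
(every read methylated) would have an infinite logit, so it is set to 1
minus half the smallest positive \(1-\hat P_m\) at its locus: the same
shrinkage philosophy applied at the other boundary. Modelling then uses
\(M = \mathrm{logit}(\hat P_m)\), which is additive, as several of the
backends are linear.

Three sequential QC filters follow the protocol defaults: drop
samples with median CpG depth < 1000, then sites with median depth < 1000
across the survivors, then samples with any remaining site under 100 reads.
Two deliberate choices where the text is ambiguous: depth always means the
corrected coverage \(K_m\) (everything downstream is computed from it), and
the locus minimum for the half-lowest rule is taken over all positive
corrected values in the data set (the offending cells are non-positive, so
excluding them is automatic). Medians with even counts use the midpoint
convention.

## Age priors

Each sample's catalogue record \((\mathrm{Age_{best}, Age_{min},
Age_{max}}, CR)\) is converted to a skew-normal distribution whose mode
equals Age_best and whose 2.5% and 97.5% quantiles equal Age_min and
Age_max. Because the skew-normal mode and quantiles are location–scale
equivariant, the three-constraint fit reduces exactly to a one-dimensional
root search: the relative position \(r = (\mathrm{Age_{best} -
Age_{min}})/(\mathrm{Age_{max} - Age_{min}})\) determines the shape
\(\alpha\) (symmetric \(r = 0.5\) gives \(\alpha = 0\); a mode nearer the
minimum forces right skew), after which location and scale follow
linearly. This replaces the obvious 3-D root solve: it is deterministic,
needs no restarts, and each constraint is verified to 1e-3 after solving.
A degenerate Age_best sitting exactly on a bound is nudged inward by
\(10^{-6}\times\) the range; the shape bracket \(|\alpha| \le 200\) covers
every nudged case. The skew-normal CDF is computed via Owen's T function
(reduced to \(|a|\le 1\), then 48-point Gauss–Legendre quadrature), the
quantiles by root-finding, the mode numerically.

The full prior is a mixture \(w\,\mathrm{SN} + (1-w)\,
\mathrm{Uniform(Age_{min}, Age_{max})}\) with \(w\) = 0.2, 0.55, 0.75, 1.0
for CR 2–5; no weight is defined for CR 1 and such records are rejected.
Two support decisions: skew-normal draws below zero are rejected and
redrawn (ages cannot be negative; only predictions, not prior draws, are
otherwise clamped), while draws outside (Age_min, Age_max) are kept — the
bounds are the 2.5%/97.5% quantiles by construction, so 5% of the mass
lies outside and truncating would distort the stated distribution. The
mixture density itself is untruncated and integrates to 1.

## Clock training designs

A clock design is a point on five axes: backend (elastic net ENR, random
forest RFR, support vector regression SVM, generalised additive model GAM)
× age transform (none / ln) × CpG site selection (all sites, ENR inclusion
frequency, RFR permutation importance; each on its own sample subset) ×
training subset (All / CR3+ / CR4+) × CR weighting. `enumerate_configs()`
expands the grid (336 combinations at full width); `search_models()`
evaluates each by leave-one-out cross-validation — out-of-bag predictions
for RFR — and ranks by the median absolute error (MAE; the median of
|predicted − Age_best|) computed **only over CR4+ samples**, since
residuals of low-confidence samples confound clock error with label error.
Pearson correlation breaks ties; per-bin MAE and mean residuals are
reported for Age_best bins 0–9, 10–24, 25+ years.

Backend tuning procedures:

* **ENR**: `cv.glmnet` fold assignment is a real noise source at these
  sample sizes, so each candidate mixing parameter α is scored by the
  median over replicate cross-validated fits (1000 at the published scale) of the
  MAE at the deviance-minimising penalty, and α is chosen by a bounded
  scalar optimiser on [1e-4, 0.5].
* **RFR**: grid over `sampsize` ∈ 0.3n–0.7n and `mtry` ∈ 0.1s–0.5s;
  the OOB-MSE surface is smoothed with a 3×3 median filter and the argmin
  taken — a deterministic surrogate for choosing the optimum by eye.
  Candidate forests use up to 500 trees; the final forest the configured
  count (default 10,000).
* **SVM**: ε-SVR with an RBF kernel, solved as the dual quadratic program
  (quadprog; a dense QP is exactly right at n ≤ ~100), inputs and response
  standardised, ε = 0.1 on the standardised response. Cost and gamma are
  grid-searched in steps of 0.1 in log10 over 1e-4–1e5 and 1e-5–1e4 with
  10-fold CV; "every 0.1" is read as log-spacing because the ranges span
  nine orders of magnitude. SVM has no sample-weighting mechanism;
  weighting still applies to its site-selection stage.
* **GAM**: one penalised thin plate regression spline per site, basis
  dimension k = 3, incremented until mgcv converges. The coefficient count
  grows with sites × k, so GAMs are practical only after site selection.

Sample weights, when enabled, are the raw CR integers (2–5) — the ordinal
confidence itself, not the mixture weights. Hyperparameters are tuned once
per design on its full training subset and held fixed across LOO folds:
per-fold retuning at 1000-replicate α optimisation is computationally
indefensible and tuning is described at the model level. Predictions are
back-transformed (exponentiated under the log transform) and clamped to
[0, 80] years — above the oldest observed individual (65) because the
observed maximum is unlikely to be the possible maximum; the bounds are
configurable.

Random-forest regression and ε-SVR are implemented inside the package
(compiled CART forest with bootstrap, `mtry`, OOB prediction and
permutation importance; QP-based SVR) because no R implementation of
either is available in the supported dependency set; glmnet and mgcv are
used directly.

## Stepwise site selection

*ENR route*: replicate cross-validated elastic-net fits (redrawn folds per
replicate, α tuned once on the selection sample set), recording nonzero
coefficients at the deviance-minimising penalty; sites included in ≥ 50%
of replicates are kept. A known caveat: when informative sites are
strongly collinear — which the default synthetic world makes extreme,
since all clock sites share one deterministic age signal — a sparse tuned
α keeps only a rotating subset of the group per replicate, so per-site
inclusion frequency understates per-site relevance; near-ridge α values
select the whole group. *RFR route*: permutation importance (increase in
OOB MSE when a site's values are shuffled) compared against a null built
by refitting on response-permuted data, \(p = (1 + \#\{null \ge
obs\})/(1 + n_{perm})\), keeping sites with p < 0.05. The selection sample
subset is independent of the final training subset; both are recorded.

## Resampling uncertainty propagation

Each of the (default 1000) replicates redraws every retained cell's count
as \(n^* \sim \mathrm{Binomial}(K_m, n_m/K_m)\) and every sample's age
from its mixture prior, pushes \(n^*/K_m\) through the same correction and
logit as the point pipeline (with the sample's fixed \(P_v\): it is
estimated from pooled counts in the 10^5–10^6 range, so its uncertainty is
negligible next to the binomial cell noise), refits the clock with the
point-estimate hyperparameters, predicts every sample, and clamps to
[0, 80]. Failed replicate fits are dropped with a warning; more than 5%
failures aborts. The per-sample draw vectors are summarised by the 95% HDI
— the shortest contiguous window containing ⌈0.95 n⌉ sorted draws, ties to
the lower window; deliberately a single interval even for multimodal draw
sets. Coverage is the fraction of samples whose Age_best falls inside its
HDI. For individuals sampled twice, ordinality is the fraction of
replicates in which the later sample out-predicts the earlier one; exact
ties count as incorrect (conservative).

## The synthetic world

`generate_cohort()` emulates the framework's data model so every stage is
testable offline: 76 individuals / 89 samples with 13 longitudinal pairs
2–13 years apart, 8 amplicons carrying 184 CpG sites (47 age-responsive)
plus non-CpG cytosine controls, per-sample read depths 1000–7000,
conversion efficiencies 0.993–0.997, a 0.02% sequencing error rate, true
ages 3–40 years, and catalogue-style degradation of true ages into
(Age_best, bounds, CR) with wider ranges at lower CR and older age — the
range always contains the true age, matching its definition as
100%-confidence bounds. Clock-site methylation is
\(p = \mathrm{logit}^{-1}(\beta_0 + \beta_1\,\mathrm{age})\) with per-year
slopes 0.02–0.08 in logit units; unmethylated-cytosine conversion failures
are injected at rate \(1 - P_v\) per read — exactly the error mode the
correction removes, which makes its unbiasedness testable.

What the generator does **not** emulate, and what a green test therefore
does not establish: by default methylation is a *deterministic* function
of age plus binomial read sampling. Real data carry inter-individual
biological variation — in the real study system most CpG sites correlate only
weakly with age — and under such noise site-selection power and clock
accuracy will be lower than the synthetic results suggest. The
`sd_biological` parameter injects logit-scale per-sample noise for
robustness experiments, but it is deliberately not part of the stated
default world. PCR duplicates, quality-score structure and alignment
artefacts are likewise out of scope (generation starts at deduplicated
counts).

## Numerical choices

Skew-normal fit tolerance 1e-3 (years on the mode, probability on the
quantiles); prior mixture mass verified to 1e-4 by quadrature. The SVR
dual adds a 1e-8 ridge to the kernel block matrix for strict positive
definiteness, and the intercept comes from free support vectors (mid-bound
fallback). Every stochastic step takes a seed derived from one master seed
through a Lehmer stream (`derive_seed`), so grid searches and resampling
runs are exactly reproducible; results never depend on the caller's RNG
state. Coarse SVM tuning grids can select ill-conditioned corners (tiny
gamma with huge cost) whose fits amplify numerically tiny perturbations;
published-scale grids make this unlikely, and `run_resampling()` accepts
pre-tuned hyperparameters where control matters.

## Limitations and external replication

The package predicts the catalogue age-estimation process, not verified
chronological age; at desk scale the tests cannot reproduce the published
headline numbers for the real population (overall MAE 1.70 years, 90% HDI
coverage, 11/13 pair ordinality), which are properties of its specific
animals and loci. The originating study's data and code are publicly
archived by its authors; running `quantify`, `fit-priors`,
`select-sites`, `train` and `resample` at published-scale settings (1000
replicates everywhere, full tuning grids) on those inputs is the intended
external replication path and should approach those values. It is a
tutorial exercise, not part of the automated suite, which must run
offline.
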