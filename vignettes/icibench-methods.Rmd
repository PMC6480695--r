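---
title: "Benchmarking and combining ICI response biomarkers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking and combining ICI response biomarkers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icibench)
```

# The problem

Response to immune checkpoint inhibitors (anti-PD-1, anti-PD-L1,
anti-CTLA4) is observed in a minority of patients, and no single proposed
biomarker — PD-L1 expression, tumour mutational burden, interferon-γ
signatures, algorithmic scores such as TIDE or the ImmunoPhenoScore —
discriminates responders reliably across cohorts. `icibench` implements a
benchmarking pipeline for this setting: score a fixed panel of 18 markers
per patient, evaluate each marker per cohort by ROC analysis, and then ask
whether combining the uncorrelated markers (by exhaustive majority voting,
or through a logistic model) buys any accuracy beyond the best single
marker.

Because the public trial cohorts this kind of analysis runs on cannot be
redistributed, the package ships a synthetic cohort generator that
reproduces their statistical shape, so every stage is exercisable and
testable offline.

# The marker panel and scoring model

`builtin_panel()` holds 18 markers: 8 single genes (CD274, PDCD1,
PDCD1LG2, CTLA4, AXL, POLE, POLE2–4), 6 gene-set signatures (two IFN-γ
sets, three ICB-resistance / EMT signatures, the AXL pathway), the
mutational load (the one DNA marker), and two plug-in scores (TIDE, IPS)
accepted as precomputed columns — their algorithms are external published
methods and are deliberately not reimplemented.

Scoring rules:

* single gene: `log2(TPM + 1)`;
* gene set: arithmetic mean of `log2(TPM + 1)` over the member genes found
  in the matrix. The aggregation rule for these signatures is not uniquely
  fixed by their original descriptions; the mean of log-transformed values
  is the minimal convention consistent with score-level signatures and is
  recorded in the run manifest. Member genes absent from a matrix are
  skipped (public matrices differ in symbol dialects) and reported, rather
  than failing the signature;
* mutational load: the absolute number of variant records per patient.
  Duplicate records count as listed by default (`dedup = TRUE` collapses
  identical variants), reading "absolute number of mutations" literally;
* gene symbols match exactly, case-sensitively, after whitespace trimming.
  No alias resolution: determinism is preferred over recall.

TPM and FPKM matrices are both accepted — scores are rank-preserving
within a unit, and no cross-unit conversion is attempted.

# Responder separation

`assign_labels()` dichotomizes heterogeneous clinical annotations: CR, PR,
SD and LB are responders; PD patients are responders only with known
overall survival strictly greater than 2 years; PD with shorter or unknown
survival, and NB, are non-responders. Survival equal to the cutoff counts
as non-responder ("greater than" is read strictly). Units are converted to
days internally (1 year = 365.25 days) so cohorts reporting days, months
or years mix freely. Study-specific response vocabularies must be mapped
to the six canonical codes up front (`read_clinical(response_map = ...)`);
the package never guesses a mapping.

# Per-marker evaluation

Each marker is evaluated on each cohort where its data type exists
(`count_tests()` counts these evaluable pairs; for the emulated design —
RNA in three of five cohorts, WES in all five, 17 RNA markers + 1 DNA
marker — that is 17 × 3 + 1 × 5 = 56 tests).

The ROC machinery makes every numerical choice explicit:

* candidate cutpoints are the midpoints between consecutive distinct
  sorted scores, plus the two infinite endpoints; a patient is called
  positive when the oriented score is **≥** the cutpoint;
* the AUC is the trapezoidal area, which with midpoint cutpoints equals
  the Mann–Whitney rank statistic with ties contributing ½ (the suite
  verifies this equivalence against an O(n²) pair-count oracle to 1e-12);
* orientation is automatic: resistance signatures discriminate with *low*
  scores in responders, so the raw AUC may fall below 0.5; the score is
  negated internally, the reported AUC is always ≥ 0.5, and the direction
  is recorded. This is why anti-correlated markers appear with honest
  AUCs rather than values below chance;
* the operating threshold maximizes sensitivity + specificity (Youden's
  J); ties are broken by the smallest oriented threshold, i.e. the most
  sensitive of the tied cutpoints, for determinism;
* patients with a missing score are excluded from that marker's
  evaluation only (complete-case per marker);
* no AUC confidence intervals are computed.

Per-cohort AUCs are then joined into minimum / mean / maximum and the
max−min delta per marker (`summarize_markers()`).

# Combination by majority voting

The per-cohort *dichotomous calls* (not the continuous scores) are pooled
across the RNA cohorts — thresholds stay cohort-specific, only the binary
predictions travel. Before searching, markers that duplicate each other's
information are removed: every pair with Pearson |r| > 0.5 **and**
p < 0.01 on the pooled continuous scores is linked, and the minimum number
of markers covering all links is excluded. This minimum vertex cover is
found exactly (exhaustive search over link-incident vertices, feasible to
~20 markers and property-tested against an independent enumeration
oracle); ties between equal-size covers are resolved by excluding the
markers with the lower mean individual AUC, then lexicographically. A
greedy heuristic would also work at this scale, but exact minimality is
cheap and testable, so it is the default and only mode.

All subsets of 2 to n retained markers — `2^n − n − 1` of them, 131,054
for n = 17 — are then evaluated by majority voting: a patient is predicted
responder when **at least half** of the subset's markers vote responder,
so an exact tie goes to the responder class (a flag flips this reading).
For a dichotomous predictor the "AUC" is the single-point ROC trapezoid,
(sensitivity + specificity)/2. Subsets are enumerated lexicographically
and results sorted by AUC then size for output stability; the search is
vectorized per subset size (one matrix product per size) and covers the
full 17-marker space in a few seconds. Combinations with AUC ≥ 0.65 are
"acceptable", and each marker's frequency among acceptable combinations
measures how indispensable it is.

# Combination by logistic regression

`fit_glm()` fits a plain binomial GLM (logit link, maximum likelihood, no
penalization) of the label on the binary marker calls. Complete
separation — nearly inevitable with 17 binary features and ~120 patients —
is detected (fitted probabilities pinned at 0/1, or a diverging
coefficient) and flagged honestly in `converged`/`separation` rather than
silently regularized; `coefficient_table()` refuses to present such
p-values as reliable. Wald statistics are reported under the conventional
`t_value` label with p-values from the normal approximation.

`repeated_holdout()` draws simple random (unstratified — "randomly
selected" is read literally; a stratified option exists) 80/20 splits,
fits on the training 80%, predicts the held-out 20%, and records the test
AUC and the Youden-optimal ("best") sensitivity and specificity of the
test ROC, averaging over iterations. Iterations whose training or test
set lacks a class are skipped and counted, never imputed; more than 50%
degenerate iterations aborts with a reliability error. The default is
10,000 iterations; the split schedule is fully determined by `seed`. The
coefficient table reported downstream comes from the single full-data
fit (reporting the across-iteration coefficient distribution instead
would answer a different question — stability, not inference).

# The synthetic cohort generator

`simulation_config()` defaults encode the study design the package
emulates: five cohorts of 28/49/33/63/41 patients, expression for cohorts
1, 2 and 5 (a merged RNA-side set of 118 patients), WES for all five, and
responder fractions between 0.38 and 0.70 — the range reported for real
ICI trial compendia.

The generative model is latent-score binormal:

* responder status is drawn first, per cohort fraction;
* each marker's latent score is standard normal among non-responders and
  `N(delta, 1)` among responders, so its population AUC is
  `pnorm(delta / sqrt(2))` — a closed form the acceptance checks exploit.
  The default `delta`s are back-solved from the mean AUCs such marker
  panels achieve in practice (0.71 / 0.67 / 0.66 for the three best —
  TIDE, an ICB-resistance signature with a *negative* shift, CTLA4 — the
  rest weakly informative to null), which puts realized per-cohort AUCs in
  the reported 0.43–0.87 band at these sample sizes;
* correlated pairs (by default PDCD1 with the reduced IFN-γ set, target
  r = 0.6) are induced by a Gaussian copula whose off-diagonal entries are
  adjusted both for the label-induced covariance `delta_a delta_b p(1−p)`
  and for the attenuation from signature-recovery noise, so the target is
  achieved on the *observed* downstream scores (±0.1 at n ≥ 200, tested);
* expression is back-filled from the latent scores: a single-gene marker's
  gene carries `log2(TPM+1) = 5 + z` exactly; each signature member gene
  scatters around its signature's latent score with independent N(0, 1)
  noise, so the mean-aggregation scoring recovers the latent score up to
  `sd/sqrt(n_genes)` noise. Genes claimed by a single-gene marker or an
  earlier signature keep their first assignment, leaving mild, realistic
  correlations between overlapping signatures (the two IFN-γ sets share
  four genes; AXL sits in two signatures);
* mutation counts are a monotone negative-binomial quantile transform of
  the mutational-load latent score (mean 100, dispersion 1.5 — typical
  exome scale), preserving the marker's ROC while keeping counts
  overdispersed; records are expanded into a MAF-like table;
* clinical annotations are generated to reproduce the latent label
  *exactly* under the 2-year rule: responders are mostly CR/PR/SD/LB with
  a 15% PD fraction whose survival is drawn above the cutoff;
  non-responders are NB (30%) or PD with survival truncated below the
  cutoff by inverse-CDF, 20% of them with survival withheld. Survival is
  exponential with class-dependent rates — the simplest model exercising
  the cutoff logic;
* TIDE and IPS plug-in columns are the latent scores themselves (their
  internals are out of scope).

Everything is deterministic given `seed`; the same configuration writes
byte-identical files.

## What the generator does *not* emulate

The synthetic cohorts are statistically homogeneous: every cohort draws
from the same marker-effect model. Real cohorts differ by tumour type,
platform and response criteria, which is precisely why cross-cohort
validations of such panels find large per-marker AUC deltas and why their
ensembles tend to improve on the best single marker only marginally. Under
homogeneity, per-cohort Youden thresholds — chosen on the *full* cohort,
test patients included, exactly as the benchmarked protocol does —
generalize unrealistically well, so the synthetic end-to-end run shows
near-ceiling ensemble performance (holdout mean AUC ≈ 0.9+, most
combinations "acceptable"). Passing tests therefore certify the
machinery — counts, oracles, closed forms, determinism — not that real
data would yield these ensemble numbers. Batch effects, clonal evolution
and read-level data are likewise out of scope.

# Problem sizes

The test suite and the acceptance script run everything at the scale the
method is designed for: the full five-cohort design (118 merged RNA-side
patients), the complete 131,054-subset exhaustive search, a
1,000-iteration holdout (the 10,000-iteration default remains the
function's default), 200-instance oracle sweeps for the ROC machinery,
100 random graphs for vertex-cover minimality, and 100 × n = 2000
replicates for GLM parameter recovery. A null design (20 cohorts of 500,
all effects zero) bounds the fraction of per-marker AUCs outside
[0.4, 0.6] at 10%.

# Known limitations

* The exact vertex cover supports at most 20 linked markers — ample for
  an 18-marker panel, not for transcriptome-wide filtering.
* The binary-combination "AUC" is the one-point trapezoid; it coincides
  with balanced accuracy and is not comparable to continuous-score AUCs
  at the third decimal.
* Separated GLMs are flagged, not fixed; users wanting shrinkage should
  fit their own penalized model on the merged call table.
* `count_tests()` counts a marker once per cohort carrying its data type;
  definitions that instead count the panel uniformly across studies would
  give 18 × cohorts.
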