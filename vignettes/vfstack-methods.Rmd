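---
title: "Classifying glaucomatous visual fields: rule-based criteria and stacked meta-learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying glaucomatous visual fields: rule-based criteria and stacked meta-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

vfstack classifies Humphrey 24-2 visual fields as glaucomatous (GL) or
not, two complementary ways: five published rule-based field criteria
expressed through one parameterised cluster-rule engine, and a stacked
weight-based meta-learning pipeline that aggregates the criteria through
neural surrogates. Because clinical perimetry archives are private, the
package also ships a synthetic cohort generator with ground-truth labels;
every claim the test suite makes is a claim about this generator's output,
a point discussed at the end.

## The measurement model

Standard automated perimetry measures a light-sensitivity threshold (in
dB) at 54 fixed locations of the 24-2 pattern: a 6°-spaced lattice offset
3° from both meridians, two locations of which fall on the physiologic
blind spot and are excluded, leaving 52 test locations. `vf_grid()` builds
this geometry with adjacency (8-connectivity by default, 4-connectivity
optional), an edge-location flag (outermost ring plus the two locations
straddling the blind spot, the convention Hodapp-style "non-edge point"
rules inherit), hemifields, and a position-based sector map
(superior-temporal ST, superior-nasal SN, inferior-temporal IT,
inferior-nasal IN). We deliberately use a field-space quadrant map rather
than a disc-sector structure-function map: the quantities the package
reports (e.g. sector-aggregated feature importance) are statements about
field locations, and a disc-space map would invert superior and inferior
between field and disc, inviting misreading. The labels T, N and central
remain available for user-supplied maps.

Deviation analysis follows the instrument's conventions. Total deviation
(TD) is measured sensitivity minus the age-expected normal; the general
height (GH) is the rank-7 largest TD (about the 85th percentile of 52,
the standard convention — the rank is configurable); pattern deviation
(PD) is TD minus GH, isolating focal from diffuse loss. Mean deviation
(MD) is here the unweighted mean of TD and PSD the unweighted dispersion
of TD, because the instrument's proprietary variance weights are not
published. Probability maps assign each deviation the most extreme
normative category it falls below (p<5%, p<2%, p<1%, p<0.5%).

### The synthetic normative reference

The original analysis chain delegates TD/PD recovery to an external
normative library backed by a proprietary database. vfstack instead
packages a synthetic reference (`vf_normative()`) with the same
structure: a linear age model per location (default slope −0.065 dB/year,
a typical perimetric ageing rate; intercept 34 dB at fixation declining
0.1 dB per degree of eccentricity at the reference age of 45) and
between-subject spread growing with eccentricity (1.4 dB at fixation +
0.03 dB/deg). TD cutoffs are Gaussian quantiles of that spread. PD
cutoffs **cannot** be scaled TD cutoffs: subtracting GH shifts normal PD
values negative by roughly the 85th percentile of the noise, so naive
cutoffs would flag a third of healthy locations. PD limits are therefore
estimated as empirical per-location quantiles over 8,000 Monte Carlo
normal fields (fixed internal seed, so the reference is deterministic),
exactly how normative databases derive them from normal cohorts. The same
draw supplies the normal 95th percentile of PSD. Absolute TD/PD values on
real exams are consequently not bit-comparable to any instrument's
output; within the package's closed world the computation is exact, and
`vf_read_normative()` accepts a user-supplied reference table when real
normative data are available.

## The five rule-based criteria

LoGTS, UKGTS, Kang, HAP2 part 1 and Foster all reduce, in their
visual-field component, to one schema: flag locations at or beyond a
probability level on the TD or PD map; find maximal contiguous clusters
(optionally non-edge only, optionally confined to one hemifield); pass
when a cluster of the required size contains an anchor point at a more
extreme level; optionally conjoin a glaucoma hemifield test (GHT) or PSD
abnormality; call the eye glaucomatous when enough exams on distinct
dates qualify. `vf_criterion_spec()` captures this schema and the five
packaged parameter sets ship as editable YAML
(`system.file("extdata", "criteria.yaml", package = "vfstack")`), so the
transcription is auditable and the engine reusable. The packaged sets are
reconstructions from the criteria's source publications restricted to
their field component (the original studies' intraocular-pressure and
optic-disc arms are out of scope); per the method's stated assignment,
UKGTS, LoGTS and Kang read the TD map while HAP2 part 1 and Foster read
PD, and each criterion's map is a config field, so the opposite
assignment is equally expressible. Confirmation defaults to a single
qualifying exam, and is configurable because published deployments of
these criteria differ on requiring confirmatory fields.

The GHT here is a documented simplification of the proprietary test: five
superior zones (a packaged table partitioning all 26 superior locations)
are mirrored inferiorly, each location scores 0/2/5/8/10 by PD
probability level, and the verdict is "outside normal limits" when any
mirrored pair differs by ≥ 12 score points ("borderline" at ≥ 6). The
thresholds were fixed once against two construction cases — a deep
unilateral arcuate must trip the test, a mirror-symmetric field must not
— and are arguments of `vf_ght()`.

Two properties the engine guarantees are worth stating: verdicts are
monotone (deepening any deviation can only turn a fail into a pass,
because probability categories are monotone in the deviation), and
cluster structure is invariant under OD/OS mirroring (location numbering
mirrors with the grid).

## The stacked weight-based meta-learning pipeline

The pipeline (`vf_run_pipeline()`) proceeds: cohort → reliability filter
(false-positive rate strictly above 0.33 excluded; the boundary exam is
retained) → longitudinal inclusion (≥ 2 distinct-date exams, ≥ 0.5 years
span) → per-eye criteria labels → patient-level 82.5/17.5 split → base
networks → meta-features → meta-learners → evaluation.

**Base models.** Two multi-layer perceptrons, one per map kind: each
takes 56 inputs (52 standardised deviation values + age, gender, race,
follow-up time; categorical encodings are explicit integer tables
persisted with the model, continuous features z-scored on training
statistics) and has multiple sigmoid output heads, one per criterion
assigned to that map. The TD net therefore carries the UKGTS/LoGTS/Kang
heads and the PD net the HAP2/Foster heads, so there is one trained model
per map kind yet every criterion has a dedicated output. Hidden layers are 128 → 64 sigmoid units trained with Adam at learning
rate 1e-3, up to 25 epochs, early stopping with patience 3 on a 15%
validation split. The sigmoid/1e-3/Adam configuration is the selected
point of the packaged grid search (`vf_hyperparameter_search()`:
{softmax, ReLU, sigmoid} × {1e-2, 1e-3, 1e-5} × {SGD, RMSprop, Adam},
stratified 5-fold CV, ties resolved toward that configuration then
first-seen). The penultimate width of 64 is fixed: it is what makes the
meta-feature dimension come out right.

**Meta-features.** Each sample is represented by 132 values: the TD net's
64 penultimate-layer activations weighted elementwise by its output-layer
weight vector averaged across heads, the same 64 for the PD net, and the
4 clinical covariates on their raw scale. This "activations ⊙ output
weights" construction is our design: of the per-sample weight-extraction
schemes that land on 132 dimensions it is the one that uses both the
sample's internal representation and the output layer, and the
pure-activation and pure-weight variants remain selectable (`vf_extract_meta(..., variant =)`) for comparison.

**Meta-learners.** Three heads consume the 132-vector: L2-regularised
logistic regression (ridge at C = 1, via glmnet's coordinate descent);
gradient-boosted trees (xgboost, learning rate 0.3, depth 6, 25 rounds);
and an MLP of 128/64/1 units with batch normalisation and ReLU between
hidden layers, dropout 0.08, Adam at 0.0031 with weight decay 1e-3,
batch size 32, 25 epochs. The decision threshold on the GL probability
defaults to 0.5. The network engine itself is written in R matrix
algebra; at these sizes (hundreds of samples, width ≤ 128) that is fast,
and the stacking construction needs direct access to penultimate
activations and output weights, which rules out closed fitting routines.

**Loss and ties.** Base heads are trained with equal-weighted binary
cross-entropy per head. All randomness descends from one root seed via
named substreams (`substream_seed()`), so the simulation, split, base and
meta stages are independently reproducible and two runs with one seed
produce byte-identical CSV artifacts.

## Evaluation

`vf_confusion()` / `vf_metrics_from_confusion()` report accuracy,
precision, sensitivity and F-score with GL positive; ratios with zero
denominators are reported as undefined (`NA`), never silently as 0. AUC
uses the midrank construction (ties count half), which the tests hold
equal to the O(n²) pairwise probability oracle. Prediction uncertainty is
the binary entropy H(p) = −(p log p + (1−p) log(1−p)); the
logarithm is natural (entropies in nats), so H ranges over [0, ln 2]
with its maximum at p = 0.5, and the 10%
display threshold for uncertainty plots is a configurable convention.
Pairwise model comparison uses the two-sided Wilcoxon signed-rank test at
α = 0.05 with zero differences dropped; an all-zero difference vector is
reported as undefined rather than as a p-value. Outlier handling uses
Tukey fences at 1.5 × IQR (the fence factor is an argument; the headline
pipeline metrics apply no outlier removal by default, since whether the
published percentages were computed before or after removal is
unstated). Permutation importance shuffles one feature column at a time
(10 repeats by default, accuracy metric) and can be rolled up by
anatomical sector via the grid map.

## The synthetic cohort generator

`vf_simulate_cohort()` emulates the statistical structure the pipeline
assumes. Demographics follow a large tertiary glaucoma-service
population: age 61.86 (SD 17.40) years truncated to [20, 95], 58%
female, a majority-White race mix, log-normal follow-up matching a 2.49
year median with quartiles [0.54, 6.22], and Beta(1, 8) false-positive
rates under which about 4% of exams fail the 0.33 reliability cut, so the
filter has work to do. Prevalence defaults to 0.45, the neighbourhood of
a clinically reviewed labelled set rather than of a screening population.

Glaucomatous eyes draw a defect archetype — superior-temporal arcuate,
inferior-nasal arcuate, nasal step, paracentral, or diffuse — as explicit
location-index masks with per-location depth weights (packaged CSV,
OD frame, mirrored for OS). The ST/IN emphasis mirrors where glaucomatous
loss typically appears first. The diffuse archetype is a general
depression plus a deeper superior arcuate accent: pure diffuse loss
without a focal component is atypical of glaucoma and would be invisible
to PD-based criteria by construction, which would make label recovery
impossible rather than merely hard. Severity is controlled either by
band targeting (default mix mild 0.5 / moderate 0.3 / severe 0.2 — a
realistic clinic mix; the bands' MD boundaries −4.20 and −8.17 dB and
band means are the conventional staging values) or by a direct depth
distribution for depth-controlled experiments. Under band targeting the
focal depth is capped at 25 dB and the residual MD target is carried by a
uniform component (negative for mild targets, i.e. a field sitting above
the age norm): a focal mask alone cannot produce a −16 dB MD, just as
real advanced glaucoma combines focal and widespread loss. Measurement
noise is Gaussian (default SD 1.5 dB) and sensitivities floor at 0 dB.

What the generator does **not** emulate: spatial noise correlation,
eccentricity-dependent test-retest variability, fixation losses and
false negatives, learning effects, media opacity, or non-glaucomatous
disease. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that its statistical claims hold under the
generator's assumptions; they do not certify performance on real
perimetry, which the private provenance of clinical archives prevents
reproducing here.

## Numerical choices and degenerate inputs

Probability categories use strict inequality (a deviation exactly at a
cutoff takes the less extreme category). Cluster components are returned
sorted by size, ties by smallest member index, so output order is
deterministic. Empty flag maps yield empty cluster lists, not errors. The
reliability filter treats a missing FPR as unreliable (excluded with a
warning). Ages outside the normative fitted range use the boundary value
with a warning. Median imputation is per column with training-cohort
medians. Single-class training labels are rejected rather than fitted.
Early stopping restores the best-validation-loss parameters. Empirical PD
quantiles are forced strictly decreasing across levels (1e-6 separation)
so the category ordering invariant survives Monte Carlo ties.

## Problem sizes

The test suite validates the cluster engine against a brute-force
union-find oracle on 1,000 random flag maps and AUC against the pairwise
oracle up to n = 200. Criteria label recovery uses a 500-eye cohort at
defect depth ≥ 15 dB and noise SD 1 — conditions under which all five
criteria reach sensitivity and specificity ≥ 0.9. The stacking property —
each meta-learner's held-out AUC within 0.02 of the best single
criterion's (and in practice well above it) — is evaluated over 10
simulation seeds of 400-patient mixed-archetype cohorts and compared on
seed-averaged AUC, the stable form of a multi-seed property. The end-to-end determinism check re-runs a 120-patient
pipeline twice and compares artifacts byte for byte. These sizes were
chosen so the full suite completes in a few minutes on one CPU while
keeping every binomial comparison comfortably powered.

## Known limitations

The five criterion parameter sets are reconstructions; where a source
publication admits multiple readings (contiguity, edge conventions,
confirmation) the packaged default takes the common one and the config
makes the alternatives expressible. The GHT is a simplification, not the
proprietary algorithm. The 132-dimensional meta-feature construction is
one defensible reading of an under-specified recipe. The location
numbering (row-major, superior to inferior, temporal to nasal, feature
indices skipping the blind spots) is internally consistent, but other
numbering frames exist in the field; the mapping from feature names
(td11, pd34, ...) to locations is therefore exposed as data rather than
assumed. None of these affect the engine's
contracts, which is why they live in configuration rather than code.
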