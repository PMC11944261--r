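# vfstack

Stacked meta-learning classification of Humphrey 24-2 visual fields.

Glaucoma produces characteristic patterns of light-sensitivity loss on
standard automated perimetry, and several published rule-based criteria —
LoGTS, UKGTS, Kang, HAP2 part 1, Foster — define what counts as a
glaucomatous field. The criteria disagree with one another across
datasets, which motivates a second-stage learner that aggregates them.
vfstack is for vision scientists and ML researchers who want both layers
in one reproducible toolbox: the rule-based criteria as a parameterised
cluster-rule engine, and a stacked weight-based meta-learning pipeline on
top, plus a synthetic cohort generator so the whole system can be
developed and tested without access to private patient data.

## What it computes

**Deviation analysis.** For sensitivities `s_i` (dB) at the 52 non-blind-spot
locations of the 24-2 pattern, total deviation is `TD_i = s_i − N_i(age)`
against a normative reference, general height `GH` is the rank-7 largest TD,
pattern deviation is `PD_i = TD_i − GH`, and probability maps categorise
each deviation at p<5%, p<2%, p<1% or p<0.5% per-location limits.
MD = mean(TD) stages severity (mild > −4.20 dB ≥ moderate > −8.17 dB ≥ severe).

**Rule-based criteria.** Each criterion is one instance of: find clusters of
contiguous flagged locations on the TD or PD probability map (optionally
non-edge, single-hemifield), require a minimum size and an anchor point at a
deeper level, optionally require the glaucoma hemifield test outside normal
limits or abnormal PSD, and confirm over distinct-date exams. Parameters ship
as editable YAML.

**Stacking.** Two multi-head MLPs (56 inputs: 52 TD or PD values + age,
gender, race, follow-up; hidden 128/64) are trained to reproduce the criteria
verdicts. Each sample is then represented by 132 meta-features — penultimate
activations weighted by output-layer weights, 64 per network, plus the 4
clinical covariates — fed to three meta-learners: ridge logistic regression,
gradient-boosted trees, and a 128/64/1 MLP. Evaluation covers confusion-matrix
metrics, midrank ROC/AUC, prediction entropy
`H(p) = −(p log p + (1−p) log(1−p))`, Wilcoxon model comparisons, IQR outlier
fences and permutation feature importance with sector roll-ups.

## Worked example

```r
library(vfstack)

grid <- vf_grid("OD")
norm <- vf_normative(grid)

cfg <- vf_pipeline_config(
  seed = 11,
  sim_config = vf_sim_config(n_patients = 200, exams_per_patient = 1,
                             seed = substream_seed(11, "simulate")),
  min_tests = 1, min_follow_up = 0)
res <- vf_run_pipeline(cfg, out_dir = "run", grid = grid, norm = norm)
#> simulated 200 exams / 200 patients
#> after QC: 195 exams / 195 patients
#> split: 161 train / 34 test patients
#> wrote metrics for 8 models to run

res$metrics[, c("model", "accuracy", "sensitivity", "specificity",
                "f_score", "auc", "entropy_mean")]
#>     model accuracy sensitivity specificity f_score   auc entropy_mean
#> 1      lr    0.853       0.824       0.882   0.848 0.976       0.1593
#> 2     gbt    0.912       0.941       0.882   0.914 0.979       0.1060
#> 3     mlp    0.882       0.765       1.000   0.867 0.983       0.0742
#> 4   LoGTS    0.912       0.824       1.000   0.903 0.912           NA
#> 5   UKGTS    0.912       0.824       1.000   0.903 0.912           NA
#> 6    Kang    0.912       0.824       1.000   0.903 0.912           NA
#> 7 HAP2_p1    0.912       0.824       1.000   0.903 0.912           NA
#> 8  Foster    0.912       0.824       1.000   0.903 0.912           NA
```

The pipeline simulated 200 one-visit patients, dropped 5 to the
false-positive-rate reliability filter, split patients 82.5/17.5, labelled
every eye with the five criteria, trained the base networks and
meta-learners, and evaluated on the 34 held-out patients. Binary criterion
verdicts cap a criterion's AUC (here 0.912); the meta-learners, working from
the 132-dimensional weight features, rank cases continuously and reach AUC
0.976–0.983, with the MLP meta-learner also showing the lowest mean
prediction entropy (0.074 nats, i.e. the most confident probabilities). On a
harder mixed-severity cohort the ordering is the same even when no single
accuracy is perfect.

Individual layers are usable on their own: `vf_simulate_cohort()` for data,
`vf_run_all_criteria()` for rule-based labels and their agreement matrix,
`vf_train_base()` / `vf_extract_meta()` / `vf_train_meta()` for the stacking
stages, `vf_permutation_importance()` for feature attribution. A thin CLI
over these functions lives at `inst/scripts/vfstack.R`
(`simulate`, `qc`, `classify`, `run-all`).

## Scope

The package operates on 24-2 fields only (10-2/30-2 and Octopus patterns,
OCT integration, and GUI front-ends are out of scope), and its normative
reference is synthetic: structure-faithful, but not a reproduction of any
instrument's proprietary database. See the methods vignette
(`vignettes/vfstack-methods.Rmd`) for the model, its assumptions, and what
passing tests do and do not establish about real clinical data.
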