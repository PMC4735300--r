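---
title: "Methods: receptor-optimized ligand discovery and ORN response kinetics"
author: "orntools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor-optimized ligand discovery and ORN response kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orntools)
```

# Scope

`orntools` implements two connected analyses around insect odorant
receptors (Ors) and the olfactory receptor neurons (ORNs) that express
them:

1. **Receptor-optimized ligand discovery.** From a panel of odorants with
   measured ORN activity (spikes/s increase above spontaneous firing),
   select a small subset of molecular descriptors in which the activators
   cluster, train an RBF-kernel regression SVM on that subspace, validate
   it by repeated k-fold cross-validation scored as ROC/AUC against the
   binary activator labels, and rank a filtered compound library by
   predicted activity.
2. **Termination kinetics of ORN responses.** From spike-time recordings,
   estimate the phasic peak, half-decay time, tonic plateau and response
   duration of an odorant response, classify *prolonged activators*
   (odorants that keep the receptor firing tonically for minutes after a
   sub-second stimulus), and quantify *masking* — the suppression of
   responses to a normally activating probe odorant after pre-exposure to
   a prolonged activator.

A synthetic-data module generates seeded fixtures with machine-readable
ground truth for every stage, so the entire pipeline is testable without
any external data.

# Chemistry arm

## Descriptor matrices

`compute_descriptors()` builds a compact open 2-D descriptor block through
the openbabel toolchain (physicochemical properties, per-element atom
counts with hydrogens, functional-group counts). Commercial descriptor
suites produce a few thousand descriptors; this open block is far smaller,
but every algorithm downstream is descriptor-set agnostic and accepts
externally computed matrices via `read_descriptor_matrix()`. The synthetic
fixtures operate directly in descriptor space (200 descriptors by
default), so selection, modelling and screening are exercised at realistic
width regardless of the computed set.

Preprocessing conventions:

* **Cleaning** (`clean_matrix()`): descriptors with a missing-value
  fraction above `max_missing_frac` (default 0.2) or with population
  standard deviation below 1e-12 are dropped (logged with reasons);
  remaining missing cells are imputed with the column median. Median
  imputation is robust and deterministic, and keeps preprocessing free of
  fitted models.
* **Scaling** (`scale_matrix()`): each descriptor is centred on its mean
  and divided by its *population* standard deviation
  (`sqrt(mean((x - mean(x))^2))`). The `(center, spread)` pairs are stored
  so screening libraries are transformed with the *training* statistics
  (`apply_scaling()`), and the transform inverts exactly
  (`invert_scaling()`). Scaling is on by default: both the selection
  fitness and the RBF kernel are distance-based, so descriptors must be
  on comparable scales; it can be disabled in the pipeline config.

## Sequential Forward Selection

`sfs_select()` grows a descriptor subset greedily: at each step it adds
the descriptor maximizing a fitness of the grown subset, recording the
fitness trajectory, and stops either at a fixed `target_size` (default 13,
the subset size used in receptor-optimized screens of this kind) or when
the best improvement falls below `plateau_tol` (default 1e-4).

Two fitness criteria are registered (`register_fitness()` accepts more):

* `nn_pos_auc` — the leave-one-out nearest-positive distance AUC. Each
  molecule is scored by its Euclidean distance to the nearest *other*
  positive in the subset subspace; the fitness is the probability (ties
  half-weighted) that a negative carries a larger score than a positive.
  It is threshold-free, bounded in [0, 1], equals 0.5 under label
  permutation, and directly rewards activator compactness. It is the
  metric we report when *evaluating* a subspace.
* `moderated_fisher` (default for *selection*) — the summed per-descriptor
  squared standardized centroid difference
  \(J = \sum_j (\bar x_{+,j} - \bar x_{-,j})^2 / \tilde s_j^2\), mapped to
  [0, 1) as \(J/(1+J)\), where \(\tilde s_j^2\) is the pooled within-class
  variance moderated toward the scaled panel's unit variance with
  \(d_0 = 20\) pseudo-observations,
  \(\tilde s_j^2 = (d_0 + \mathrm{SS}_{w,j}) / (d_0 + n - 2)\).

The default matters. On a realistic panel (roughly 47 molecules, 14
activators) the rank-based AUC has resolution \(1/(n_+ n_-) \approx
1/462\): it saturates at exactly 1.0 once two informative descriptors are
in — after which every further greedy step is decided by tie-breaking
among dozens of candidates — and at intermediate steps the maximum over
~200 noise descriptors routinely exceeds the true descriptor's AUC by a
few rank units. Greedy selection under `nn_pos_auc` therefore recovers a
planted 3-descriptor subspace in only about 1% of seeded runs. The
moderated Fisher criterion keeps full sample efficiency (each planted
descriptor carries a univariate standardized separation of about 9 s.e.
units against a max-of-noise around 2), does not saturate, and — because
the variance moderation stops small-panel within-class variance estimates
from handing noise descriptors a lucky denominator — recovers the planted
subspace in 100/100 seeded runs at the default study conditions. Since
\(J\) is a sum of non-negative per-descriptor terms, the trajectory is
non-decreasing and the plateau rule is meaningful under either fitness.

Candidates with exactly tied fitness are ordered by the continuous
separation margin `subset_separation()` (mean nearest-positive distance of
negatives minus positives), then by lowest column index, keeping runs
bitwise reproducible.

`kinetics_subset()` applies the same machinery within the activator panel
with positives = prolonged activators, mirroring the search for
descriptors that cluster prolonged activators apart from ordinary ones.

## Clustering

`cluster_odorants()` runs agglomerative clustering on the scaled selected
subspace — average linkage on Euclidean distances by default, the common
choice for descriptor dendrograms; both are configurable. Rows enter the
distance computation in molecule-id order, so leaf order is deterministic
regardless of input order. `write_dendrogram()` exports Newick via `ape`
(each merge height is split across the two child branches).

## SVM, cross-validation, ROC

`train_svm()` fits an epsilon-regression SVM with an RBF kernel through
`e1071` (libsvm) on the scaled subspace, with defaults `C = 1`,
`gamma = 1/|subset|`, `epsilon = 0.1` — no tuning by default, since panels
of ~47 molecules do not support nested tuning (an optional seeded grid
search, `tune_svm()`, is provided for larger panels); the libsvm termination
tolerance is tightened to 1e-10 so the fit is insensitive to training row
order to better than 1e-9 on predictions. Prediction is an explicit
support-vector expansion \(f(x) = \sum_i \alpha_i K(s_i, x) - \rho\)
computed in-package (it agrees with libsvm's own predictions to machine
precision), which lets models serialize to structured *text*
(`save_model()` / `load_model()`, full-precision `%.17g` payload) and
predict identically after a round trip.

The model is a regression on activity magnitude, but validation is asked a
classification question: does the model rank activators above
non-activators? `cross_validate()` makes the bridge explicit: per repeat,
a seeded shuffle partitions the panel into k folds (sizes within one),
each molecule is scored exactly once out-of-fold, and the pooled
out-of-fold regression scores are ranked against the binary labels to give
one ROC/AUC per repeat; `mean_auc` averages over repeats, and a pooled ROC
across repeats is emitted for plotting. Both presets in common use are
supported: 4-fold x 100 repeats and 5-fold x 20 repeats.

Fold assignment is **stratified** by the binary label by default (per-class
counts balanced to within one, overall sizes still within one). With
unstratified folds on a small panel, a fold that happens to hold out more
activators was trained on fewer, which systematically depresses the
held-out activators' scores and biases the pooled AUC below 0.5 on null
data (we observe ~0.39 on a 47-molecule null panel); stratification
removes the composition artifact (~0.5) without touching the separable
case. Unstratified assignment remains available (`stratify = FALSE`).

`roc_auc()` computes the AUC by the rank (Mann-Whitney) identity with
average ranks, so ties count one half and the value equals the all-pairs
enumeration exactly; the ROC itself is the step curve over score
thresholds.

## Library filtering and screening

`filter_library()` implements the screening filters: molecular weight
strictly below 325 (average atomic masses, implicit hydrogens included —
the conventional choice when a bound's mass type is unspecified) and an
exclusive element whitelist C, O, N, H, S (any other element
disqualifies). Multi-fragment SMILES fail with reason `multifragment`
(curated screening libraries are single-fragment; salts are out of scope),
and unparseable SMILES fail with reason `parse` rather than aborting a
large screen. `screen_library()` chains filter, descriptor lookup or
computation, training-scale transform and prediction, processing the
library in chunks of configurable size (constant memory per chunk,
chunk-size invariant output) and ranks passing molecules by descending
score with ties broken by id.

# Kinetics arm

## Rate timecourses

`rate_timecourse()` bins each trial (default 1-s bins), converts to
spikes/s, and averages across trials with the across-trial s.e.m. per bin
— per-trial binning first, then averaging, matches how mean responses with
s.e.m. error bars are computed from repeated single-unit recordings. The
spontaneous (baseline) rate is the mean over a strictly pre-stimulus
window (default [-10, 0) s). Binned counts are kept as integers so spike
conservation (sum of binned counts = total spikes) is exact, not merely to
rounding.

## Termination-kinetics summary

All estimators operate on the excess rate
\(e(t) = \text{rate}(t) - \text{baseline}\), with times relative to
stimulus onset. Defaults (each config-exposed, chosen so that simulated
responses matched to the recorded regimes reproduce the qualitative
anchors: transient activators returning to baseline in 2–6 s, prolonged
activators holding ~60 spikes/s excess for on the order of 220 s within a
300-s recording):

* **Activation threshold**: a response requires peak excess above
  3 x baseline s.e.m.; below that, an all-baseline recording would
  otherwise always show a small positive "peak" by noise alone, and all
  kinetics fields are reported undefined.
* **Peak**: maximum excess within 5 s of onset (`t_peak` its bin centre).
* **Half-decay `t_half`**: first bin after the peak with excess below half
  the peak.
* **Duration**: first time the excess stays below the return threshold —
  `max(2 x baseline s.e.m., 0.1 x peak)` — for 3 consecutive bins. If it
  never does within the recording, the window end is reported with a
  `censored` flag (a lower bound), so very long tonic responses still
  classify correctly.
* **Plateau**: median excess from 30 s after onset to the response end;
  undefined for responses ending before 30 s. Ending the window at the
  estimated duration (rather than the recording end) keeps the late
  post-response tail from diluting the plateau of mid-length responses.
* **Prolonged**: duration >= 30 s. The threshold sits an order of
  magnitude above transient durations (2–6 s) and well below tonic ones
  (minutes), so classification is insensitive to its exact value.

## Masking

`masking_profile()` quantifies probe suppression: for each probe time, the
probe-evoked excess is the firing rate in a 2-s probe window minus the
rate in the immediately preceding 2-s pre-probe window, averaged across
trials, in both the pre-exposed and the control condition. Subtracting the
local pre-probe rate cancels the tonic pedestal that a prolonged
pre-exposure superimposes. The masking index is
\(1 - e_{\text{exposed}}/e_{\text{control}}\): 0 for no masking, 1 for a
fully abolished probe response; probes whose control excess is
non-positive are flagged undefined. Window lengths are defaults of this
package, configurable; 2-s probe windows match the probe-stimulus
protocol the masking design emulates.

# Synthetic data

`gen_training_set()` emulates the study conditions of a receptor-optimized
training panel at desk scale: 47 odorants, 30% activators
(`round(0.3 x 47) = 14`), 200 iid standard-normal descriptors of which 3
are informative — activators shifted by 3 population spreads in each — and
4 prolonged activators additionally shifted in 2 dedicated kinetics
descriptors. Activity values are centred at 60 spikes/s above spontaneous
for activators (the magnitude of a strong tonic response) and near zero
otherwise. Structures are deterministic placeholders: the map from real
structures to a commercial descriptor suite is not reproducible, so chem
fixtures live in descriptor space, while `gen_library()` additionally
plants real SMILES — a deterministic fraction built to fail each filter —
so screening logic is exercised end to end. Library panels share the
planted geometry of their training config (the informative dimensions are
a pure function of the config seed).

`gen_spike_trains()` draws inhomogeneous-Poisson spike trains by thinning:
rate = baseline (8 spikes/s) plus, from stimulus onset, a phasic component
`peak_excess * exp(-t/tau)` (200 spikes/s; tau 1.5 s transient, 4 s
prolonged) plus, for prolonged profiles, a 60 spikes/s tonic plateau
lasting 220 s, inside a [-30, 300] s window with a 0.5-s stimulus at
t = 0. Thinning (not time-discretized sampling) means downstream bin-width
choices cannot bias fixtures; the proposal envelope is piecewise constant
on a 1-s grid augmented with every upward rate jump (onset, probe times),
within which the rate is non-increasing, so the envelope — the rate at
each segment's left edge — dominates exactly. The exact rate function is
returned for oracle checks. `gen_masking_experiment()` layers transient
probe responses (default at 15 s and 30 s) on a control condition, and on
an exposed condition that adds the pre-exposure response and multiplies
probe gain by `masking_gain` (0.1) when the pre-exposure is prolonged —
the planted masking index is `1 - gain`.

What the generators deliberately do **not** emulate: correlated
descriptors (real descriptor blocks are strongly collinear), non-Gaussian
chemical-space structure, dose-response/dilution series, spike refractory
periods, firing-rate adaptation, and trial-to-trial gain drift. Passing
the recovery and enrichment tests therefore demonstrates the algorithms
are correct and well-calibrated under the planted model, not that a
particular real receptor screen will reach the same AUC; on real panels
with collinear descriptors, expect SFS to pick one representative of each
correlated block.

# Problem sizes and numerical choices

The test-suite and acceptance problem sizes are desk-scale versions of the
study conditions: 47-molecule panels with 200 descriptors (100 seeded
replicates for recovery rates), 4-fold x 100-repeat cross-validation,
5,000-compound screening libraries with 50 planted actives, and 20-trial
spike simulations over the [-30, 300] s window (25–100 seeded replicates
for kinetics recovery). All randomness is seeded; generators,
preprocessing, selection and cross-validation are bitwise reproducible
under fixed seeds. Ties in ranking are broken by id; ties in selection by
separation margin, then column index. The pipeline runner
(`run_train_validate()`, `run_screen()`, `run_kinetics()`) snapshots its
resolved configuration, stamps outputs with a config hash, and on resume
refuses artifacts whose hash does not match.

# Known limitations

* The open descriptor block is small (tens of descriptors); users wanting
  descriptor-suite parity should ingest their own matrices.
* Regression scores are unbounded and uncalibrated; an antagonist would
  plausibly appear as a strongly negative score, but no calibration into
  inhibition probability is attempted.
* Kinetics estimators assume a single stimulus per recording (plus probes
  in the masking design) and stationary spontaneous rate.
* `duration` is right-censored by the recording window; the `censored`
  flag must be consulted before averaging durations across odorants.
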