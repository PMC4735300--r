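# orntools

Receptor-optimized ligand discovery and olfactory receptor neuron (ORN)
response kinetics, in R.

Insect odorant receptors (Ors) are prime targets for behavior-modifying
compounds: a single receptor such as *Drosophila* Or42b can drive strong
attraction, and odorants that evoke *prolonged* tonic firing from a
receptor can mask its response to other activators for minutes after a
sub-second encounter. Finding new ligands — and specifically ligands with
prolonged termination kinetics — benefits from descriptor-based machine
learning over a small measured odorant panel, combined with careful
quantification of spike-train kinetics. `orntools` packages both halves
for people doing this kind of work: cheminformatics screening of compound
libraries against a receptor-optimized model, and estimation of
phasic/tonic response structure from spike-time recordings.

## What it computes

**Chemistry.** Given a panel of molecules with activity
(spikes/s increase above spontaneous firing) and binary activator labels:

* descriptor matrices (computed via openbabel, or ingested), cleaned and
  standardized: `compute_descriptors()`, `clean_matrix()`,
  `scale_matrix()`;
* Sequential Forward Selection (SFS) of an informative descriptor subset:
  greedily add the descriptor maximizing a subset fitness — by default a
  moderated Fisher separation
  `J = sum_j (mean_pos_j - mean_neg_j)^2 / s~_j^2`, reported as
  `J/(1+J)`; a leave-one-out nearest-positive distance AUC is available
  as an evaluation metric (`sfs_select()`, `subset_fitness()`);
* hierarchical clustering of odorants in the selected subspace, with
  Newick export (`cluster_odorants()`);
* an epsilon-regression SVM with RBF kernel
  `f(x) = sum_i alpha_i exp(-gamma ||s_i - x||^2) - rho` on the selected
  subspace (`train_svm()`), validated by repeated k-fold cross-validation
  whose pooled out-of-fold regression scores are ranked against the
  binary labels: one ROC/AUC per repeat, averaged (`cross_validate()`,
  `roc_auc()`);
* virtual screening of compound libraries under the physicochemical
  filters MW < 325 (average masses, implicit H) and element whitelist
  {C, O, N, H, S}, ranked by predicted activity (`filter_library()`,
  `screen_library()`).

**Electrophysiology.** Given spike times from repeated trials:
peri-stimulus rate timecourses with s.e.m. (`rate_timecourse()`);
termination kinetics — phasic peak, half-decay time `t_half`, tonic
plateau rate, response duration, prolonged-activator classification
(duration >= 30 s) — via `kinetics_summary()`; and masking indices
`1 - exposed_excess/control_excess` for probe stimuli after pre-exposure
(`masking_profile()`).

**Synthetic data.** Seeded generators with ground truth for every stage:
training panels with planted informative descriptor subspaces
(`gen_training_set()`), screening libraries with planted actives and
filter-failing records (`gen_library()`), and inhomogeneous-Poisson spike
trains — transient, prolonged, and masking designs — drawn by thinning
(`gen_spike_trains()`, `gen_masking_experiment()`).

## Worked example

```r
library(orntools)

## a 47-odorant panel, 200 descriptors, 3 informative, seeded
sim <- gen_training_set(chem_sim_config(seed = 1))
m   <- scale_matrix(clean_matrix(sim$matrix))

sub <- sfs_select(m, sim$compounds$active_label, target_size = 3)
sub
#> descriptor_subset: 3 descriptor(s) [moderated_fisher, fixed_size]
#>    1. D0068 (fitness 0.8528)
#>    2. D0129 (fitness 0.9202)
#>    3. D0167 (fitness 0.9431)

cv <- cross_validate(m, sub, sim$compounds$activity,
                     sim$compounds$active_label, k = 4, repeats = 100,
                     seed = 1)
cv
#> cv_result: 4-fold x 100 repeats (seed 1)
#>   mean AUC 1.0000 (per-repeat range 1.0000-1.0000)

model <- train_svm(m, sub, sim$compounds$activity)
lib <- gen_library(chem_sim_config(seed = 1), n_library = 1000,
                   n_planted_active = 20, fail_fraction = 0.1, seed = 6)
res <- screen_library(model, lib$compounds, descriptors = lib$matrix)
res
#> screen_result: 900 / 1000 molecules passed filters
#>   attrition:
#>     element:Cl     34
#>     multifragment  33
#>     mw:338.65      33
```

The three selected descriptors are exactly the planted informative ones
(`sim$truth$informative`), the cross-validated AUC of 1.0 says the
regression scores rank every held-out activator above every non-activator,
and the attrition counts show the 100 filter-failing library records
rejected for the right reasons.

On the kinetics side:

```r
spk <- gen_spike_trains(spike_sim_config(n_trials = 20, seed = 8),
                        "prolonged")
kinetics_summary(rate_timecourse(spk$trains))
#>   peak_rate t_peak t_half plateau_rate duration prolonged censored baseline
#> 1   236.985    0.5    5.5       59.835      220      TRUE    FALSE    8.015
```

A 0.5-s stimulus at t = 0 evokes a ~237 spikes/s phasic peak decaying to
half within ~5.5 s, then a tonic plateau of ~60 spikes/s above the ~8
spikes/s spontaneous rate that lasts 220 s — a prolonged activator.

End-to-end runs from a single YAML config are available via
`run_train_validate()`, `run_screen()` and `run_kinetics()` (artifacts,
config snapshot, hash-checked resume), or from the shell through the thin
`exec/orntools` front-end (`simulate`, `train`, `screen`, `kinetics`).

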