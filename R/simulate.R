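# Seeded generators for every fixture the pipeline consumes: descriptor
# training panels with planted informative subspaces, screening libraries
# with planted actives, and inhomogeneous-Poisson spike trains with
# transient / prolonged / masking structure. Each generator returns
# machine-readable ground truth for recovery tests.

#' Configuration for synthetic descriptor/activity panels
#'
#' Defaults emulate the study conditions of a receptor-optimized training
#' panel at desk scale: 47 odorants, ~30% activators, 200 descriptors of
#' which 3 are informative for activity (actives shifted by 3 population
#' spreads), plus 4 prolonged activators carrying an extra shift in 2
#' dedicated kinetics descriptors.
#'
#' @param n_molecules Panel size (default 47).
#' @param active_fraction Fraction of activators (default 0.3; the number
#'   of actives is `round(active_fraction * n_molecules)`).
#' @param n_descriptors Total descriptors (default 200).
#' @param n_informative Descriptors carrying the activity signal (default 3).
#' @param effect_size Centroid shift of actives in informative dimensions,
#'   in spread units (default 3).
#' @param n_prolonged Prolonged activators among the actives (default 4).
#' @param n_kinetics_descriptors Descriptors carrying the prolonged-kinetics
#'   signal (default 2).
#' @param seed Integer seed.
#' @return A `chem_sim_config` list.
#' @export
chem_sim_config <- function(n_molecules = 47, active_fraction = 0.3,
                            n_descriptors = 200, n_informative = 3,
                            effect_size = 3.0, n_prolonged = 4,
                            n_kinetics_descriptors = 2, seed = 1) {
  n_active <- round(active_fraction * n_molecules)
  if (n_informative + n_kinetics_descriptors > n_descriptors)
    stopf("n_informative + n_kinetics_descriptors exceeds n_descriptors")
  if (n_active < 2 || n_active > n_molecules - 2)
    stopf("need 2 <= n_active <= n_molecules - 2 (got %d of %d)",
          n_active, n_molecules)
  if (n_prolonged > n_active)
    stopf("n_prolonged exceeds the number of actives")
  structure(list(n_molecules = n_molecules, active_fraction = active_fraction,
                 n_descriptors = n_descriptors, n_informative = n_informative,
                 effect_size = effect_size, n_prolonged = n_prolonged,
                 n_kinetics_descriptors = n_kinetics_descriptors,
                 n_active = n_active, seed = as.integer(seed)),
            class = "chem_sim_config")
}

# planted descriptor dimensions are a pure function of the config seed, so
# libraries generated from the same config share the training geometry
planted_dims <- function(cfg) {
  set.seed(cfg$seed)
  idx <- sample.int(cfg$n_descriptors,
                    cfg$n_informative + cfg$n_kinetics_descriptors)
  list(informative = sort(idx[seq_len(cfg$n_informative)]),
       kinetics = sort(idx[cfg$n_informative +
                             seq_len(cfg$n_kinetics_descriptors)]))
}

desc_names <- function(n) sprintf("D%04d", seq_len(n))

# deterministic placeholder structures (simple alkanols/alkanes); the
# chemistry of these strings is irrelevant for descriptor-space fixtures
placeholder_smiles <- function(n) {
  paste0(strrep("C", 1 + (seq_len(n) - 1) %% 10),
         ifelse(seq_len(n) %% 2 == 0, "O", ""))
}

#' Generate a synthetic training panel with planted structure
#'
#' Descriptor values are iid standard normal; activators are shifted by
#' `effect_size` in the informative dimensions, and prolonged activators
#' additionally in the kinetics dimensions. Activity values are centred at
#' 60 spikes/s above spontaneous firing for actives (the magnitude of a
#' strong tonic ORN response) and near 0 for inactives.
#'
#' @param cfg A [chem_sim_config()].
#' @return List with `compounds` (id, smiles, activity, active_label,
#'   kinetics_label), `matrix` (raw `descriptor_matrix`, provenance
#'   `"simulated"`), and `truth`: `informative` / `kinetics` descriptor
#'   names, `informative_idx` / `kinetics_idx` column indices, `active_ids`,
#'   `prolonged_ids`.
#' @examples
#' sim <- gen_training_set(chem_sim_config(seed = 1))
#' dim(sim$matrix$values)            # 47 x 200
#' sum(sim$compounds$active_label == "active")  # 14
#' @export
gen_training_set <- function(cfg = chem_sim_config()) {
  stopifnot(inherits(cfg, "chem_sim_config"))
  dims <- planted_dims(cfg)  # also seeds the RNG deterministically
  n <- cfg$n_molecules; d <- cfg$n_descriptors
  active_idx <- sort(sample.int(n, cfg$n_active))
  prolonged_idx <- sort(sample(active_idx, cfg$n_prolonged))
  V <- matrix(rnorm(n * d), n, d)
  V[active_idx, dims$informative] <-
    V[active_idx, dims$informative] + cfg$effect_size
  V[prolonged_idx, dims$kinetics] <-
    V[prolonged_idx, dims$kinetics] + cfg$effect_size
  activity <- rnorm(n, 0, 1)
  activity[active_idx] <- 60 * (1 + 0.1 * rnorm(cfg$n_active))
  ids <- sprintf("mol%03d", seq_len(n))
  active_label <- rep("inactive", n); active_label[active_idx] <- "active"
  kinetics_label <- rep("unknown", n)
  kinetics_label[active_idx] <- "transient"
  kinetics_label[prolonged_idx] <- "prolonged"
  compounds <- data.frame(id = ids, smiles = placeholder_smiles(n),
                          name = NA_character_, activity = activity,
                          active_label = active_label,
                          kinetics_label = kinetics_label,
                          stringsAsFactors = FALSE)
  dn <- desc_names(d)
  m <- descriptor_matrix(V, ids = ids, descriptors = dn,
                         provenance = "simulated")
  list(compounds = compounds, matrix = m,
       truth = list(informative = dn[dims$informative],
                    kinetics = dn[dims$kinetics],
                    informative_idx = dims$informative,
                    kinetics_idx = dims$kinetics,
                    active_ids = ids[active_idx],
                    prolonged_ids = ids[prolonged_idx]))
}

#' Generate a synthetic screening library with planted actives
#'
#' Samples a library in the same descriptor space as a training panel
#' generated from `cfg` (the planted informative dimensions are shared),
#' with `n_planted_active` molecules shifted like training actives. A
#' deterministic `fail_fraction` of records (the first
#' `round(fail_fraction * n_library)`) is given real SMILES violating the
#' physicochemical filters (disallowed element, excessive molecular weight
#' or multi-fragment), so filter logic is exercised end to end; all other
#' records carry small filter-passing SMILES.
#'
#' @param cfg The [chem_sim_config()] defining the planted geometry.
#' @param n_library Library size.
#' @param n_planted_active Number of planted actives (placed among
#'   filter-passing records).
#' @param fail_fraction Fraction of records built to fail the filters
#'   (default 0).
#' @param seed Seed for the library sampling (independent of the planted
#'   geometry, which follows `cfg$seed`).
#' @return List with `compounds`, `matrix` (raw, provenance
#'   `"simulated"`), and `truth`: `active_ids`, `fail_ids`, `informative`.
#' @export
gen_library <- function(cfg = chem_sim_config(), n_library = 5000,
                        n_planted_active = 50, fail_fraction = 0,
                        seed = 6) {
  stopifnot(inherits(cfg, "chem_sim_config"))
  dims <- planted_dims(cfg)
  set.seed(as.integer(seed))
  n <- n_library; d <- cfg$n_descriptors
  n_fail <- round(fail_fraction * n)
  fail_idx <- seq_len(n_fail)
  eligible <- setdiff(seq_len(n), fail_idx)
  if (length(eligible) < n_planted_active)
    stopf("not enough filter-passing records to plant %d actives",
          n_planted_active)
  active_idx <- sort(sample(eligible, n_planted_active))
  V <- matrix(rnorm(n * d), n, d)
  V[active_idx, dims$informative] <-
    V[active_idx, dims$informative] + cfg$effect_size
  ids <- sprintf("lib%06d", seq_len(n))
  pass_pool <- c("CCO", "CCOC(C)=O", "CCCCO", "CC(C)=O", "CCN", "CCS",
                 "c1ccoc1", "CC(C)O")
  fail_pool <- c("Clc1ccccc1",                       # disallowed element
                 "CCCCCCCCCCCCCCCCCCCCCCCC",        # C24 alkane, MW > 325
                 "[Na+].[Cl-]")                     # multifragment
  smiles <- pass_pool[1 + (seq_len(n) - 1) %% length(pass_pool)]
  if (n_fail) smiles[fail_idx] <-
    fail_pool[1 + (fail_idx - 1) %% length(fail_pool)]
  compounds <- data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
  dn <- desc_names(d)
  m <- descriptor_matrix(V, ids = ids, descriptors = dn,
                         provenance = "simulated")
  list(compounds = compounds, matrix = m,
       truth = list(active_ids = ids[active_idx],
                    fail_ids = ids[fail_idx],
                    informative = dn[dims$informative]))
}

#' Configuration for synthetic ORN spike trains
#'
#' Defaults mirror the recorded response regimes: spontaneous firing ~8
#' spikes/s, a phasic peak of 200 spikes/s excess decaying with time
#' constant 1.5 s (transient activators) or 4 s (prolonged), a tonic
#' plateau of 60 spikes/s excess lasting 220 s for prolonged activators, a
#' 0.5-s stimulus at t = 0, and a [-30, 300] s recording window.
#'
#' @param baseline_rate Spontaneous rate, spikes/s (default 8).
#' @param peak_excess Phasic peak excess, spikes/s (default 200).
#' @param decay_tau_transient,decay_tau_prolonged Phasic decay time
#'   constants, s (defaults 1.5 and 4).
#' @param plateau_excess Tonic plateau excess, spikes/s (default 60).
#' @param plateau_duration Plateau length, s (default 220).
#' @param stim_duration Stimulus length, s (default 0.5).
#' @param window Recording window (default `c(-30, 300)`).
#' @param n_trials Trials per condition (default 20).
#' @param masking_gain Multiplicative probe-response gain after a prolonged
#'   pre-exposure (default 0.1; planted masking index is `1 - gain`).
#' @param seed Integer seed.
#' @return A `spike_sim_config` list.
#' @export
spike_sim_config <- function(baseline_rate = 8, peak_excess = 200,
                             decay_tau_transient = 1.5,
                             decay_tau_prolonged = 4,
                             plateau_excess = 60, plateau_duration = 220,
                             stim_duration = 0.5, window = c(-30, 300),
                             n_trials = 20, masking_gain = 0.1, seed = 1) {
  if (any(c(baseline_rate, peak_excess, plateau_excess) < 0))
    stopf("rates must be non-negative")
  if (masking_gain < 0 || masking_gain > 1)
    stopf("masking_gain must be in [0, 1]")
  structure(list(baseline_rate = baseline_rate, peak_excess = peak_excess,
                 decay_tau_transient = decay_tau_transient,
                 decay_tau_prolonged = decay_tau_prolonged,
                 plateau_excess = plateau_excess,
                 plateau_duration = plateau_duration,
                 stim_duration = stim_duration, window = window,
                 n_trials = n_trials, masking_gain = masking_gain,
                 seed = as.integer(seed)),
            class = "spike_sim_config")
}

# Sample one inhomogeneous-Poisson trial by thinning under a
# piecewise-constant dominating envelope. `breaks` must include every time
# at which the rate can jump upward; between consecutive grid points the
# rate is non-increasing, so the envelope is the rate at the left edge.
thin_poisson <- function(rate_fn, window, breaks = numeric(0)) {
  grid <- sort(unique(c(seq(window[1], window[2], by = 1), breaks,
                        window[2])))
  grid <- grid[grid >= window[1] & grid <= window[2]]
  left <- grid[-length(grid)]
  len <- diff(grid)
  env <- rate_fn(left + 1e-12)
  counts <- rpois(length(left), env * len)
  t_prop <- runif(sum(counts)) * rep(len, counts) + rep(left, counts)
  keep <- runif(length(t_prop)) < rate_fn(t_prop) / rep(env, counts)
  s <- sort(t_prop[keep])
  # enforce the 1e-6 s distinctness invariant of spike_trains
  if (length(s) > 1L) s <- s[c(TRUE, diff(s) >= 1e-6)]
  s
}

#' Generate synthetic ORN spike trains
#'
#' Draws `n_trials` spike trains from an inhomogeneous Poisson process by
#' thinning. The rate is `baseline` everywhere, plus -- for the transient
#' and prolonged profiles -- a phasic component
#' `peak_excess * exp(-(t - t0)/tau)` from stimulus onset, plus -- for the
#' prolonged profile only -- a tonic component `plateau_excess` on
#' `[t0, t0 + plateau_duration]`. The exact rate function is returned for
#' oracle checks.
#'
#' @param cfg A [spike_sim_config()].
#' @param profile `"transient"`, `"prolonged"` or `"baseline"`.
#' @param seed Seed override (defaults to `cfg$seed`).
#' @return List with `trains` (a [spike_trains()] object), `rate_fn`
#'   (vectorized function of time, spikes/s), `profile`, `cfg`.
#' @examples
#' sim <- gen_spike_trains(spike_sim_config(n_trials = 3, seed = 8),
#'                         "prolonged")
#' tc <- rate_timecourse(sim$trains)
#' kinetics_summary(tc)
#' @export
gen_spike_trains <- function(cfg = spike_sim_config(),
                             profile = c("transient", "prolonged",
                                         "baseline"),
                             seed = cfg$seed) {
  stopifnot(inherits(cfg, "spike_sim_config"))
  profile <- match.arg(profile)
  t0 <- 0
  tau <- switch(profile, transient = cfg$decay_tau_transient,
                prolonged = cfg$decay_tau_prolonged, baseline = NA)
  rate_fn <- function(t) {
    r <- rep(cfg$baseline_rate, length(t))
    if (profile != "baseline") {
      on <- t >= t0
      r[on] <- r[on] + cfg$peak_excess * exp(-(t[on] - t0) / tau)
      if (profile == "prolonged") {
        plat <- t >= t0 & t <= t0 + cfg$plateau_duration
        r[plat] <- r[plat] + cfg$plateau_excess
      }
    }
    r
  }
  set.seed(as.integer(seed))
  breaks <- if (profile == "baseline") numeric(0)
            else c(t0, t0 + cfg$plateau_duration)
  spikes <- lapply(seq_len(cfg$n_trials), function(i)
    thin_poisson(rate_fn, cfg$window, breaks))
  trains <- spike_trains(spikes, t0 = t0, stim_duration = cfg$stim_duration,
                         window = cfg$window,
                         odorant = paste0("sim_", profile))
  list(trains = trains, rate_fn = rate_fn, profile = profile, cfg = cfg)
}

#' Generate a synthetic masking experiment
#'
#' Builds matched exposed/control spike-train sets for a pre-exposure
#' masking experiment. Control trials receive only brief probe stimuli
#' (transient responses at each probe time). Exposed trials additionally
#' receive a pre-exposure response at t = 0 -- transient or prolonged --
#' and their probe-response gain is multiplied by `masking_gain` when the
#' pre-exposure is prolonged (1.0 when transient). The prolonged
#' pre-exposure also superimposes its own tonic plateau on the exposed
#' trials.
#'
#' @param cfg A [spike_sim_config()].
#' @param pre_exposure `"transient"` or `"prolonged"`.
#' @param probe_times Probe onset times, s (default `c(15, 30)`).
#' @param seed Seed override (defaults to `cfg$seed`).
#' @return List with `exposed`, `control` ([spike_trains()] objects),
#'   `gains` (true probe gain per probe time), `exposed_rate_fn`,
#'   `control_rate_fn`, `probe_times`, `cfg`.
#' @export
gen_masking_experiment <- function(cfg = spike_sim_config(),
                                   pre_exposure = c("transient", "prolonged"),
                                   probe_times = c(15, 30),
                                   seed = cfg$seed) {
  stopifnot(inherits(cfg, "spike_sim_config"))
  pre_exposure <- match.arg(pre_exposure)
  gain <- if (pre_exposure == "prolonged") cfg$masking_gain else 1.0
  tau_probe <- cfg$decay_tau_transient
  probe_component <- function(t) {
    r <- numeric(length(t))
    for (tp in probe_times) {
      on <- t >= tp
      r[on] <- r[on] + cfg$peak_excess * exp(-(t[on] - tp) / tau_probe)
    }
    r
  }
  tau_pre <- if (pre_exposure == "prolonged") cfg$decay_tau_prolonged
             else cfg$decay_tau_transient
  pre_component <- function(t) {
    r <- numeric(length(t))
    on <- t >= 0
    r[on] <- cfg$peak_excess * exp(-t[on] / tau_pre)
    if (pre_exposure == "prolonged") {
      plat <- t >= 0 & t <= cfg$plateau_duration
      r[plat] <- r[plat] + cfg$plateau_excess
    }
    r
  }
  control_rate <- function(t) cfg$baseline_rate + probe_component(t)
  exposed_rate <- function(t)
    cfg$baseline_rate + pre_component(t) + gain * probe_component(t)
  breaks <- c(0, probe_times, cfg$plateau_duration)
  set.seed(as.integer(seed))
  exposed <- lapply(seq_len(cfg$n_trials), function(i)
    thin_poisson(exposed_rate, cfg$window, breaks))
  control <- lapply(seq_len(cfg$n_trials), function(i)
    thin_poisson(control_rate, cfg$window, breaks))
  list(exposed = spike_trains(exposed, t0 = 0,
                              stim_duration = cfg$stim_duration,
                              window = cfg$window,
                              odorant = paste0("masking_", pre_exposure)),
       control = spike_trains(control, t0 = 0,
                              stim_duration = cfg$stim_duration,
                              window = cfg$window, odorant = "masking_control"),
       gains = setNames(rep(gain, length(probe_times)),
                        as.character(probe_times)),
       exposed_rate_fn = exposed_rate, control_rate_fn = control_rate,
       probe_times = probe_times, cfg = cfg)
}
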