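#' Construct a set of spike trains
#'
#' Container for repeated single-unit trials of one odorant stimulus:
#' per-trial sorted spike times (seconds) on a common recording window,
#' with the stimulus onset and duration (the standard protocol is a 0.5-s
#' odor pulse at t = 0 within a window such as [-30, 300] s).
#'
#' @param spikes List of numeric vectors, one per trial, of spike times in
#'   seconds (will be sorted; duplicates within 1e-6 s rejected).
#' @param t0 Stimulus onset (s), default 0.
#' @param stim_duration Stimulus duration (s), default 0.5.
#' @param window Recording window `c(t_start, t_end)`; must contain the
#'   stimulus.
#' @param odorant,dilution Identifier strings (dilution as log10 string,
#'   e.g. `"1e-2"`).
#' @param trial_ids Optional trial identifiers.
#' @return An object of class `spike_trains`.
#' @export
spike_trains <- function(spikes, t0 = 0, stim_duration = 0.5,
                         window = c(-30, 300), odorant = "odor",
                         dilution = "1e-2", trial_ids = NULL) {
  stopifnot(is.list(spikes), length(window) == 2L, window[1] < window[2])
  if (t0 < window[1] || t0 + stim_duration > window[2])
    stopf("stimulus [%g, %g] not within recording window [%g, %g]",
          t0, t0 + stim_duration, window[1], window[2])
  if (is.null(trial_ids)) trial_ids <- paste0("trial", seq_along(spikes))
  spikes <- lapply(seq_along(spikes), function(i) {
    s <- sort(as.numeric(spikes[[i]]))
    if (length(s)) {
      if (any(s < window[1] | s > window[2]))
        stopf("trial %s has spike times outside the recording window",
              trial_ids[i])
      if (any(diff(s) < 1e-6))
        stopf("trial %s has duplicate spike times (within 1e-6 s)",
              trial_ids[i])
    }
    s
  })
  structure(list(spikes = spikes, trial_ids = as.character(trial_ids),
                 t0 = t0, stim_duration = stim_duration, window = window,
                 odorant = odorant, dilution = dilution),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("spike_trains: %s (%s), %d trial(s), window [%g, %g] s, %d spikes\n",
              x$odorant, x$dilution, length(x$spikes), x$window[1],
              x$window[2], total_spikes(x)))
  invisible(x)
}

#' Total spike count across trials
#' @param trains A `spike_trains` object.
#' @return Integer total number of spikes.
#' @export
total_spikes <- function(trains) sum(lengths(trains$spikes))

#' Read / write spike trains as long-format delimited text
#'
#' One spike per row with columns `trial_id`, `odorant`, `dilution`, `t0`,
#' `stim_duration`, `spike_time_s` (tab-separated). `read_spike_trains`
#' returns a list of `spike_trains`, one per odorant x dilution group.
#' Trials with zero spikes cannot be represented in this format.
#'
#' @param path File path.
#' @param window Recording window to assume on read (default `c(-30, 300)`).
#' @return A named list of `spike_trains` (read) or `path` (write).
#' @export
read_spike_trains <- function(path, window = c(-30, 300)) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("trial_id", "odorant", "dilution", "t0", "stim_duration",
            "spike_time_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("spike table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  key <- paste(df$odorant, df$dilution, sep = "@")
  lapply(split(df, key), function(g) {
    by_trial <- split(g$spike_time_s, g$trial_id)
    spike_trains(by_trial, t0 = g$t0[1], stim_duration = g$stim_duration[1],
                 window = window, odorant = g$odorant[1],
                 dilution = as.character(g$dilution[1]),
                 trial_ids = names(by_trial))
  })
}

#' @rdname read_spike_trains
#' @param trains A `spike_trains` object.
#' @export
write_spike_trains <- function(trains, path) {
  df <- do.call(rbind, lapply(seq_along(trains$spikes), function(i) {
    s <- trains$spikes[[i]]
    if (!length(s)) return(NULL)
    data.frame(trial_id = trains$trial_ids[i], odorant = trains$odorant,
               dilution = trains$dilution, t0 = trains$t0,
               stim_duration = trains$stim_duration,
               spike_time_s = fmt_num(s), stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Peri-stimulus firing-rate timecourse
#'
#' Bins each trial's spikes on a common uniform grid, converts to rates
#' (spikes/s), and averages across trials, with the across-trial s.e.m.
#' per bin -- the standard mean long-term response display. The baseline
#' (spontaneous) rate is the mean rate over a strictly pre-stimulus window.
#'
#' @param trains A `spike_trains` object.
#' @param bin_width Bin width in seconds (default 1).
#' @param baseline_window Pre-stimulus window `c(from, to)` for the
#'   spontaneous rate, default `c(-10, 0)`; must lie within the recording
#'   window and end at or before stimulus onset.
#' @return An object of class `rate_timecourse`: `edges`, `mid`, `rate`
#'   (mean spikes/s per bin), `sem`, `bin_counts` (pooled integer spike
#'   counts per bin), `n_trials`, `baseline`, `baseline_sem`, `bin_width`,
#'   `t0`, `total_spikes`.
#' @export
rate_timecourse <- function(trains, bin_width = 1,
                            baseline_window = c(-10, 0)) {
  stopifnot(inherits(trains, "spike_trains"))
  if (bin_width <= 0) stopf("bin_width must be positive")
  w <- trains$window
  if (baseline_window[1] < w[1] || baseline_window[2] > w[2])
    stopf("baseline window [%g, %g] outside recording window [%g, %g]",
          baseline_window[1], baseline_window[2], w[1], w[2])
  if (baseline_window[2] > trains$t0)
    stopf("baseline window must end at or before stimulus onset")
  n_bins <- ceiling((w[2] - w[1]) / bin_width - 1e-9)
  edges <- w[1] + bin_width * seq(0, n_bins)
  n_trials <- length(trains$spikes)
  counts <- matrix(0L, n_trials, n_bins)
  for (i in seq_len(n_trials)) {
    s <- trains$spikes[[i]]
    if (!length(s)) next
    idx <- pmin(floor((s - w[1]) / bin_width) + 1L, n_bins)  # end-inclusive last bin
    counts[i, ] <- tabulate(idx, nbins = n_bins)
  }
  rates <- counts / bin_width
  rate <- colMeans(rates)
  sem <- if (n_trials > 1) apply(rates, 2, sd) / sqrt(n_trials)
         else rep(NA_real_, n_bins)
  mid <- edges[-length(edges)] + bin_width / 2
  base_bins <- edges[-length(edges)] >= baseline_window[1] - 1e-9 &
    edges[-1] <= baseline_window[2] + 1e-9
  if (!any(base_bins)) stopf("baseline window contains no complete bin")
  baseline <- mean(rate[base_bins])
  baseline_sem <- if (n_trials > 1) mean(sem[base_bins]) else NA_real_
  structure(list(edges = edges, mid = mid, rate = rate, sem = sem,
                 bin_counts = as.integer(colSums(counts)),
                 n_trials = n_trials,
                 baseline = baseline, baseline_sem = baseline_sem,
                 bin_width = bin_width, t0 = trains$t0,
                 total_spikes = total_spikes(trains)),
            class = "rate_timecourse")
}

#' @export
print.rate_timecourse <- function(x, ...) {
  cat(sprintf("rate_timecourse: %d bins of %g s, %d trial(s), baseline %.2f spikes/s\n",
              length(x$rate), x$bin_width, x$n_trials, x$baseline))
  invisible(x)
}

#' Termination-kinetics summary of an ORN response
#'
#' Quantifies the phasic/tonic structure of a stimulus-evoked firing-rate
#' timecourse in terms of the excess rate `excess(t) = rate(t) - baseline`:
#'
#' * `peak_rate`: maximum excess within `peak_window` s of onset, and its
#'   time `t_peak`;
#' * `t_half`: time (after onset) at which the excess first falls below
#'   half the peak;
#' * `duration`: time after onset at which the excess first stays below
#'   `return_threshold` for `persistence` consecutive bins (if it never
#'   does, the window end is reported and `censored` is set);
#' * `plateau_rate`: median excess between `plateau_start` s after onset
#'   and the response end (undefined for responses ending before
#'   `plateau_start`);
#' * `prolonged`: `TRUE` iff `duration >= prolonged_threshold`.
#'
#' An odorant whose peak excess does not clear the activation threshold
#' (3 baseline s.e.m. above baseline by default, i.e. indistinguishable
#' from spontaneous-rate fluctuation) is treated as a non-activator: all
#' kinetics fields are `NA` and `prolonged` is `FALSE`.
#'
#' @param tc A `rate_timecourse` covering at least 10 s post-stimulus.
#' @param onset Stimulus onset (s); defaults to the timecourse's `t0`.
#' @param peak_window Width of the peak search window after onset (s,
#'   default 5).
#' @param plateau_start Start of the tonic plateau window, s after onset
#'   (default 30).
#' @param return_threshold Excess rate (spikes/s) under which the response
#'   is considered ended; default `max(2 * baseline_sem, 0.1 * peak_rate)`.
#' @param persistence Number of consecutive sub-threshold bins required to
#'   call the response ended (default 3).
#' @param prolonged_threshold Duration (s) at or above which an odorant is
#'   classified a prolonged activator (default 30).
#' @param activation_threshold Minimum peak excess (spikes/s) to count as
#'   an activation; default `3 * baseline_sem` (0 if unavailable).
#' @return An object of class `kinetics_summary` (a one-row data.frame):
#'   `peak_rate`, `t_peak`, `t_half`, `plateau_rate`, `duration`,
#'   `prolonged`, `censored`, `baseline`.
#' @export
kinetics_summary <- function(tc, onset = tc$t0, peak_window = 5,
                             plateau_start = 30, return_threshold = NULL,
                             persistence = 3, prolonged_threshold = 30,
                             activation_threshold = NULL) {
  stopifnot(inherits(tc, "rate_timecourse"))
  t_end <- tc$edges[length(tc$edges)]
  if (t_end - onset < 10) stopf("timecourse covers < 10 s post-stimulus")
  left <- tc$edges[-length(tc$edges)]
  post <- which(left >= onset - 1e-9)
  excess <- tc$rate - tc$baseline
  na_summary <- function() data.frame(
    peak_rate = NA_real_, t_peak = NA_real_, t_half = NA_real_,
    plateau_rate = NA_real_, duration = NA_real_, prolonged = FALSE,
    censored = FALSE, baseline = tc$baseline)
  peak_bins <- post[left[post] < onset + peak_window]
  pk <- which.max(excess[peak_bins])
  peak_rate <- excess[peak_bins][pk]
  act_thr <- activation_threshold %||%
    (3 * (if (is.na(tc$baseline_sem)) 0 else tc$baseline_sem))
  if (!length(peak_rate) || peak_rate <= act_thr) {
    out <- na_summary()
    class(out) <- c("kinetics_summary", class(out))
    return(out)
  }
  i_peak <- peak_bins[pk]
  t_peak <- tc$mid[i_peak] - onset
  after <- post[post > i_peak]
  below_half <- after[excess[after] < peak_rate / 2]
  t_half <- if (length(below_half)) tc$mid[below_half[1]] - onset else NA_real_
  thr <- return_threshold %||%
    max(2 * (if (is.na(tc$baseline_sem)) 0 else tc$baseline_sem),
        0.1 * peak_rate)
  below <- excess[post] < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= persistence)
  if (length(qual)) {
    duration <- left[post[starts[qual[1]]]] - onset
    censored <- FALSE
  } else {
    duration <- t_end - onset
    censored <- TRUE
  }
  plateau_rate <- NA_real_
  if (duration > plateau_start) {
    plat_bins <- post[left[post] >= onset + plateau_start - 1e-9 &
                        left[post] < onset + duration]
    if (length(plat_bins)) plateau_rate <- median(excess[plat_bins])
  }
  out <- data.frame(peak_rate = peak_rate, t_peak = t_peak, t_half = t_half,
                    plateau_rate = plateau_rate, duration = duration,
                    prolonged = duration >= prolonged_threshold,
                    censored = censored, baseline = tc$baseline)
  class(out) <- c("kinetics_summary", class(out))
  out
}

#' Masking of probe responses after odor pre-exposure
#'
#' Quantifies how pre-exposure to an odorant suppresses responses to brief
#' probe stimuli of an activating odorant delivered at later times. For
#' each probe time and condition, the probe-evoked excess is the firing
#' rate in the probe window minus the rate in the immediately preceding
#' pre-probe window (averaged across trials); subtracting the local
#' pre-probe rate cancels any tonic pedestal from the pre-exposure itself.
#' The masking index is `1 - exposed_excess / control_excess`: 0 when the
#' exposed response equals control, 1 when fully abolished.
#'
#' @param exposed `spike_trains` recorded after the pre-exposure.
#' @param control Matched `spike_trains` without (or with a transient)
#'   pre-exposure, same probe times.
#' @param probe_times Probe onset times (s).
#' @param probe_window Probe response window length (s, default 2).
#' @param preprobe_window Pre-probe reference window length (s, default 2).
#' @return An object of class `masking_profile` (a data.frame): per probe,
#'   `probe_time`, `control_excess`, `exposed_excess`, `masking_index`,
#'   `defined` (`FALSE`, with `NA` index, where the control excess is
#'   non-positive).
#' @export
masking_profile <- function(exposed, control, probe_times, probe_window = 2,
                            preprobe_window = 2) {
  stopifnot(inherits(exposed, "spike_trains"),
            inherits(control, "spike_trains"))
  win_rate <- function(trains, from, to) {
    mean(vapply(trains$spikes, function(s)
      sum(s >= from & s < to) / (to - from), numeric(1)))
  }
  probe_excess <- function(trains, tp) {
    win_rate(trains, tp, tp + probe_window) -
      win_rate(trains, tp - preprobe_window, tp)
  }
  ctrl <- vapply(probe_times, probe_excess, numeric(1), trains = control)
  expo <- vapply(probe_times, probe_excess, numeric(1), trains = exposed)
  defined <- ctrl > 0
  idx <- ifelse(defined, 1 - expo / ctrl, NA_real_)
  out <- data.frame(probe_time = probe_times, control_excess = ctrl,
                    exposed_excess = expo, masking_index = idx,
                    defined = defined)
  class(out) <- c("masking_profile", class(out))
  out
}
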