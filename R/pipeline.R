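# End-to-end orchestration: train -> validate -> screen, and kinetics runs,
# from a single config, with a resolved-config snapshot, stage logging and
# hash-checked resume.

pipeline_defaults <- function() {
  list(
    seed = 1,
    outdir = "orntools_run",
    compounds = NULL,          # path to compound table
    descriptors = NULL,        # optional path to precomputed matrix
    spikes = NULL,             # path to spike-train table (kinetics runs)
    library = NULL,            # path to screening library table
    library_descriptors = NULL,
    scale = TRUE,
    max_missing_frac = 0.2,
    target_size = 13,
    stop_rule = "fixed_size",
    plateau_tol = 1e-4,
    fitness = "moderated_fisher",
    linkage = "average",
    distance = "euclidean",
    cost = 1, gamma = NULL, epsilon = 0.1,
    cv_k = 5, cv_repeats = 20,
    mw_max = 325,
    allowed_elements = c("C", "O", "N", "H", "S"),
    chunk_size = 10000,
    bin_width = 1,
    baseline_window = c(-10, 0),
    prolonged_threshold = 30,
    log_level = "info")
}

#' Read (or build) a pipeline run configuration
#'
#' Merges a YAML config file and/or an override list over the package
#' defaults. See [run_train_validate()] for the recognized fields.
#'
#' @param path Optional YAML file.
#' @param overrides Optional named list applied after the file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stopf("unknown config field(s): %s",
                               paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stopf("unknown config override(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg, files = character(0)) {
  files <- files[!vapply(files, is.null, logical(1))]
  fh <- if (length(files)) unname(tools::md5sum(unlist(files))) else character(0)
  object_hash(lapply(cfg[order(names(cfg))], function(x)
    paste(as.character(x), collapse = ",")), fh)
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[orntools %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

write_snapshot <- function(cfg, hash, outdir) {
  snap <- c(list(tool = "orntools",
                 version = as.character(packageVersion("orntools")),
                 config_hash = hash), unclass(cfg))
  snap <- snap[!vapply(snap, is.null, logical(1))]
  yaml::write_yaml(snap, file.path(outdir, "config.snapshot.yaml"))
}

stamp_header <- function(path, hash, seed) {
  lines <- readLines(path)
  writeLines(c(sprintf("# orntools config_hash=%s seed=%d", hash,
                       as.integer(seed)), lines), path)
}

# A stage is current when its artifact exists and the stored stage hash
# matches; `resume = TRUE` demands that any existing artifact match.
stage_current <- function(artifact, hash, resume) {
  hfile <- paste0(artifact, ".hash")
  if (!file.exists(artifact) || !file.exists(hfile)) return(FALSE)
  stored <- readLines(hfile, n = 1L)
  if (identical(stored, hash)) return(TRUE)
  if (resume)
    stopf("artifact %s was produced under a different config/input (hash mismatch); rerun without resume for a clean run",
          artifact)
  FALSE
}

mark_stage <- function(artifact, hash) writeLines(hash, paste0(artifact, ".hash"))

#' Run the training and validation pipeline
#'
#' Executes descriptors -> clean/scale -> SFS subset selection ->
#' clustering -> SVM training -> repeated k-fold cross-validation, from a
#' compound table (and optional precomputed descriptor table), persisting
#' all artifacts under `cfg$outdir`: `descriptors.tsv` (+ scaling sidecar),
#' `subset.txt`, `dendrogram.nwk`, `model.txt`, `cv_report.tsv` (+ `.roc`),
#' and a resolved `config.snapshot.yaml`. Each artifact carries a config
#' hash; with `resume = TRUE`, stages whose artifact and hash are current
#' are skipped, and a hash mismatch aborts with instructions to rerun
#' clean.
#'
#' @param cfg A `run_config` (see [read_run_config()]) or path to a YAML
#'   config.
#' @param resume Reuse current artifacts where hashes match (default
#'   `FALSE`).
#' @return Invisibly, a list with the `subset`, `model`, `cv` and
#'   `dendrogram` objects and the artifact paths.
#' @export
run_train_validate <- function(cfg, resume = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$compounds)) stopf("config field 'compounds' is required")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg, c(cfg$compounds, cfg$descriptors))
  write_snapshot(cfg, hash, cfg$outdir)
  mols <- parse_compounds(cfg$compounds)
  labels <- mols$active_label
  path <- function(f) file.path(cfg$outdir, f)

  desc_art <- path("descriptors.tsv")
  if (stage_current(desc_art, hash, resume)) {
    log_msg(cfg, "descriptors: reusing %s", desc_art)
    m <- read_descriptor_matrix(desc_art)
  } else {
    raw <- if (!is.null(cfg$descriptors)) read_descriptor_matrix(cfg$descriptors)
           else compute_descriptors(mols)
    m <- clean_matrix(raw, max_missing_frac = cfg$max_missing_frac)
    if (isTRUE(cfg$scale)) m <- scale_matrix(m)
    write_descriptor_matrix(m, desc_art)
    mark_stage(desc_art, hash)
    log_msg(cfg, "descriptors: %d x %d (%d dropped in cleaning)",
            nrow(m$values), ncol(m$values),
            if (is.null(m$drop_log)) 0L else nrow(m$drop_log))
  }

  subset_art <- path("subset.txt")
  if (stage_current(subset_art, hash, resume)) {
    log_msg(cfg, "subset: reusing %s", subset_art)
    subset <- read_subset(subset_art)
  } else {
    subset <- sfs_select(m, labels,
                         target_size = min(cfg$target_size, ncol(m$values)),
                         stop_rule = cfg$stop_rule,
                         plateau_tol = cfg$plateau_tol,
                         fitness = cfg$fitness)
    write_subset(subset, subset_art)
    mark_stage(subset_art, hash)
    log_msg(cfg, "subset: selected %d descriptor(s), fitness %.4f",
            length(subset$selected), max(subset$fitness_trajectory))
  }

  dend_art <- path("dendrogram.nwk")
  if (!stage_current(dend_art, hash, resume)) {
    den <- cluster_odorants(m, subset, linkage = cfg$linkage,
                            distance = cfg$distance)
    write_dendrogram(den, dend_art)
    mark_stage(dend_art, hash)
    log_msg(cfg, "dendrogram: %d leaves", length(den$leaf_ids))
  } else {
    log_msg(cfg, "dendrogram: reusing %s", dend_art)
    den <- NULL
  }

  model_art <- path("model.txt")
  if (stage_current(model_art, hash, resume)) {
    log_msg(cfg, "model: reusing %s", model_art)
    model <- load_model(model_art)
  } else {
    model <- train_svm(m, subset, mols$activity, cost = cfg$cost,
                       gamma = cfg$gamma, epsilon = cfg$epsilon)
    save_model(model, model_art)
    mark_stage(model_art, hash)
    log_msg(cfg, "model: %d support vectors", nrow(model$SV))
  }

  cv_art <- path("cv_report.tsv")
  if (stage_current(cv_art, hash, resume)) {
    log_msg(cfg, "cv: reusing %s", cv_art)
    cv <- NULL
  } else {
    cv <- cross_validate(m, subset, mols$activity, labels, k = cfg$cv_k,
                         repeats = cfg$cv_repeats, seed = cfg$seed,
                         cost = cfg$cost, gamma = cfg$gamma,
                         epsilon = cfg$epsilon)
    write_cv_report(cv, cv_art)
    stamp_header(cv_art, hash, cfg$seed)
    mark_stage(cv_art, hash)
    log_msg(cfg, "cv: %d-fold x %d mean AUC %.4f", cv$k, cv$repeats,
            cv$mean_auc)
  }

  invisible(list(subset = subset, model = model, cv = cv, dendrogram = den,
                 artifacts = c(descriptors = desc_art, subset = subset_art,
                               dendrogram = dend_art, model = model_art,
                               cv_report = cv_art)))
}

#' Run the virtual screen
#'
#' Loads the trained model artifact and a compound library (optionally with
#' a precomputed descriptor table), applies the physicochemical filters and
#' the model, and writes the ranked candidate list (`screen.tsv` +
#' `screen.tsv.rejected`) under `cfg$outdir`, logging filter attrition
#' counts.
#'
#' @inheritParams run_train_validate
#' @return Invisibly, the `screen_result`.
#' @export
run_screen <- function(cfg, resume = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$library)) stopf("config field 'library' is required")
  model_art <- file.path(cfg$outdir, "model.txt")
  if (!file.exists(model_art)) stopf("model artifact not found: %s (run run_train_validate first)",
                                     model_art)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg, c(cfg$library, cfg$library_descriptors, model_art))
  model <- load_model(model_art)
  lib <- parse_compounds(cfg$library)
  desc <- if (!is.null(cfg$library_descriptors))
    read_descriptor_matrix(cfg$library_descriptors)
  res <- screen_library(model, lib, descriptors = desc, mw_max = cfg$mw_max,
                        allowed_elements = cfg$allowed_elements,
                        chunk_size = cfg$chunk_size)
  out <- file.path(cfg$outdir, "screen.tsv")
  write_screen_result(res, out)
  stamp_header(out, hash, cfg$seed)
  mark_stage(out, hash)
  log_msg(cfg, "screen: %d / %d passed filters", res$n_passed, res$n_library)
  for (r in names(res$attrition))
    log_msg(cfg, "  attrition %s: %d", r, res$attrition[[r]])
  invisible(res)
}

#' Run the kinetics analysis
#'
#' Reads a long-format spike-train table, computes the rate timecourse and
#' termination-kinetics summary for each odorant x dilution group, and
#' writes `timecourse.tsv` (per-bin mean rate and s.e.m. per group) and
#' `kinetics_summary.tsv` (one row per group) under `cfg$outdir`.
#'
#' @inheritParams run_train_validate
#' @return Invisibly, a list with `timecourses` and the `summary`
#'   data.frame.
#' @export
run_kinetics <- function(cfg, resume = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$spikes)) stopf("config field 'spikes' is required")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg, cfg$spikes)
  groups <- read_spike_trains(cfg$spikes)
  tcs <- lapply(groups, rate_timecourse, bin_width = cfg$bin_width,
                baseline_window = cfg$baseline_window)
  summaries <- do.call(rbind, lapply(names(tcs), function(g) {
    ks <- kinetics_summary(tcs[[g]],
                           prolonged_threshold = cfg$prolonged_threshold)
    data.frame(odorant = groups[[g]]$odorant,
               dilution = groups[[g]]$dilution, ks,
               stringsAsFactors = FALSE)
  }))
  tc_long <- do.call(rbind, lapply(names(tcs), function(g) {
    tc <- tcs[[g]]
    data.frame(odorant = groups[[g]]$odorant,
               dilution = groups[[g]]$dilution, t = tc$mid, rate = tc$rate,
               sem = tc$sem, stringsAsFactors = FALSE)
  }))
  tc_path <- file.path(cfg$outdir, "timecourse.tsv")
  sum_path <- file.path(cfg$outdir, "kinetics_summary.tsv")
  write.table(tc_long, tc_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(summaries, sum_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  stamp_header(tc_path, hash, cfg$seed)
  stamp_header(sum_path, hash, cfg$seed)
  mark_stage(sum_path, hash)
  log_msg(cfg, "kinetics: %d odorant x dilution group(s)", length(tcs))
  invisible(list(timecourses = tcs, summary = summaries))
}
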