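#' Construct a descriptor matrix
#'
#' Container for a molecules-by-descriptors numeric table, with optional
#' per-descriptor scaling metadata and a provenance tag. Most users obtain
#' one from [compute_descriptors()], [read_descriptor_matrix()] or the
#' synthetic generators rather than calling this directly.
#'
#' @param values Numeric matrix, rows = molecules, columns = descriptors.
#' @param ids Molecule identifiers (unique), length `nrow(values)`.
#' @param descriptors Descriptor names (unique), length `ncol(values)`.
#' @param scaling `NULL`, or `list(center=, spread=)` of named numeric
#'   vectors, one entry per descriptor, recording the transform already
#'   applied to `values`.
#' @param provenance One of `"computed"`, `"ingested"`, `"simulated"`.
#' @return An object of class `descriptor_matrix`: a list with elements
#'   `values`, `scaling`, `provenance` and (after [clean_matrix()]) a
#'   `drop_log`.
#' @export
descriptor_matrix <- function(values, ids = rownames(values),
                              descriptors = colnames(values),
                              scaling = NULL,
                              provenance = c("computed", "ingested",
                                             "simulated")) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids)) ids <- paste0("mol", seq_len(nrow(values)))
  if (is.null(descriptors)) descriptors <- paste0("d", seq_len(ncol(values)))
  ids <- as.character(ids); descriptors <- as.character(descriptors)
  if (anyDuplicated(ids)) stopf("duplicate molecule ids in descriptor matrix")
  if (anyDuplicated(descriptors)) stopf("duplicate descriptor names")
  if (length(ids) != nrow(values) || length(descriptors) != ncol(values))
    stopf("dimension mismatch between values and ids/descriptors")
  dimnames(values) <- list(ids, descriptors)
  if (!is.null(scaling)) {
    scaling$center <- scaling$center[descriptors]
    scaling$spread <- scaling$spread[descriptors]
    if (anyNA(scaling$center) || anyNA(scaling$spread))
      stopf("scaling metadata does not cover all descriptors")
  }
  structure(list(values = values, scaling = scaling, provenance = provenance,
                 drop_log = NULL),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("descriptor_matrix: %d molecules x %d descriptors (%s%s)\n",
              nrow(x$values), ncol(x$values), x$provenance,
              if (is.null(x$scaling)) "" else ", scaled"))
  if (!is.null(x$drop_log) && nrow(x$drop_log))
    cat(sprintf("  %d descriptor(s) dropped during cleaning\n",
                nrow(x$drop_log)))
  invisible(x)
}

# Parse SMILES into an SDFset, raising an error that names the offending
# molecule id. Batch conversion first (fast path); on failure, bisect by
# converting one at a time.
smiles_to_sdf <- function(smiles, ids) {
  stopifnot(length(smiles) == length(ids))
  names(smiles) <- ids
  res <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  ok <- !is.null(res) && length(res) == length(smiles) &&
    all(ChemmineR::validSDF(res))
  if (ok) return(res)
  for (i in seq_along(smiles)) {
    one <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
                    error = function(e) NULL)
    if (is.null(one) || !all(ChemmineR::validSDF(one)))
      stopf("unparseable SMILES for molecule '%s'", ids[i])
  }
  stopf("SMILES batch conversion failed for an undetermined molecule")
}

# Heavy-atom element symbols of one SDF molecule.
sdf_elements <- function(sdf1) {
  ab <- ChemmineR::atomblock(sdf1)
  unique(gsub("_[0-9]+$", "", rownames(ab)))
}

#' Compute an open 2-D molecular descriptor matrix
#'
#' Computes a compact open-source 2-D descriptor block for each compound via
#' the openbabel toolchain (ChemmineR/ChemmineOB): physicochemical
#' properties (molecular weight with implicit hydrogens, logP, molar
#' refractivity, topological polar surface area, H-bond donor/acceptor
#' counts), per-element atom counts (hydrogens included) and functional
#' group counts. The pipeline downstream is descriptor-set agnostic, so
#' externally computed matrices (e.g. a commercial descriptor suite) can be
#' supplied instead via [read_descriptor_matrix()].
#'
#' @param mols Compound table (see [parse_compounds()]).
#' @param descriptor_set Descriptor collection; currently `"openbabel_2d"`.
#' @return A `descriptor_matrix` with `provenance = "computed"`, one row per
#'   input molecule in input order. Descriptors that fail for a molecule are
#'   `NA` (handled by [clean_matrix()]).
#' @examples
#' \donttest{
#' mols <- data.frame(id = c("etoh", "ea"), smiles = c("CCO", "CCOC(C)=O"))
#' m <- compute_descriptors(mols)
#' m$values[, "MW"]
#' }
#' @export
compute_descriptors <- function(mols, descriptor_set = "openbabel_2d") {
  descriptor_set <- match.arg(descriptor_set)
  if (nrow(mols) == 0L)
    return(descriptor_matrix(matrix(numeric(0), 0, 0), ids = character(0),
                             descriptors = character(0),
                             provenance = "computed"))
  sdf <- smiles_to_sdf(mols$smiles, mols$id)
  prop <- ChemmineR::propOB(sdf)
  num <- prop[, vapply(prop, is.numeric, logical(1)), drop = FALSE]
  blocks <- list(as.matrix(num))
  ac <- tryCatch(ChemmineR::atomcountMA(sdf, addH = TRUE),
                 error = function(e) NULL)
  if (!is.null(ac)) {
    colnames(ac) <- paste0("n", colnames(ac))
    blocks <- c(blocks, list(ac))
  }
  gr <- tryCatch(ChemmineR::groups(sdf, type = "countMA"),
                 error = function(e) NULL)
  if (!is.null(gr)) blocks <- c(blocks, list(as.matrix(gr)))
  vals <- do.call(cbind, blocks)
  rownames(vals) <- mols$id
  descriptor_matrix(vals, ids = mols$id, provenance = "computed")
}

#' Clean a descriptor matrix
#'
#' Drops descriptors whose missing-value fraction exceeds
#' `max_missing_frac` and descriptors with (near-)zero spread (population
#' standard deviation below `1e-12` on the non-missing raw values), then
#' imputes any remaining missing cells with the column median. The dropped
#' descriptors and reasons are recorded in the returned object's
#' `drop_log`.
#'
#' @param m A `descriptor_matrix`.
#' @param max_missing_frac Maximum tolerated fraction of missing values per
#'   descriptor (default 0.2).
#' @return A cleaned `descriptor_matrix` (no missing values, no zero-spread
#'   columns) with a `drop_log` data.frame (`descriptor`, `reason`).
#' @export
clean_matrix <- function(m, max_missing_frac = 0.2) {
  stopifnot(inherits(m, "descriptor_matrix"))
  v <- m$values
  miss_frac <- colMeans(is.na(v))
  pop_sd <- apply(v, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 1L) return(0)
    sqrt(mean((x - mean(x))^2))
  })
  drop_missing <- miss_frac > max_missing_frac
  drop_flat <- !drop_missing & (pop_sd < 1e-12)
  keep <- !(drop_missing | drop_flat)
  reason <- ifelse(drop_missing, "missing", "zero_spread")
  log <- data.frame(descriptor = colnames(v)[!keep],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  if (!any(keep)) stopf("cleaning dropped all %d descriptors", ncol(v))
  v <- v[, keep, drop = FALSE]
  for (j in seq_len(ncol(v))) {
    nas <- is.na(v[, j])
    if (any(nas)) v[nas, j] <- median(v[!nas, j])
  }
  out <- descriptor_matrix(v, provenance = m$provenance)
  out$drop_log <- log
  out
}

#' Center and scale a descriptor matrix
#'
#' Centers each descriptor on its mean and divides by its population
#' standard deviation, storing the `(center, spread)` pairs so that the same
#' transform can be replayed on screening libraries with [apply_scaling()]
#' and inverted with [invert_scaling()].
#'
#' @param m A cleaned `descriptor_matrix` (see [clean_matrix()]).
#' @return A scaled `descriptor_matrix` with `scaling` metadata.
#' @export
scale_matrix <- function(m) {
  stopifnot(inherits(m, "descriptor_matrix"))
  v <- m$values
  if (anyNA(v)) stopf("scale_matrix requires a cleaned matrix (no missing values)")
  center <- colMeans(v)
  spread <- sqrt(colMeans(sweep(v, 2, center)^2))
  if (any(spread < 1e-12))
    stopf("zero-spread descriptor(s) present; run clean_matrix first: %s",
          paste(colnames(v)[spread < 1e-12], collapse = ", "))
  scaled <- sweep(sweep(v, 2, center), 2, spread, "/")
  out <- descriptor_matrix(scaled,
                           scaling = list(center = center, spread = spread),
                           provenance = m$provenance)
  out$drop_log <- m$drop_log
  out
}

#' Apply stored scaling to a raw descriptor matrix
#'
#' Transforms a raw matrix with training-set `(center, spread)` statistics,
#' e.g. to put a screening library on the training scale. Every descriptor
#' named in `scaling` must be present; extra columns are dropped.
#'
#' @param m A raw `descriptor_matrix`.
#' @param scaling Scaling metadata, e.g. `scale_matrix(train)$scaling`.
#' @return A scaled `descriptor_matrix` restricted to the scaled descriptors.
#' @export
apply_scaling <- function(m, scaling) {
  stopifnot(inherits(m, "descriptor_matrix"))
  want <- names(scaling$center)
  miss <- setdiff(want, colnames(m$values))
  if (length(miss)) stopf("matrix lacks descriptor(s) required by scaling: %s",
                          paste(miss, collapse = ", "))
  v <- m$values[, want, drop = FALSE]
  scaled <- sweep(sweep(v, 2, scaling$center), 2, scaling$spread, "/")
  descriptor_matrix(scaled, scaling = scaling, provenance = m$provenance)
}

#' Invert the scaling of a descriptor matrix
#'
#' @param m A scaled `descriptor_matrix` (with `scaling` metadata).
#' @return The raw-scale `descriptor_matrix` (scaling metadata removed).
#' @export
invert_scaling <- function(m) {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (is.null(m$scaling)) stopf("matrix carries no scaling metadata")
  v <- sweep(sweep(m$values, 2, m$scaling$spread, "*"), 2,
             m$scaling$center, "+")
  descriptor_matrix(v, provenance = m$provenance)
}

#' Read a descriptor matrix from delimited text
#'
#' Ingests a precomputed descriptor table (first column = molecule id,
#' remaining columns numeric descriptors). A scaling sidecar written by
#' [write_descriptor_matrix()] is picked up automatically when present.
#'
#' @param path Delimited text file (comma or tab; autodetected).
#' @param sep Field separator override.
#' @return A `descriptor_matrix` with `provenance = "ingested"` (scaling
#'   restored from the sidecar if found).
#' @export
read_descriptor_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   comment.char = "#", check.names = FALSE)
  ids <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  m <- descriptor_matrix(v, ids = ids, provenance = "ingested")
  sidecar <- paste0(path, ".scaling")
  if (file.exists(sidecar)) {
    sc <- read.table(sidecar, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, comment.char = "#")
    m$scaling <- list(center = setNames(sc$center, sc$descriptor),
                      spread = setNames(sc$spread, sc$descriptor))
    m$scaling$center <- m$scaling$center[colnames(m$values)]
    m$scaling$spread <- m$scaling$spread[colnames(m$values)]
  }
  m
}

#' Write a descriptor matrix to delimited text
#'
#' Writes the values with molecule id as first column; scaling metadata, if
#' any, goes to a `<path>.scaling` tab-separated sidecar.
#'
#' @param m A `descriptor_matrix`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(id = rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(m$scaling)) {
    sc <- data.frame(descriptor = names(m$scaling$center),
                     center = fmt_num(m$scaling$center),
                     spread = fmt_num(m$scaling$spread))
    write.table(sc, paste0(path, ".scaling"), sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}
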