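#' Hierarchically cluster odorants in a descriptor subspace
#'
#' Agglomerative clustering of molecules in the (scaled) selected descriptor
#' subspace, the view used to check that activators -- or prolonged
#' activators among activators -- group together. Defaults: average linkage
#' on Euclidean distances.
#'
#' @param m A scaled `descriptor_matrix` with at least 2 molecules.
#' @param subset A `descriptor_subset` (or character vector of descriptor
#'   names); must be non-empty.
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @param distance Distance measure passed to [stats::dist()]
#'   (default `"euclidean"`).
#' @return An object of class `odor_dendrogram`: list with the underlying
#'   `hclust` object (`merge` heights and order), `leaf_ids`, `linkage`,
#'   `distance`, `subset`.
#' @examples
#' sim <- gen_training_set(chem_sim_config(n_descriptors = 40, seed = 1))
#' m <- scale_matrix(clean_matrix(sim$matrix))
#' den <- cluster_odorants(m, sim$truth$informative)
#' table(cutree(den$hclust, k = 2))
#' @export
cluster_odorants <- function(m, subset, linkage = "average",
                             distance = "euclidean") {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (inherits(subset, "descriptor_subset")) subset <- subset$selected
  if (length(subset) == 0L) stopf("descriptor subset is empty")
  if (nrow(m$values) < 2L) stopf("need at least 2 molecules to cluster")
  miss <- setdiff(subset, colnames(m$values))
  if (length(miss)) stopf("unknown descriptor(s): %s",
                          paste(miss, collapse = ", "))
  X <- m$values[, subset, drop = FALSE]
  # deterministic tie handling: rows enter dist() in id order
  ord <- order(rownames(X))
  hc <- hclust(dist(X[ord, , drop = FALSE], method = distance),
               method = linkage)
  structure(list(hclust = hc, leaf_ids = hc$labels[hc$order],
                 linkage = linkage, distance = distance,
                 subset = subset),
            class = "odor_dendrogram")
}

#' @export
print.odor_dendrogram <- function(x, ...) {
  cat(sprintf("odor_dendrogram: %d leaves, %s linkage, %s distance, %d descriptor(s)\n",
              length(x$leaf_ids), x$linkage, x$distance, length(x$subset)))
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' Converts the dendrogram to a phylogeny-style tree (via
#' [ape::as.phylo()], which splits each merge height across the two child
#' branches) and writes Newick text.
#'
#' @param x An `odor_dendrogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(x, path) {
  stopifnot(inherits(x, "odor_dendrogram"))
  phy <- ape::as.phylo(x$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
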