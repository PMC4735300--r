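# Independent oracles and small fixture builders shared across tests.

# descriptor_matrix from a bare matrix (dimnames preserved when present)
make_dm <- function(values, ids = rownames(values),
                    descriptors = colnames(values), scaled = FALSE) {
  m <- descriptor_matrix(values, ids = ids, descriptors = descriptors,
                         provenance = "simulated")
  if (scaled) m <- scale_matrix(m)
  m
}

# brute-force AUC: all positive-negative pair enumeration, ties 1/2
auc_brute <- function(scores, pos) {
  p <- scores[pos]; n <- scores[!pos]
  cmp <- outer(p, n, ">") + 0.5 * outer(p, n, "==")
  sum(cmp) / (length(p) * length(n))
}

# brute-force leave-one-out nearest-positive distance AUC
nn_fitness_brute <- function(X, pos) {
  n <- nrow(X)
  d <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in which(pos)) {
      if (j == i) next
      best <- min(best, sqrt(sum((X[i, ] - X[j, ])^2)))
    }
    d[i] <- best
  }
  auc_brute(-d, pos)
}

# exhaustive per-step argmax with the package's documented candidate
# ordering (fitness, then separation margin on exact ties, then lowest
# column index), via public functions only
greedy_oracle <- function(m, labels, target_size, fitness, positive = "active") {
  selected <- character(0)
  for (step in seq_len(target_size)) {
    remaining <- setdiff(colnames(m$values), selected)
    fit <- vapply(remaining, function(d)
      subset_fitness(m, labels, c(selected, d), fitness = fitness,
                     positive = positive), numeric(1))
    best_fit <- max(fit)
    tied <- which(fit == best_fit)
    if (length(tied) > 1L) {
      marg <- vapply(remaining[tied], function(d)
        subset_separation(m, labels, c(selected, d), positive = positive),
        numeric(1))
      tied <- tied[which.max(marg)]
    }
    selected <- c(selected, remaining[tied[1]])
  }
  selected
}

# compound table written to a temp file
write_compound_fixture <- function(lines, sep = ",") {
  f <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  writeLines(lines, f)
  f
}
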