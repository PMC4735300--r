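#' ROC curve and AUC
#'
#' Computes the receiver-operating-characteristic step curve over score
#' thresholds and its area. The AUC equals the probability that a randomly
#' chosen positive outscores a randomly chosen negative, with ties counted
#' one half (the Mann-Whitney identity); it is therefore invariant under
#' any strictly monotone transform of the scores.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels: logical, or character with positive level
#'   `positive`. Both classes must be present.
#' @param positive Positive level when `labels` is character.
#' @return List with `auc` (scalar) and `roc`, a data.frame of
#'   (`threshold`, `fpr`, `tpr`) step-curve points starting at (Inf, 0, 0).
#' @examples
#' roc_auc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))$auc  # 1
#' roc_auc(c(1, 1), c(TRUE, FALSE))$auc                     # 0.5
#' @export
roc_auc <- function(scores, labels, positive = "active") {
  pos <- as_binary_labels(labels, positive)
  if (anyNA(pos) || anyNA(scores)) stopf("scores/labels contain NA")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stopf("both classes must be present (got %d positive, %d negative)",
          n_pos, n_neg)
  r <- rank(scores)  # average ranks: ties contribute 1/2 per pair
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  grp <- cumsum(!duplicated(s))  # tie groups share one threshold
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(grp != c(grp[-1], -1))  # last index of each tie group
  roc <- data.frame(threshold = c(Inf, s[last]),
                    fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  list(auc = auc, roc = roc)
}

# fold assignment randomized by the current RNG state; overall fold sizes
# differ by at most one. With `pos` given, folds are stratified: each class
# is shuffled and dealt round-robin in one continuous cycle (positives
# first), so per-class counts also differ by at most one per fold.
make_folds <- function(n, k, pos = NULL) {
  fold <- integer(n)
  ord <- if (is.null(pos)) sample.int(n)
         else {
           ip <- which(pos); iq <- which(!pos)
           c(ip[sample.int(length(ip))], iq[sample.int(length(iq))])
         }
  fold[ord] <- rep(seq_len(k), length.out = n)
  fold
}

#' Repeated k-fold cross-validation of the regression SVM
#'
#' Randomly partitions the training panel into `k` equal-sized folds (sizes
#' differing by at most one), trains the RBF regression SVM on `k - 1`
#' folds and scores the held-out fold, so every molecule receives exactly
#' one out-of-fold score per repeat. Each repeat reshuffles the folds with
#' a fresh seed derived from `seed`. By default the folds are stratified by
#' the binary label (per-class counts also balanced to within one): with
#' unstratified folds on a small panel, folds that happen to hold out more
#' actives were trained with fewer, which depresses held-out active scores
#' and biases the pooled AUC pessimistically. Predictive power is
#' summarized by
#' ranking the out-of-fold regression scores against binary activator
#' labels: one ROC/AUC per repeat, averaged into `mean_auc`, plus a pooled
#' ROC over all repeats for plotting. Common presets: `k = 4, repeats =
#' 100` and `k = 5, repeats = 20`.
#'
#' @inheritParams train_svm
#' @param labels Binary activator labels (logical or character with level
#'   `positive`).
#' @param k Number of folds (>= 2).
#' @param repeats Number of independent repetitions.
#' @param seed Integer seed; repeat `r` uses `seed + r - 1`.
#' @param stratify Stratify fold assignment by the binary label (default
#'   `TRUE`).
#' @param positive Positive level when `labels` is character.
#' @return An object of class `cv_result`: `k`, `repeats`, `seed`, `folds`
#'   (n x repeats integer matrix of fold ids), `scores` (n x repeats
#'   out-of-fold scores), `auc` (per repeat), `mean_auc`, `pooled_roc`.
#' @export
cross_validate <- function(m, subset, targets, labels, k = 5, repeats = 20,
                           seed = 1, cost = 1, gamma = NULL, epsilon = 0.1,
                           stratify = TRUE, positive = "active") {
  stopifnot(inherits(m, "descriptor_matrix"))
  if (inherits(subset, "descriptor_subset")) subset <- subset$selected
  n <- nrow(m$values)
  if (k < 2L) stopf("k must be >= 2")
  if (k > n) stopf("k (%d) exceeds number of molecules (%d)", k, n)
  pos <- as_binary_labels(labels, positive)
  if (sum(pos) == 0L || sum(!pos) == 0L)
    stopf("both classes must be present for ROC validation")
  ids <- rownames(m$values)
  folds <- matrix(NA_integer_, n, repeats, dimnames = list(ids, NULL))
  scores <- matrix(NA_real_, n, repeats, dimnames = list(ids, NULL))
  auc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r - 1L)
    fold <- make_folds(n, k, pos = if (stratify) pos)
    folds[, r] <- fold
    for (f in seq_len(k)) {
      test <- fold == f
      train_m <- descriptor_matrix(m$values[!test, , drop = FALSE],
                                   scaling = m$scaling,
                                   provenance = m$provenance)
      fit <- train_svm(train_m, subset, targets[!test], cost = cost,
                       gamma = gamma, epsilon = epsilon)
      test_m <- descriptor_matrix(m$values[test, , drop = FALSE],
                                  scaling = m$scaling,
                                  provenance = m$provenance)
      scores[test, r] <- predict(fit, test_m)
    }
    auc[r] <- roc_auc(scores[, r], pos)$auc
  }
  pooled <- roc_auc(as.vector(scores), rep(pos, times = repeats))
  structure(list(k = k, repeats = repeats, seed = seed, folds = folds,
                 scores = scores, auc = auc, mean_auc = mean(auc),
                 pooled_roc = pooled$roc),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold x %d repeats (seed %d)\n", x$k, x$repeats,
              x$seed))
  cat(sprintf("  mean AUC %.4f (per-repeat range %.4f-%.4f)\n", x$mean_auc,
              min(x$auc), max(x$auc)))
  invisible(x)
}

#' Write a cross-validation report
#'
#' Writes per-repeat AUCs plus a summary line as a delimited table, and the
#' pooled ROC step curve as two-column delimited text (`<path>.roc`).
#'
#' @param cv A `cv_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  df <- data.frame(repeat_id = seq_len(cv$repeats), auc = fmt_num(cv$auc))
  con <- file(path, "w")
  writeLines(sprintf("# cv_result k=%d repeats=%d seed=%d mean_auc=%s",
                     cv$k, cv$repeats, cv$seed, fmt_num(cv$mean_auc)), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  write.table(data.frame(fpr = cv$pooled_roc$fpr, tpr = cv$pooled_roc$tpr),
              paste0(path, ".roc"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
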