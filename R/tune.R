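#' Seeded grid search over SVM hyperparameters
#'
#' Optional helper (no tuning happens by default anywhere in the pipeline):
#' evaluates a small fixed grid of `(cost, gamma)` pairs by repeated k-fold
#' cross-validated mean AUC ([cross_validate()]) and returns the winning
#' pair. The grid defaults to `cost` in {0.1, 1, 10} and `gamma` in
#' {0.5, 1, 2} / `length(subset)`; ties resolve to the first grid point in
#' row order, so results are reproducible for a fixed seed.
#'
#' @inheritParams cross_validate
#' @param costs Candidate cost values.
#' @param gamma_scale Candidate multipliers of the default
#'   `1/length(subset)` kernel width.
#' @param k,repeats Cross-validation preset used for scoring (defaults 5
#'   and 5; keep small -- this is model selection, not validation).
#' @return List with `best` (`cost`, `gamma`, `mean_auc`) and `grid`, a
#'   data.frame of all evaluated combinations.
#' @export
tune_svm <- function(m, subset, targets, labels, costs = c(0.1, 1, 10),
                     gamma_scale = c(0.5, 1, 2), k = 5, repeats = 5,
                     seed = 1, epsilon = 0.1, positive = "active") {
  if (inherits(subset, "descriptor_subset")) subset <- subset$selected
  grid <- expand.grid(cost = costs,
                      gamma = gamma_scale / length(subset),
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_auc <- vapply(seq_len(nrow(grid)), function(i) {
    cross_validate(m, subset, targets, labels, k = k, repeats = repeats,
                   seed = seed, cost = grid$cost[i], gamma = grid$gamma[i],
                   epsilon = epsilon, positive = positive)$mean_auc
  }, numeric(1))
  best <- grid[which.max(grid$mean_auc), ]
  list(best = list(cost = best$cost, gamma = best$gamma,
                   mean_auc = best$mean_auc),
       grid = grid)
}
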