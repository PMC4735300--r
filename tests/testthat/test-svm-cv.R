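sim_panel <- function(seed = 5, n_desc = 40) {
  sim <- gen_training_set(chem_sim_config(n_descriptors = n_desc,
                                          seed = seed))
  list(sim = sim, m = scale_matrix(clean_matrix(sim$matrix)))
}

test_that("ROC AUC handles the canonical trivial cases", {
  expect_equal(roc_auc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(c(1, 1), c(TRUE, FALSE))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("ROC AUC equals the all-pairs enumeration oracle exactly", {
  set.seed(30)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    scores <- sample(round(rnorm(n), 1))  # rounding forces ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(roc_auc(scores, pos)$auc, auc_brute(scores, pos),
                 tolerance = 0)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(31)
  scores <- rnorm(40)
  pos <- rep(c(TRUE, FALSE), 20)
  a <- roc_auc(scores, pos)$auc
  expect_identical(roc_auc(3 * scores + 7, pos)$auc, a)
  expect_identical(roc_auc(exp(scores), pos)$auc, a)
  expect_identical(roc_auc(rank(scores), pos)$auc, a)
})

test_that("the ROC step curve runs from (0,0) to (1,1) monotonically", {
  set.seed(32)
  r <- roc_auc(rnorm(50), rep(c(TRUE, FALSE), 25))$roc
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[nrow(r)], r$tpr[nrow(r)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("the regression SVM fits a noiseless linear target within the band", {
  set.seed(33)
  X <- matrix(rnorm(90), 30, 3, dimnames = list(sprintf("m%02d", 1:30),
                                                c("a", "b", "c")))
  m <- make_dm(X, scaled = TRUE)
  y <- 2 * m$values[, "a"]
  fit <- train_svm(m, c("a", "b", "c"), y, cost = 100, epsilon = 0.1)
  expect_lt(max(abs(predict(fit, m) - y)), 0.1 + 0.05)
})

test_that("training is invariant to row order and consistent with fitted values", {
  p <- sim_panel(seed = 5)
  sub <- p$sim$truth$informative
  y <- p$sim$compounds$activity
  fit <- train_svm(p$m, sub, y)
  expect_equal(unname(predict(fit, p$m)), unname(fit$fitted),
               tolerance = 1e-9)
  set.seed(34)
  perm <- sample(seq_len(nrow(p$m$values)))
  m_perm <- descriptor_matrix(p$m$values[perm, ], scaling = p$m$scaling,
                              provenance = "simulated")
  fit2 <- train_svm(m_perm, sub, y[perm])
  expect_lt(max(abs(predict(fit2, p$m) - predict(fit, p$m))), 1e-9)
})

test_that("models survive a text serialization round trip bitwise", {
  p <- sim_panel(seed = 5)
  fit <- train_svm(p$m, p$sim$truth$informative, p$sim$compounds$activity)
  f <- tempfile(fileext = ".txt")
  save_model(fit, f)
  back <- load_model(f)
  expect_identical(back$fingerprint, fit$fingerprint)
  expect_lt(max(abs(predict(back, p$m) - predict(fit, p$m))), 1e-12)
  # raw (unscaled) matrices are scored through the stored training scaling
  raw <- descriptor_matrix(p$sim$matrix$values, provenance = "simulated")
  expect_lt(max(abs(predict(back, raw) - predict(fit, p$m))), 1e-9)
})

test_that("scoring refuses matrices lacking a selected descriptor", {
  p <- sim_panel(seed = 5)
  fit <- train_svm(p$m, p$sim$truth$informative, p$sim$compounds$activity)
  drop1 <- p$sim$truth$informative[1]
  m_missing <- descriptor_matrix(
    p$m$values[, setdiff(colnames(p$m$values), drop1)],
    provenance = "simulated")
  expect_error(predict(fit, m_missing), drop1)
})

test_that("duplicated input rows receive duplicated scores", {
  p <- sim_panel(seed = 5)
  fit <- train_svm(p$m, p$sim$truth$informative, p$sim$compounds$activity)
  v <- p$m$values[c(1, 1), ]
  rownames(v) <- c("r1", "r2")
  s <- predict(fit, descriptor_matrix(v, scaling = p$m$scaling,
                                      provenance = "simulated"))
  expect_identical(unname(s[1]), unname(s[2]))
})

test_that("n=20 with 5 folds gives four molecules per fold, always balanced", {
  sim <- gen_training_set(chem_sim_config(n_molecules = 20,
                                          n_descriptors = 15,
                                          n_prolonged = 2, seed = 14))
  m <- scale_matrix(clean_matrix(sim$matrix))
  cv <- cross_validate(m, sim$truth$informative, sim$compounds$activity,
                       sim$compounds$active_label, k = 5, repeats = 6,
                       seed = 2)
  for (r in seq_len(cv$repeats))
    expect_true(all(table(cv$folds[, r]) == 4))
  # fold balance on a non-divisible n
  sim2 <- gen_training_set(chem_sim_config(n_molecules = 23,
                                           n_descriptors = 15,
                                           n_prolonged = 2, seed = 15))
  m2 <- scale_matrix(clean_matrix(sim2$matrix))
  cv2 <- cross_validate(m2, sim2$truth$informative, sim2$compounds$activity,
                        sim2$compounds$active_label, k = 4, repeats = 5,
                        seed = 2)
  for (r in seq_len(cv2$repeats)) {
    sz <- table(cv2$folds[, r])
    expect_lte(max(sz) - min(sz), 1)
  }
})

test_that("cross-validation is bitwise deterministic for a fixed seed", {
  p <- sim_panel(seed = 5)
  a <- cross_validate(p$m, p$sim$truth$informative, p$sim$compounds$activity,
                      p$sim$compounds$active_label, k = 4, repeats = 5,
                      seed = 11)
  b <- cross_validate(p$m, p$sim$truth$informative, p$sim$compounds$activity,
                      p$sim$compounds$active_label, k = 4, repeats = 5,
                      seed = 11)
  expect_identical(a$scores, b$scores)
  expect_identical(a$auc, b$auc)
  expect_identical(a$folds, b$folds)
})

test_that("cv reports round-trip their per-repeat AUCs", {
  p <- sim_panel(seed = 5)
  cv <- cross_validate(p$m, p$sim$truth$informative,
                       p$sim$compounds$activity,
                       p$sim$compounds$active_label, k = 4, repeats = 3,
                       seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_cv_report(cv, f)
  tab <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(tab$auc, cv$auc, tolerance = 1e-15)
  expect_true(file.exists(paste0(f, ".roc")))
})

test_that("holdout actives outscore holdout inactives", {
  p <- sim_panel(seed = 5)
  train_idx <- seq_len(30)
  m_train <- descriptor_matrix(p$m$values[train_idx, ],
                               scaling = p$m$scaling,
                               provenance = "simulated")
  m_hold <- descriptor_matrix(p$m$values[-train_idx, ],
                              scaling = p$m$scaling,
                              provenance = "simulated")
  fit <- train_svm(m_train, p$sim$truth$informative,
                   p$sim$compounds$activity[train_idx])
  s <- predict(fit, m_hold)
  act <- p$sim$compounds$active_label[-train_idx] == "active"
  expect_gt(mean(s[act]), mean(s[!act]))
})

test_that("the optional grid search scores every pair and is reproducible", {
  p <- sim_panel(seed = 5)
  tn <- tune_svm(p$m, p$sim$truth$informative, p$sim$compounds$activity,
                 p$sim$compounds$active_label, k = 4, repeats = 2, seed = 6)
  expect_equal(nrow(tn$grid), 9)
  expect_equal(tn$best$mean_auc, max(tn$grid$mean_auc))
  tn2 <- tune_svm(p$m, p$sim$truth$informative, p$sim$compounds$activity,
                  p$sim$compounds$active_label, k = 4, repeats = 2, seed = 6)
  expect_identical(tn$grid$mean_auc, tn2$grid$mean_auc)
})
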