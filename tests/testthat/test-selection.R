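test_that("nearest-positive AUC fitness is exact on hand-built instances", {
  # perfectly separated classes -> 1
  m <- make_dm(cbind(x = c(0, 0, 10, 10, 10)))
  lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(subset_fitness(m, lab, "x", fitness = "nn_pos_auc"), 1.0)
  # 6-molecule, 2-descriptor instance vs brute-force pair enumeration
  set.seed(7)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], c("d1", "d2")))
  pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  got <- subset_fitness(make_dm(X), pos, c("d1", "d2"),
                        fitness = "nn_pos_auc")
  expect_equal(got, nn_fitness_brute(X, pos), tolerance = 0)
})

test_that("fitness requires two molecules per class and known descriptors", {
  m <- make_dm(matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b"))))
  expect_error(subset_fitness(m, c(TRUE, FALSE, FALSE, FALSE, FALSE), "a"),
               "2")
  expect_error(subset_fitness(m, rep(c(TRUE, FALSE), c(2, 3)), "zz"), "zz")
  expect_error(subset_fitness(m, rep(c(TRUE, FALSE), c(2, 3)),
                              character(0)), "empty")
})

test_that("permuted labels give null fitness near one half", {
  sim <- gen_training_set(chem_sim_config(seed = 12))
  m <- scale_matrix(clean_matrix(sim$matrix))
  lab <- sim$compounds$active_label == "active"
  vals <- vapply(0:199, function(s) {
    set.seed(s)
    subset_fitness(m, sample(lab), sim$truth$informative,
                   fitness = "nn_pos_auc")
  }, numeric(1))
  expect_gt(mean(vals), 0.45)
  expect_lt(mean(vals), 0.55)
})

test_that("greedy steps match the exhaustive per-step argmax", {
  for (s in 1:5) {
    sim <- gen_training_set(chem_sim_config(n_molecules = 30,
                                            n_descriptors = 15,
                                            active_fraction = 0.3,
                                            n_prolonged = 2, seed = s))
    m <- scale_matrix(clean_matrix(sim$matrix))
    lab <- sim$compounds$active_label
    got <- sfs_select(m, lab, target_size = 4)
    expect_equal(got$selected,
                 greedy_oracle(m, lab, 4, fitness = "moderated_fisher"))
  }
})

test_that("SFS recovers a planted informative subspace", {
  sim <- gen_training_set(chem_sim_config(n_descriptors = 50, seed = 1))
  m <- scale_matrix(clean_matrix(sim$matrix))
  sub <- sfs_select(m, sim$compounds$active_label, target_size = 3)
  expect_setequal(sub$selected, sim$truth$informative)
})

test_that("target_size 13 yields exactly 13 descriptors", {
  sim <- gen_training_set(chem_sim_config(n_molecules = 30,
                                          n_descriptors = 20,
                                          n_prolonged = 2, seed = 4))
  m <- scale_matrix(clean_matrix(sim$matrix))
  sub <- sfs_select(m, sim$compounds$active_label, target_size = 13)
  expect_length(sub$selected, 13)
  expect_length(sub$fitness_trajectory, 13)
  expect_false(anyDuplicated(sub$selected) > 0)
})

test_that("plateau stopping yields a strictly improving trajectory", {
  sim <- gen_training_set(chem_sim_config(n_descriptors = 60, seed = 5))
  m <- scale_matrix(clean_matrix(sim$matrix))
  sub <- sfs_select(m, sim$compounds$active_label, target_size = 20,
                    stop_rule = "plateau", plateau_tol = 1e-3)
  expect_true(all(diff(sub$fitness_trajectory) >= 0))
  expect_lt(length(sub$selected), 20)
})

test_that("exact ties break towards the lowest column index", {
  # duplicated informative column: both give identical fitness and margin
  set.seed(9)
  base <- c(rnorm(4, 3), rnorm(8, 0))
  X <- cbind(n1 = rnorm(12), dupA = base, dupB = base)
  m <- make_dm(X, scaled = TRUE)
  lab <- rep(c(TRUE, FALSE), c(4, 8))
  sub <- sfs_select(m, lab, target_size = 1, positive = TRUE)
  expect_equal(sub$selected, "dupA")
})

test_that("subsets serialize to structured text and back", {
  sub <- structure(list(selected = c("D1", "D2"),
                        fitness_trajectory = c(0.7, 0.95),
                        fitness_name = "moderated_fisher",
                        target_size = 2L, stop_rule = "fixed_size"),
                   class = "descriptor_subset")
  f <- tempfile()
  write_subset(sub, f)
  back <- read_subset(f)
  expect_equal(back$selected, sub$selected)
  expect_equal(back$fitness_trajectory, sub$fitness_trajectory,
               tolerance = 1e-15)
  expect_equal(back$target_size, 2L)
})

test_that("kinetics selection recovers the planted prolonged subspace", {
  sim <- gen_training_set(chem_sim_config(seed = 2))
  m <- scale_matrix(clean_matrix(sim$matrix))
  sub <- kinetics_subset(m, sim$compounds$kinetics_label, target_size = 2)
  expect_setequal(sub$selected, sim$truth$kinetics)
  # selected subspace beats the full matrix on the same labels
  act <- sim$compounds$kinetics_label %in% c("prolonged", "transient")
  m_act <- descriptor_matrix(m$values[act, ], provenance = "simulated")
  lab <- sim$compounds$kinetics_label[act]
  expect_gte(subset_fitness(m_act, lab, sub$selected, positive = "prolonged"),
             subset_fitness(m_act, lab, colnames(m$values),
                            positive = "prolonged"))
})

test_that("kinetics selection demands both kinetics classes", {
  sim <- gen_training_set(chem_sim_config(seed = 2))
  m <- scale_matrix(clean_matrix(sim$matrix))
  all_prolonged <- ifelse(sim$compounds$active_label == "active",
                          "prolonged", "unknown")
  expect_error(kinetics_subset(m, all_prolonged), "transient")
  expect_error(kinetics_subset(m, rep("transient", 47)), "prolonged")
})

test_that("average-linkage dendrograms match hand agglomeration", {
  # colinear points 0, 1, 10, 11: merges at 1, 1, then mean(10,11,9,10)=10
  m <- make_dm(cbind(x = c(0, 1, 10, 11)),
               ids = c("a", "b", "c", "d"))
  den <- cluster_odorants(m, "x")
  expect_equal(sort(den$hclust$height), c(1, 1, 10))
  # identical rows merge at height zero
  m2 <- make_dm(cbind(x = c(5, 5, 9), y = c(2, 2, 0)))
  expect_equal(min(cluster_odorants(m2, c("x", "y"))$hclust$height), 0)
})

test_that("activators isolate in a two-cluster cut of the selected subspace", {
  sim <- gen_training_set(chem_sim_config(seed = 1))
  m <- scale_matrix(clean_matrix(sim$matrix))
  den <- cluster_odorants(m, sim$truth$informative)
  cut <- cutree(den$hclust, k = 2)
  frac <- max(table(cut[sim$truth$active_ids])) /
    length(sim$truth$active_ids)
  expect_gte(frac, 0.9)
})

test_that("dendrograms export as readable Newick with n leaves", {
  sim <- gen_training_set(chem_sim_config(n_molecules = 12,
                                          n_descriptors = 10,
                                          n_prolonged = 2, seed = 6))
  m <- scale_matrix(clean_matrix(sim$matrix))
  den <- cluster_odorants(m, colnames(m$values)[1:3])
  f <- tempfile(fileext = ".nwk")
  write_dendrogram(den, f)
  phy <- ape::read.tree(f)
  expect_equal(sort(phy$tip.label), sort(sim$compounds$id))
})
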