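# hand-built 10-compound filter panel with known composition
filter_panel <- function() {
  data.frame(
    id = c("ea", "clb", "c20", "c24", "bad", "salt", "pyr", "dmso", "tfm",
           "etoh"),
    smiles = c("CCOC(C)=O",                   # ethyl acetate, MW 88.11
               "Clc1ccccc1",                  # chlorobenzene: Cl
               strrep("C", 20),               # C20H42, MW 282.55
               strrep("C", 24),               # C24H50, MW 338.65
               "not_a_smiles",                # unparseable
               "[Na+].[Cl-]",                 # multifragment
               "c1ccncc1",                    # pyridine: C,H,N
               "CS(C)=O",                     # DMSO: C,H,O,S
               "FC(F)F",                      # fluoroform: F
               "CCO"),                        # ethanol
    stringsAsFactors = FALSE)
}

test_that("library filters match manual enumeration on the hand panel", {
  flt <- filter_library(filter_panel())
  expect_equal(flt$pass,
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                 TRUE))
  expect_equal(flt$reason[flt$id == "clb"], "element:Cl")
  expect_match(flt$reason[flt$id == "c24"], "^mw:")
  expect_equal(flt$reason[flt$id == "bad"], "parse")
  expect_equal(flt$reason[flt$id == "salt"], "multifragment")
  expect_equal(flt$reason[flt$id == "tfm"], "element:F")
  expect_true(all(flt$reason[flt$pass] == ""))
  # average-mass molecular weights with implicit hydrogens
  expect_equal(flt$mw[flt$id == "ea"], 88.11, tolerance = 0.01)
  expect_equal(flt$mw[flt$id == "c20"], 282.55, tolerance = 0.01)
  expect_equal(flt$mw[flt$id == "c24"], 338.65, tolerance = 0.01)
  expect_true(is.na(flt$mw[flt$id == "bad"]))
})

test_that("filter decisions are order-invariant", {
  panel <- filter_panel()
  a <- filter_library(panel)
  perm <- c(4, 9, 1, 10, 2, 7, 5, 3, 8, 6)
  b <- filter_library(panel[perm, ])
  expect_equal(b[order(b$id), ], a[order(a$id), ], ignore_attr = TRUE)
})

screen_fixture <- function(n_library = 60, n_planted = 10,
                           fail_fraction = 0, lib_seed = 5) {
  cfg <- chem_sim_config(n_descriptors = 40, seed = 5)
  sim <- gen_training_set(cfg)
  m <- scale_matrix(clean_matrix(sim$matrix))
  fit <- train_svm(m, sim$truth$informative, sim$compounds$activity)
  lib <- gen_library(cfg, n_library = n_library,
                     n_planted_active = n_planted,
                     fail_fraction = fail_fraction, seed = lib_seed)
  list(model = fit, lib = lib, sim = sim, m = m)
}

test_that("screening ranks pass 1..n_passed with non-increasing scores", {
  fx <- screen_fixture(n_library = 10, n_planted = 3, fail_fraction = 0.4)
  res <- screen_library(fx$model, fx$lib$compounds,
                        descriptors = fx$lib$matrix)
  expect_equal(res$n_library, 10L)
  expect_equal(res$n_passed, 6L)
  ranked <- res$table[res$table$pass, ]
  expect_equal(ranked$rank, 1:6)
  expect_true(all(diff(ranked$score) <= 0))
  expect_true(all(nzchar(res$table$reason[!res$table$pass])))
})

test_that("chunk size does not change screening output", {
  fx <- screen_fixture(n_library = 40, n_planted = 8, fail_fraction = 0.2)
  a <- screen_library(fx$model, fx$lib$compounds,
                      descriptors = fx$lib$matrix, chunk_size = 1)
  b <- screen_library(fx$model, fx$lib$compounds,
                      descriptors = fx$lib$matrix, chunk_size = 10000)
  expect_equal(a$table, b$table, tolerance = 1e-12)
  expect_identical(a$n_passed, b$n_passed)
})

test_that("shuffling the library changes neither pass set nor ranking", {
  fx <- screen_fixture(n_library = 40, n_planted = 8, fail_fraction = 0.2)
  a <- screen_library(fx$model, fx$lib$compounds,
                      descriptors = fx$lib$matrix)
  set.seed(40)
  perm <- sample(nrow(fx$lib$compounds))
  b <- screen_library(fx$model, fx$lib$compounds[perm, ],
                      descriptors = fx$lib$matrix)
  ranked_a <- a$table[a$table$pass, ]
  ranked_b <- b$table[b$table$pass, ]
  expect_equal(ranked_a, ranked_b, ignore_attr = TRUE, tolerance = 1e-12)
  expect_setequal(a$table$id[!a$table$pass], b$table$id[!b$table$pass])
})

test_that("training actives rank above training inactives when screened", {
  cfg <- chem_sim_config(n_descriptors = 40, seed = 5)
  sim <- gen_training_set(cfg)
  m <- scale_matrix(clean_matrix(sim$matrix))
  fit <- train_svm(m, sim$truth$informative, sim$compounds$activity)
  res <- screen_library(fit, sim$compounds, descriptors = sim$matrix)
  ranked <- res$table[res$table$pass, ]
  act <- ranked$id %in% sim$truth$active_ids
  expect_lt(mean(ranked$rank[act]), mean(ranked$rank[!act]))
})

test_that("an empty library yields an empty result, not an error", {
  fx <- screen_fixture(n_library = 5, n_planted = 2)
  res <- screen_library(fx$model,
                        fx$lib$compounds[0, ],
                        descriptors = fx$lib$matrix)
  expect_equal(res$n_library, 0L)
  expect_equal(nrow(res$table), 0L)
})

test_that("screen results write ranked and rejected files", {
  fx <- screen_fixture(n_library = 10, n_planted = 3, fail_fraction = 0.4)
  res <- screen_library(fx$model, fx$lib$compounds,
                        descriptors = fx$lib$matrix)
  f <- tempfile(fileext = ".tsv")
  write_screen_result(res, f)
  ranked <- read.table(f, header = TRUE, sep = "\t")
  rejected <- read.table(paste0(f, ".rejected"), header = TRUE, sep = "\t")
  expect_equal(nrow(ranked), res$n_passed)
  expect_equal(nrow(rejected), res$n_library - res$n_passed)
})
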