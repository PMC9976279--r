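# Counterfactual mutation, selection, pairing and fragment effects.

test_that("zero mutations yield no candidates", {
  lib <- generate_library(synthetic_spec(5, seed = 6))
  res <- mutate_molecule(library_genotype(lib, 1), max_mutations = 0)
  expect_equal(nrow(res$records), 0)
})

test_that("mutation is deterministic and never duplicates the original", {
  lib <- generate_library(synthetic_spec(5, seed = 6))
  g <- library_genotype(lib, 2)
  a <- mutate_molecule(g, n_candidates = 10, seed = 9)
  b <- mutate_molecule(g, n_candidates = 10, seed = 9)
  expect_identical(a$records, b$records)
  orig <- ob_canonical(lib$records$smiles[2])
  expect_false(orig %in% a$records$smiles)
  expect_false(any(duplicated(a$records$smiles)))
})

test_that("every candidate decodes to a valid, standardizable molecule", {
  lib <- generate_library(synthetic_spec(8, seed = 19))
  for (i in seq_len(4)) {
    cand <- mutate_molecule(library_genotype(lib, i), n_candidates = 8,
                            seed = 100 + i)
    if (nrow(cand$records) == 0) next
    std <- standardize_set(cand$records)
    expect_equal(nrow(std$rejections), 0)
    fl <- apply_filters(std$records)
    expect_equal(fl$report$retained, nrow(cand$records))
  }
})

test_that("selection keeps shifts of at least delta, inclusively, one per cluster", {
  # a transparent model: the first feature column IS the prediction
  vals <- c(orig = 0, c1 = 1.0, c2 = 0.4, c3 = -1.5, c4 = 1.6)
  model <- function(X) X[, "v"]
  # c1/c4 are near-identical structures (equivalent SMILES below), c3 distinct
  cands <- data.frame(id = c("c1", "c2", "c3", "c4"),
                      smiles = c("CCO", "c1ccccc1", "CCCCCCCC", "OCC"))
  # map candidate smiles to the value lookup by id instead
  featurize_id <- function(sm) {
    key <- c("CCO" = "c1", "c1ccccc1" = "c2", "CCCCCCCC" = "c3",
             "OCC" = "c4", "C" = "orig")
    matrix(vals[key[sm]], ncol = 1, dimnames = list(NULL, "v"))
  }
  sel <- select_counterfactuals(model, "C", cands, featurize_id,
                                delta = 1.0, cluster_threshold = 0.7)
  # c2 excluded (|0.4| < 1); c1 (exactly 1.0) included were it not clustered
  # with c4 (same molecule, tanimoto 1): the larger |shift| wins
  expect_setequal(sel$id, c("c3", "c4"))
  expect_equal(sel$delta_pred[sel$id == "c4"], 1.6)
  # with distinct clusters, the exact-delta candidate is kept (inclusive)
  sel2 <- select_counterfactuals(model, "C",
                                 cands[cands$id %in% c("c1", "c3"), ],
                                 featurize_id, delta = 1.0)
  expect_setequal(sel2$id, c("c1", "c3"))
})

test_that("pairs require exactly one differing fragment descriptor", {
  # toluene -> ethylbenzene: no fragment descriptor changes (fr_methyl stays 1)
  # toluene -> benzyl chloride-like mutant: fr_halogen changes only
  sel <- data.frame(id = c("noop", "halo"),
                    smiles = c("CCc1ccccc1", "Cc1ccccc1Cl"),
                    pred = c(0, 0), delta_pred = c(-1.2, -1.1))
  pr <- fragment_pairs("Cc1ccccc1", sel)
  expect_equal(pr$id, "halo")
  expect_equal(pr$descriptor, "fr_halogen")
  expect_equal(pr$direction, 1)
})

test_that("fragment effects reproduce the three-pair hand example", {
  pairs <- data.frame(descriptor = "fr_primary_amine",
                      direction = c(1, 1, 1),
                      delta_pred = c(1.2, 1.1, -1.0))
  eff <- fragment_effects(pairs)
  expect_equal(eff$n_pairs, 3L)
  expect_equal(eff$f_increase, 2 / 3)
  expect_equal(eff$f_decrease, 1 / 3)
  expect_equal(eff$effect, 1 / 3, tolerance = 1e-12)
  # all-increase boundary
  eff2 <- fragment_effects(data.frame(descriptor = "fr_methyl",
                                      direction = c(-1, -1),
                                      delta_pred = c(-1.5, -2)))
  expect_equal(eff2$effect, 1)  # removing methyl raised... adding raises
})

test_that("negating all shifts negates every effect", {
  pairs <- withr::with_seed(21, data.frame(
    descriptor = sample(c("fr_methyl", "fr_halogen", "fr_hydroxyl"), 30,
                        replace = TRUE),
    direction = sample(c(-1, 1), 30, replace = TRUE),
    delta_pred = rnorm(30)))
  e1 <- fragment_effects(pairs)
  pairs2 <- pairs; pairs2$delta_pred <- -pairs2$delta_pred
  e2 <- fragment_effects(pairs2)
  m <- merge(e1, e2, by = "descriptor")
  expect_equal(m$effect.x, -m$effect.y)
  expect_true(all(abs(e1$effect) <= 1))
  expect_true(all(e1$f_increase + e1$f_decrease <= 1))
  expect_equal(sum(e1$n_pairs), 30)
})

test_that("on the synthetic truth model, H-bond donors raise predicted solubility", {
  fx <- fixture_noiseless()
  model <- fit_model(model_spec("rf", list(n_trees = 300), seed = 8L),
                     fx$X, fx$y)
  featurize <- function(sm) compute_descriptors(sm, panel = "counts")
  res <- counterfactual_attribution(fx$lib, model, featurize,
                                    parents = 1:12, n_candidates = 12,
                                    delta = 0.8, seed = 33)
  expect_gt(nrow(res$pairs), 0)
  amine <- res$effects[res$effects$descriptor == "fr_primary_amine", ]
  methyl <- res$effects[res$effects$descriptor == "fr_methyl", ]
  if (nrow(amine)) expect_gt(amine$effect, 0)
  if (nrow(methyl)) expect_lt(methyl$effect, 0)
  expect_gt(max(nrow(amine), nrow(methyl)), 0)
})
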