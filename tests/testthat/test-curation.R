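# Curation: standardization, salt stripping, deduplication, filters.

test_that("salt stripping removes the lowest-MW counterion and neutralizes", {
  rec <- standardize("CC(=O)[O-].[Na+]")
  expect_s3_class(rec, "data.frame")
  expect_equal(rec$smiles, ob_canonical("CC(=O)O"))
  expect_true(rec$salt_stripped)
  expect_false(rec$charged)
})

test_that("a plain single-component molecule passes through unchanged", {
  rec <- standardize("CCO")
  expect_equal(rec$smiles, ob_canonical("CCO"))
  expect_false(rec$salt_stripped)
  expect_match(rec$inchi, "^InChI=1S/C2H6O")
})

test_that("multi-component strings without recognized counterions reject", {
  rej <- standardize("C1CC1.C1CC1")
  expect_s3_class(rej, "curation_rejection")
  expect_equal(rej$reason, "multicomponent")
})

test_that("unparseable SMILES reject with the right reason", {
  rej <- standardize("not_a_smiles")
  expect_s3_class(rej, "curation_rejection")
  expect_equal(rej$reason, "unparseable")
  # batch path attributes failures to the right rows
  res <- standardize_set(data.frame(
    id = c("a", "b", "c"), smiles = c("CCO", "C1CC", "c1ccccc1"),
    logS = c(-1, -2, -3)))
  expect_equal(res$rejections$id, "b")
  expect_equal(res$records$id, c("a", "c"))
})

test_that("a double salt with two identical counterions is stripped", {
  rec <- standardize("[Ca+2].[Cl-].[Cl-]")
  # the parent here is Ca itself; more relevantly, an organic double salt:
  rec2 <- standardize("C(C(=O)[O-])C(=O)[O-].[Na+].[Na+]")
  expect_s3_class(rec2, "data.frame")
  expect_equal(rec2$smiles, ob_canonical("C(C(=O)O)C(=O)O"))
})

test_that("single-component zwitterions are kept, not neutralized, flagged", {
  rec <- standardize("[NH3+]CC(=O)[O-]")
  expect_s3_class(rec, "data.frame")
  expect_true(rec$charged)
  expect_equal(rec$smiles, ob_canonical("[NH3+]CC(=O)[O-]"))
})

test_that("standardization is a fixpoint", {
  for (sm in c("OCC", "CC(=O)[O-].[Na+]", "c1ccccc1C(=O)N")) {
    once <- standardize(sm)
    twice <- standardize(once$smiles)
    expect_equal(twice$smiles, once$smiles)
    expect_equal(twice$inchi, once$inchi)
  }
})

test_that("deduplication is by InChI, keeping the first occurrence", {
  res <- standardize_set(data.frame(
    id = c("a", "b", "c"),
    smiles = c("CCO", "OCC", "CCC(=O)O"),  # a and b are the same molecule
    logS = c(-2.0, -2.3, -1.0)))
  dd <- deduplicate(res$records)
  expect_equal(dd$removed_count, 1)
  expect_equal(dd$records$id, c("a", "c"))
  expect_equal(dd$records$logS[1], -2.0)  # first kept
  # all-unique input is a no-op
  dd2 <- deduplicate(dd$records)
  expect_equal(dd2$removed_count, 0)
  expect_identical(dd2$records, dd$records)
})

test_that("size/flexibility filters use strict printed bounds", {
  c30 <- paste(rep("C", 30), collapse = "")  # 27 rotatable bonds
  res <- standardize_set(data.frame(
    id = c("propane", "butane", "c30"),
    smiles = c("CCC", "CCCC", c30), logS = NA_real_))
  fl <- apply_filters(res$records)
  expect_equal(fl$report$rejected_small, 1)     # 3 heavy atoms < 4
  expect_equal(fl$report$rejected_flexible, 1)  # 27 rotatable bonds > 20
  expect_equal(fl$records$id, "butane")         # 4 heavy atoms retained
  # a linear n-carbon chain has n - 3 rotatable bonds
  g <- mol_graphs(c30)[[1]]
  expect_equal(rotatable_bonds(g), 27)
})

test_that("apply_filters is idempotent", {
  lib <- fixture_tight(60, seed = 301)
  std <- standardize_set(lib$lib$records)
  f1 <- apply_filters(std$records)
  f2 <- apply_filters(f1$records)
  expect_identical(f2$records, f1$records)
  expect_equal(f2$report$retained, f1$report$retained)
})

test_that("the curation report conserves record counts", {
  input <- data.frame(
    id = paste0("m", 1:7),
    smiles = c("CCO", "OCC", "bad(", "C1CC1.C1CC1", "CC(=O)[O-].[Na+]",
               "CCC", "c1ccccc1"),
    logS = NA_real_)
  res <- curate(input)
  rep <- res$report
  expect_equal(rep$input, 7)
  expect_equal(rep$rejected_unparseable, 1)
  expect_equal(rep$rejected_multicomponent, 1)
  expect_equal(rep$deduplicated, 1)
  # ethanol (3 heavy atoms, surviving deduplication) and propane
  expect_equal(rep$rejected_small, 2)
  expect_equal(rep$retained, 2)
  expect_equal(rep$input,
               rep$retained + rep$rejected_unparseable +
                 rep$rejected_multicomponent + rep$deduplicated +
                 rep$rejected_small + rep$rejected_large +
                 rep$rejected_flexible)
  expect_equal(rep$salt_stripped, 1)
  # and it serializes to JSON
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(js$retained, rep$retained)
})
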