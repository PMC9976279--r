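# Tanimoto distributions, Murcko scaffolds, similarity graph.

test_that("tanimoto matches hand-computed bit-set examples", {
  expect_equal(tanimoto(make_fp(c(1, 2, 3)), make_fp(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(make_fp(1:5), make_fp(1:5)), 1)
  expect_equal(tanimoto(make_fp(1:3), make_fp(10:12)), 0)
  expect_equal(tanimoto(make_fp(integer(0)), make_fp(integer(0))), 0)
  expect_error(tanimoto(make_fp(1, nbits = 1024), make_fp(1)),
               "length mismatch")
  # symmetry
  a <- make_fp(c(5, 9, 100)); b <- make_fp(c(9, 100, 101, 7))
  expect_equal(tanimoto(a, b), tanimoto(b, a))
})

test_that("the vectorized similarity matrix equals the brute-force double loop", {
  fps <- morgan_fp(unname(fixture_smiles10))
  m <- tanimoto_matrix(fps)
  brute <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) brute[i, j] <- tanimoto(fps[[i]], fps[[j]])
  expect_equal(m, brute, tolerance = 1e-12)
  expect_equal(diag(m), rep(1, 10))
})

test_that("set-to-set distributions have the right pair counts", {
  a <- unname(fixture_smiles10[1:3])
  b <- unname(fixture_smiles10[4:7])
  d <- set_to_set_distribution(a, b)
  expect_equal(d$summary$n, 12)
  expect_true(all(d$scores >= 0 & d$scores <= 1))
  expect_equal(sum(d$histogram$count), 12)
  expect_equal(d$histogram$lower, seq(0, 0.95, by = 0.05))
  # within-set
  dw <- set_to_set_distribution(a)
  expect_equal(dw$summary$n, 3)
  # one molecule against itself scores 1
  d1 <- set_to_set_distribution("CCO", "CCO")
  expect_equal(d1$scores, 1)
})

test_that("Murcko scaffolds strip side chains and bucket acyclics", {
  sc <- murcko_scaffold(c("Cc1ccccc1", "CCc1ccccc1", "c1ccccc1", "CCCCCC",
                          "O=C1CCCCC1", "c1ccccc1CC(=O)C"))
  expect_equal(sc[1], sc[2])          # toluene == ethylbenzene scaffold
  expect_equal(sc[1], sc[3])          # ... which is benzene
  expect_equal(sc[4], "")             # hexane is acyclic
  expect_equal(sc[5], murcko_scaffold("O=C1CCCCC1"))  # exocyclic =O kept
  expect_equal(sc[6], sc[3])          # full side chain removed
})

test_that("scaffold summaries count uniques and overlaps like a set oracle", {
  sets <- list(
    train = c("Cc1ccccc1", "CCc1ccccc1", "C1CCCCC1", "CCCC"),
    test = c("Oc1ccccc1", "CC1CCCCC1", "c1ccncc1")
  )
  ms <- murcko_summary(sets)
  expect_equal(unname(ms$unique_counts), c(2L, 3L))
  expect_equal(unname(ms$acyclic_counts), c(1L, 0L))
  # oracle: brute-force intersection of the scaffold string sets
  s_train <- unique(setdiff(murcko_scaffold(sets$train), ""))
  s_test <- unique(setdiff(murcko_scaffold(sets$test), ""))
  expect_equal(ms$overlap["train", "test"], length(intersect(s_train, s_test)))
  expect_equal(ms$overlap["train", "test"], 2L)  # benzene and cyclohexane
  expect_lte(ms$overlap["train", "test"], min(ms$unique_counts))
})

test_that("similarity graph edges respect the inclusive threshold", {
  sm <- unname(fixture_smiles10)
  fps <- morgan_fp(sm)
  m <- tanimoto_matrix(fps)
  off <- m[upper.tri(m)]
  thr <- max(off[off < 1])  # an attained similarity value
  g <- build_similarity_graph(list(all = sm), threshold = thr)
  # the pair attaining the threshold is connected (inclusive edge rule)
  expect_gte(nrow(g$edges), 1)
  expect_true(all(g$edges$weight >= thr & g$edges$weight <= 1))
  expect_equal(sum(g$nodes$degree), 2 * nrow(g$edges))
  expect_true(all(is.finite(g$layout)))
})

test_that("a single molecule yields a valid one-node graph", {
  g <- build_similarity_graph(list(only = "CCO"))
  expect_equal(nrow(g$nodes), 1)
  expect_equal(nrow(g$edges), 0)
  expect_equal(dim(g$layout), c(1L, 2L))
})

test_that("the edge set is invariant under input permutation", {
  sm <- unname(fixture_smiles10)
  ids <- names(fixture_smiles10)
  g1 <- build_similarity_graph(list(s = stats::setNames(sm, ids)),
                               threshold = 0.2)
  perm <- withr::with_seed(4, sample(10))
  g2 <- build_similarity_graph(list(s = stats::setNames(sm[perm], ids[perm])),
                               threshold = 0.2)
  key <- function(g) sort(paste(pmin(g$edges$id_a, g$edges$id_b),
                                pmax(g$edges$id_a, g$edges$id_b),
                                round(g$edges$weight, 10)))
  expect_equal(key(g1), key(g2))
})

test_that("graph exports write the edge list and GraphML", {
  g <- build_similarity_graph(list(a = c(m1 = "CCO", m2 = "OCC",
                                         m3 = "c1ccccc1")),
                              threshold = 0.5)
  csv <- withr::local_tempfile(fileext = ".csv")
  xml <- withr::local_tempfile(fileext = ".graphml")
  write_similarity_graph(g, edge_csv = csv, graphml = xml)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(g$edges))
  expect_match(readLines(xml, n = 2)[2], "graphml", ignore.case = TRUE)
})
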