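# Shared fixtures, built once per test run. All molecule sets are generated
# in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

# a small noiseless library plus its structural-count features
fixture_noiseless <- function(n = 250, seed = 101) {
  key <- paste0("nl", n, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    lib <- generate_library(synthetic_spec(n, seed = seed, noise_sigma = 0))
    X <- compute_descriptors(lib, panel = "counts")
    .fixture_cache[[key]] <- list(lib = lib, X = X, y = lib$records$logS)
  }
  .fixture_cache[[key]]
}

# a small tight-noise library with features
fixture_tight <- function(n = 200, seed = 103) {
  key <- paste0("ti", n, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    lib <- generate_library(synthetic_spec(n, seed = seed,
                                           noise_sigma = "tight"))
    X <- compute_descriptors(lib, panel = "counts")
    .fixture_cache[[key]] <- list(lib = lib, X = X, y = lib$records$logS)
  }
  .fixture_cache[[key]]
}

# ten structurally diverse drug-like molecules for fingerprint/scaffold tests
fixture_smiles10 <- c(
  benzene      = "c1ccccc1",
  toluene      = "Cc1ccccc1",
  phenol       = "Oc1ccccc1",
  pyridine     = "c1ccncc1",
  cyclohexane  = "C1CCCCC1",
  piperidine   = "C1CCNCC1",
  hexane       = "CCCCCC",
  ibuprofen    = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  caffeine     = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  naphthalene  = "c1ccc2ccccc2c1"
)

# deterministic toy prediction sets
random_prediction_set <- function(n, seed) {
  withr::with_seed(seed, {
    prediction_set(paste0("m", seq_len(n)),
                   y_calc = rnorm(n, -3, 1.5),
                   y_exp = rnorm(n, -3, 1.5))
  })
}

make_fp <- function(bits, nbits = 2048L) {
  structure(list(bits = as.integer(sort(bits)), nbits = as.integer(nbits),
                 radius = 2L), class = "morgan_fp")
}
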