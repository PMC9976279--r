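# Synthetic molecule libraries with a known structure -> log(S) ground truth.
#
# Molecules are assembled by decorating a small pool of drug-like scaffolds
# with substituents, so every generated SMILES is chemically valid by
# construction (no validity-repair loop). The noiseless log(S) is linear in
# five cheap structural counts with a dominant lipophilicity-like term
# (aliphatic carbon count), and Gaussian measurement noise is added in log10
# units at the tight (0.17) or loose (0.62) preset, mirroring the
# low-variance and high-variance halves of the solubility-challenge data.

.scaffolds <- list(
  benzene = list(
    tokens = c("c1", "c", "c", "c", "c", "c1"),
    sub_ok = rep(TRUE, 6),
    counts = c(aromatic_rings = 1, aliphatic_carbons = 0, hbd = 0, hba = 0,
               halogens = 0),
    heavy = 6
  ),
  pyridine = list(
    tokens = c("c1", "c", "c", "n", "c", "c1"),
    sub_ok = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    counts = c(aromatic_rings = 1, aliphatic_carbons = 0, hbd = 0, hba = 1,
               halogens = 0),
    heavy = 6
  ),
  piperidine = list(
    tokens = c("C1", "C", "C", "N", "C", "C1"),
    sub_ok = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    counts = c(aromatic_rings = 0, aliphatic_carbons = 5, hbd = 1, hba = 1,
               halogens = 0),
    heavy = 6
  ),
  cyclohexane = list(
    tokens = c("C1", "C", "C", "C", "C", "C1"),
    sub_ok = rep(TRUE, 6),
    counts = c(aromatic_rings = 0, aliphatic_carbons = 6, hbd = 0, hba = 0,
               halogens = 0),
    heavy = 6
  ),
  biphenyl = list(
    tokens = c("c1", "c", "c", "c(-c2ccccc2)", "c", "c1"),
    sub_ok = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    counts = c(aromatic_rings = 2, aliphatic_carbons = 0, hbd = 0, hba = 0,
               halogens = 0),
    heavy = 12
  )
)

.substituents <- local({
  m <- rbind(
    #                branch      alC hbd hba hal heavy  weight
    methyl     = c("C",          1,  0,  0,  0,  1),
    ethyl      = c("CC",         2,  0,  0,  0,  2),
    propyl     = c("CCC",        3,  0,  0,  0,  3),
    butyl      = c("CCCC",       4,  0,  0,  0,  4),
    isopropyl  = c("C(C)C",      3,  0,  0,  0,  3),
    hydroxyl   = c("O",          0,  1,  1,  0,  1),
    amine      = c("N",          0,  1,  1,  0,  1),
    carboxyl   = c("C(=O)O",     1,  1,  2,  0,  3),
    methoxy    = c("OC",         1,  0,  1,  0,  2),
    fluoro     = c("F",          0,  0,  0,  1,  1),
    chloro     = c("Cl",         0,  0,  0,  1,  1),
    bromo      = c("Br",         0,  0,  0,  1,  1)
  )
  data.frame(name = rownames(m), branch = m[, 1],
             aliphatic_carbons = as.numeric(m[, 2]), hbd = as.numeric(m[, 3]),
             hba = as.numeric(m[, 4]), halogens = as.numeric(m[, 5]),
             heavy = as.numeric(m[, 6]),
             weight = c(0.18, 0.12, 0.08, 0.06, 0.06, 0.12, 0.08, 0.07,
                        0.08, 0.05, 0.06, 0.04),
             row.names = NULL)
})

.count_names <- c("aromatic_rings", "aliphatic_carbons", "hbd", "hba",
                  "halogens")

#' Measurement-noise presets
#'
#' Standard deviations (log10 molar units) of the two solubility-challenge
#' test sets: `tight` = 0.17 (consistent inter-laboratory measurements),
#' `loose` = 0.62 (less reliable measurements).
#'
#' @return named numeric vector.
#' @export
noise_presets <- function() c(tight = 0.17, loose = 0.62)

#' Specification of a synthetic molecule library
#'
#' @param n_molecules number of molecules to generate (>= 1).
#' @param seed integer seed; the library is bit-reproducible given the seed.
#' @param noise_sigma Gaussian measurement-noise SD in log10 molar units, or
#'   one of the preset names `"tight"` (0.17) / `"loose"` (0.62).
#' @param coef named coefficient vector of the ground-truth linear model over
#'   the structural counts `aromatic_rings`, `aliphatic_carbons`, `hbd`,
#'   `hba`, `halogens`.
#' @param intercept intercept of the ground-truth model, log10 molar.
#' @param logS_range target range for the noiseless log(S); molecules outside
#'   it are resampled.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules, seed = 1L,
                           noise_sigma = noise_presets()[["tight"]],
                           coef = c(aromatic_rings = -1.2,
                                    aliphatic_carbons = -0.45,
                                    hbd = 0.60, hba = 0.30, halogens = -0.70),
                           intercept = -0.3,
                           logS_range = c(-8.5, 0.5)) {
  if (is.character(noise_sigma))
    noise_sigma <- noise_presets()[[match.arg(noise_sigma,
                                              names(noise_presets()))]]
  stopifnot(n_molecules >= 1, noise_sigma >= 0,
            length(logS_range) == 2, logS_range[1] < logS_range[2],
            setequal(names(coef), .count_names))
  structure(list(n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed),
                 noise_sigma = noise_sigma,
                 coef = coef[.count_names],
                 intercept = intercept,
                 logS_range = logS_range),
            class = "synthetic_spec")
}

# run expr under a given seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assemble_smiles <- function(scaffold, sites, subs) {
  sc <- .scaffolds[[scaffold]]
  tok <- sc$tokens
  if (length(sites)) {
    br <- .substituents$branch[match(subs, .substituents$name)]
    tok[sites] <- paste0(tok[sites], "(", br, ")")
  }
  paste0(tok, collapse = "")
}

.genotype_counts <- function(scaffold, subs) {
  counts <- .scaffolds[[scaffold]]$counts
  if (length(subs)) {
    idx <- match(subs, .substituents$name)
    for (nm in .count_names[-1])
      counts[nm] <- counts[nm] + sum(.substituents[[nm]][idx])
  }
  counts[.count_names]
}

.truth_logS <- function(spec, counts) {
  unname(spec$intercept + sum(spec$coef * counts))
}

#' Generate a synthetic molecule library
#'
#' Deterministic for a fixed seed. Molecules are drawn from the
#' scaffold-decoration grammar until their noiseless log(S) falls inside
#' `spec$logS_range`; observed values are truth plus i.i.d. Gaussian noise of
#' SD `spec$noise_sigma`. All generated molecules satisfy the curation
#' filters (heavy atoms >= 4, MW <= 1400, rotatable bonds <= 20) by
#' construction of the grammar.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_library`: `records` (data.frame with
#'   id, smiles, logS = observed, truth_logS, set_label), `counts` (matrix of
#'   the five ground-truth structural counts), `genotypes` (list of
#'   scaffold/sites/substituent encodings used for counterfactual mutation),
#'   and the `spec`.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_molecules
  with_local_seed(spec$seed, {
    scaff_names <- names(.scaffolds)
    scaff_prob <- c(0.30, 0.15, 0.15, 0.20, 0.20)
    genotypes <- vector("list", n)
    counts <- matrix(0, n, length(.count_names),
                     dimnames = list(NULL, .count_names))
    truth <- numeric(n)
    max_tries <- 1000L
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        sc <- sample(scaff_names, 1L, prob = scaff_prob)
        sites_avail <- which(.scaffolds[[sc]]$sub_ok)
        k <- sample(0:4, 1L, prob = c(0.10, 0.25, 0.30, 0.20, 0.15))
        k <- min(k, length(sites_avail))
        sites <- sort(sample(sites_avail, k))
        subs <- if (k) sample(.substituents$name, k, replace = TRUE,
                              prob = .substituents$weight) else character(0)
        ct <- .genotype_counts(sc, subs)
        tr <- .truth_logS(spec, ct)
        if (tr > spec$logS_range[1] && tr < spec$logS_range[2]) {
          genotypes[[i]] <- list(scaffold = sc, sites = sites, subs = subs)
          counts[i, ] <- ct
          truth[i] <- tr
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("generate_library: target log(S) range [",
             spec$logS_range[1], ", ", spec$logS_range[2],
             "] is unreachable with the given coefficients/intercept ",
             "(no grammar molecule landed inside it in ", max_tries,
             " draws)")
    }
    noise <- stats::rnorm(n, mean = 0, sd = spec$noise_sigma)
    smiles <- vapply(genotypes, function(g)
      .assemble_smiles(g$scaffold, g$sites, g$subs), character(1))
    records <- data.frame(
      id = sprintf("syn%05d", seq_len(n)),
      smiles = smiles,
      logS = truth + noise,
      truth_logS = truth,
      set_label = "synthetic"
    )
    structure(list(records = records, counts = counts,
                   genotypes = genotypes, spec = spec),
              class = "synthetic_library")
  })
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat("<synthetic_library> ", nrow(x$records), " molecules, noise sigma ",
      x$spec$noise_sigma, ", seed ", x$spec$seed, "\n", sep = "")
  cat("  truth log(S) range: [",
      round(min(x$records$truth_logS), 2), ", ",
      round(max(x$records$truth_logS), 2), "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.synthetic_library <- function(x, ...) x$records

#' Subset a synthetic library by row index
#' @param lib a `synthetic_library`.
#' @param idx integer row indices.
#' @return a `synthetic_library` with the selected molecules.
#' @export
subset_library <- function(lib, idx) {
  stopifnot(inherits(lib, "synthetic_library"))
  structure(list(records = lib$records[idx, , drop = FALSE],
                 counts = lib$counts[idx, , drop = FALSE],
                 genotypes = lib$genotypes[idx],
                 spec = lib$spec),
            class = "synthetic_library")
}

#' Train/test split of a molecule library
#'
#' `random` mode partitions molecules uniformly at random. `scaffold_disjoint`
#' mode guarantees that no Bemis-Murcko scaffold occurs in both partitions by
#' assigning whole scaffold groups to the test side (best-fit greedy in a
#' seeded random group order).
#'
#' @param lib a `synthetic_library` or a record data.frame with a `smiles`
#'   column.
#' @param mode `"random"` or `"scaffold_disjoint"`.
#' @param test_frac fraction of molecules in the test partition (0 < f < 1).
#' @param seed integer seed.
#' @param tol maximum tolerated deviation of the achieved test fraction in
#'   `scaffold_disjoint` mode before the split is declared infeasible.
#' @return list with `train` and `test`, same type as the input.
#' @export
split_fixture <- function(lib, mode = c("random", "scaffold_disjoint"),
                          test_frac = 0.30, seed = 1L, tol = 0.05) {
  mode <- match.arg(mode)
  stopifnot(test_frac > 0, test_frac < 1)
  records <- if (inherits(lib, "synthetic_library")) lib$records else lib
  n <- nrow(records)
  stopifnot(n >= 2)
  take <- function(idx) {
    if (inherits(lib, "synthetic_library")) subset_library(lib, idx)
    else records[idx, , drop = FALSE]
  }
  if (mode == "random") {
    test_idx <- with_local_seed(seed, sort(sample.int(n, floor(n * test_frac))))
  } else {
    scaf <- murcko_scaffold(records$smiles)
    groups <- split(seq_len(n), scaf)
    target <- test_frac * n
    test_idx <- with_local_seed(seed, {
      ord <- sample(length(groups))
      cur <- integer(0)
      for (g in ord) {
        cand <- c(cur, groups[[g]])
        if (abs(length(cand) - target) < abs(length(cur) - target))
          cur <- cand
      }
      sort(cur)
    })
    achieved <- length(test_idx) / n
    if (abs(achieved - test_frac) > tol) {
      sizes <- sort(vapply(groups, length, integer(1)), decreasing = TRUE)
      stop("split_fixture: scaffold-disjoint split at test_frac = ",
           test_frac, " is infeasible (closest achievable fraction ",
           round(achieved, 3), "); achievable fractions are multiples of ",
           "the scaffold group sizes ",
           paste(round(cumsum(sizes) / n, 3), collapse = ", "))
    }
  }
  list(train = take(setdiff(seq_len(n), test_idx)), test = take(test_idx))
}
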