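# Counterfactual fragment attribution: mutate molecules in a representation
# where every edit decodes to a valid structure, keep mutants whose predicted
# log(S) shifts by at least one log unit, reduce them to cluster
# representatives by fingerprint similarity, pair each representative with
# its parent when exactly one fragment descriptor differs, and aggregate the
# increase/decrease fractions per fragment.
#
# The robust encoding is the synthetic library's scaffold-decoration
# genotype (scaffold token + substituent tokens at named sites): token
# substitutions, insertions and deletions always decode to valid molecules,
# the property a SELFIES-style string encoding provides. Mutation is
# therefore defined for genotype-bearing molecules, i.e. the generated
# libraries this attribution procedure runs on.

#' Genotype of a library molecule
#'
#' @param lib a `synthetic_library`.
#' @param which molecule id or row index.
#' @return genotype list (`scaffold`, `sites`, `subs`).
#' @export
library_genotype <- function(lib, which) {
  stopifnot(inherits(lib, "synthetic_library"))
  i <- if (is.character(which)) match(which, lib$records$id) else which
  stopifnot(length(i) == 1L, !is.na(i), i >= 1, i <= nrow(lib$records))
  lib$genotypes[[i]]
}

.mutate_once <- function(g) {
  sc <- .scaffolds[[g$scaffold]]
  free <- setdiff(which(sc$sub_ok), g$sites)
  ops <- c(if (length(g$sites)) "substitute",
           if (length(free)) "insert",
           if (length(g$sites)) "delete")
  if (is.null(ops)) return(g)
  op <- sample(ops, 1L)
  if (op == "substitute") {
    k <- sample.int(length(g$sites), 1L)
    alt <- setdiff(.substituents$name, g$subs[k])
    g$subs[k] <- sample(alt, 1L)
  } else if (op == "insert") {
    s <- free[sample.int(length(free), 1L)]
    pos <- order(c(g$sites, s))
    g$sites <- c(g$sites, s)[pos]
    g$subs <- c(g$subs, sample(.substituents$name, 1L))[pos]
  } else {
    k <- sample.int(length(g$sites), 1L)
    g$sites <- g$sites[-k]
    g$subs <- g$subs[-k]
  }
  g
}

#' Generate mutated candidate molecules
#'
#' Applies 1 to `max_mutations` random token edits (substituent
#' substitution, insertion or deletion) to the genotype encoding. Every
#' candidate decodes to a valid molecule by construction; candidates
#' identical to the original are removed.
#'
#' @param genotype genotype list (see [library_genotype()]).
#' @param max_mutations maximum edits per candidate; 0 yields no candidates.
#' @param n_candidates number of distinct candidates requested.
#' @param seed integer seed; the candidate set is deterministic.
#' @return list with `records` (data.frame: id, smiles (canonical),
#'   raw_smiles) and `genotypes`; zero-row when no valid candidate was found
#'   within the attempt budget.
#' @export
mutate_molecule <- function(genotype, max_mutations = 3L, n_candidates = 20L,
                            seed = 1L) {
  stopifnot(is.list(genotype),
            all(c("scaffold", "sites", "subs") %in% names(genotype)),
            max_mutations >= 0, n_candidates >= 1)
  empty <- list(records = data.frame(id = character(0), smiles = character(0),
                                     raw_smiles = character(0)),
                genotypes = list())
  if (max_mutations == 0L) return(empty)
  orig_can <- ob_canonical(.assemble_smiles(genotype$scaffold,
                                            genotype$sites, genotype$subs))
  res <- with_local_seed(seed, {
    genos <- list()
    raws <- character(0)
    budget <- n_candidates * 20L
    for (attempt in seq_len(budget)) {
      g <- genotype
      for (m in seq_len(sample.int(max_mutations, 1L))) g <- .mutate_once(g)
      raw <- .assemble_smiles(g$scaffold, g$sites, g$subs)
      if (raw %in% raws) next
      genos[[length(genos) + 1L]] <- g
      raws <- c(raws, raw)
      if (length(raws) >= n_candidates + 5L) break
    }
    list(genos = genos, raws = raws)
  })
  if (!length(res$raws)) return(empty)
  can <- ob_canonical(res$raws)
  ok <- !is.na(can) & can != orig_can & !duplicated(can)
  keep <- utils::head(which(ok), n_candidates)
  if (!length(keep)) return(empty)
  list(records = data.frame(id = sprintf("cf%03d", seq_along(keep)),
                            smiles = can[keep],
                            raw_smiles = res$raws[keep]),
       genotypes = res$genos[keep])
}

#' Select counterfactual candidates by predicted shift
#'
#' Predicts the original molecule and all candidates, keeps candidates whose
#' predicted log(S) differs from the original by at least `delta` log units
#' (inclusive), clusters the kept candidates by fingerprint Tanimoto
#' similarity (greedy leader clustering at `cluster_threshold`), and returns
#' one representative per cluster: the candidate with the largest |shift|.
#'
#' @param model fitted model (`solq_model` or [final_fit()] result).
#' @param original_smiles SMILES of the parent molecule.
#' @param candidates candidate data.frame from [mutate_molecule()] (or any
#'   data.frame with `id` and `smiles`).
#' @param featurize function mapping a SMILES vector to the model's feature
#'   matrix.
#' @param delta minimum |predicted shift| in log units.
#' @param cluster_threshold Tanimoto threshold above which two candidates
#'   fall into the same cluster.
#' @return data.frame: id, smiles, pred, delta_pred (counterfactual minus
#'   original), one row per cluster representative.
#' @export
select_counterfactuals <- function(model, original_smiles, candidates,
                                   featurize, delta = 1.0,
                                   cluster_threshold = 0.7) {
  stopifnot(is.function(featurize), delta >= 0)
  predict_fun <- if (is.function(model)) {
    model
  } else if (inherits(model, "solq_model")) {
    function(X) predict(model, X)
  } else {
    function(X) predict_final(model, X)
  }
  if (nrow(candidates) == 0L)
    return(data.frame(id = character(0), smiles = character(0),
                      pred = numeric(0), delta_pred = numeric(0)))
  pred0 <- predict_fun(featurize(original_smiles))
  pred <- predict_fun(featurize(candidates$smiles))
  dp <- pred - pred0
  keep <- which(abs(dp) >= delta)
  if (!length(keep))
    return(data.frame(id = character(0), smiles = character(0),
                      pred = numeric(0), delta_pred = numeric(0)))
  keep <- keep[order(-abs(dp[keep]))]
  fps <- morgan_fp(candidates$smiles[keep])
  if (inherits(fps, "morgan_fp")) fps <- list(fps)
  reps <- integer(0)
  for (k in seq_along(keep)) {
    dup <- any(vapply(reps, function(r)
      tanimoto(fps[[k]], fps[[r]]) >= cluster_threshold, logical(1)))
    if (!dup) reps <- c(reps, k)
  }
  sel <- keep[reps]
  data.frame(id = candidates$id[sel], smiles = candidates$smiles[sel],
             pred = pred[sel], delta_pred = dp[sel])
}

#' Pair counterfactuals with their parent on single-fragment differences
#'
#' Computes the fragment-descriptor panel for the parent and each selected
#' counterfactual and keeps the pairs in which exactly one fragment
#' descriptor changed, recording which descriptor, the direction of its
#' change, and the predicted shift.
#'
#' @param original_smiles SMILES of the parent molecule.
#' @param selected data.frame from [select_counterfactuals()].
#' @return data.frame of class `counterfactual_pairs`: id, descriptor,
#'   direction (+1 fragment added / count increased, -1 removed),
#'   delta_pred.
#' @export
fragment_pairs <- function(original_smiles, selected) {
  empty <- structure(data.frame(id = character(0), descriptor = character(0),
                                direction = numeric(0),
                                delta_pred = numeric(0)),
                     class = c("counterfactual_pairs", "data.frame"))
  if (nrow(selected) == 0L) return(empty)
  fr <- compute_descriptors(c(original_smiles, selected$smiles),
                            panel = "fragments")
  orig <- fr[1, , drop = TRUE]
  rows <- list()
  for (k in seq_len(nrow(selected))) {
    d <- fr[k + 1L, ] - orig
    changed <- which(d != 0)
    if (length(changed) != 1L) next
    nm <- colnames(fr)[changed]
    rows[[length(rows) + 1L]] <- data.frame(
      id = selected$id[k], descriptor = nm,
      direction = sign(d[changed]), delta_pred = selected$delta_pred[k])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("counterfactual_pairs", "data.frame")
  out
}

#' Fragment effects over counterfactual pairs
#'
#' For each fragment descriptor, the fraction of pairs in which *adding*
#' the fragment (descriptor direction normalized) increased the predicted
#' solubility (`f_increase`), the fraction in which it decreased it
#' (`f_decrease`; ties count in neither), and the signed effect
#' `f_increase - f_decrease` in [-1, 1]. A positive effect means adding the
#' fragment raises predicted log(S).
#'
#' @param pairs data.frame with columns `descriptor`, `direction`,
#'   `delta_pred` (see [fragment_pairs()]); rows may pool many parents.
#' @return data.frame: descriptor, n_pairs, f_increase, f_decrease, effect,
#'   sorted by |effect| then descriptor.
#' @export
fragment_effects <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("descriptor", "direction", "delta_pred") %in% names(pairs)))
  if (nrow(pairs) == 0L)
    return(data.frame(descriptor = character(0), n_pairs = integer(0),
                      f_increase = numeric(0), f_decrease = numeric(0),
                      effect = numeric(0)))
  stopifnot(all(pairs$direction %in% c(-1, 1)))
  eff_shift <- pairs$delta_pred * pairs$direction  # shift per fragment added
  out <- do.call(rbind, lapply(split(seq_len(nrow(pairs)), pairs$descriptor),
    function(idx) {
      data.frame(descriptor = pairs$descriptor[idx[1]],
                 n_pairs = length(idx),
                 f_increase = mean(eff_shift[idx] > 0),
                 f_decrease = mean(eff_shift[idx] < 0))
    }))
  out$effect <- out$f_increase - out$f_decrease
  out <- out[order(-abs(out$effect), out$descriptor), ]
  rownames(out) <- NULL
  out
}

#' Run the full attribution over a synthetic library
#'
#' Mutates each selected parent, selects large-shift counterfactual
#' representatives, forms single-fragment pairs, and aggregates fragment
#' effects.
#'
#' @param lib a `synthetic_library`.
#' @param model fitted model (see [select_counterfactuals()]).
#' @param featurize function mapping SMILES to the model's feature matrix.
#' @param parents indices of parent molecules (default: all).
#' @param n_candidates,max_mutations,delta,cluster_threshold procedure
#'   parameters, see the stage functions.
#' @param seed integer master seed.
#' @return list with `pairs` (pooled) and `effects`.
#' @export
counterfactual_attribution <- function(lib, model, featurize,
                                       parents = seq_len(nrow(lib$records)),
                                       n_candidates = 20L, max_mutations = 3L,
                                       delta = 1.0, cluster_threshold = 0.7,
                                       seed = 1L) {
  stopifnot(inherits(lib, "synthetic_library"))
  seeds <- with_local_seed(seed, sample.int(2147483646L, length(parents)))
  all_pairs <- list()
  for (k in seq_along(parents)) {
    i <- parents[k]
    cand <- mutate_molecule(lib$genotypes[[i]], max_mutations = max_mutations,
                            n_candidates = n_candidates, seed = seeds[k])
    sel <- select_counterfactuals(model, lib$records$smiles[i], cand$records,
                                  featurize, delta = delta,
                                  cluster_threshold = cluster_threshold)
    pr <- fragment_pairs(lib$records$smiles[i], sel)
    if (nrow(pr)) {
      pr$id <- paste(lib$records$id[i], pr$id, sep = "/")
      all_pairs[[length(all_pairs) + 1L]] <- pr
    }
  }
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else
    fragment_pairs("C", data.frame(id = character(0), smiles = character(0),
                                   pred = numeric(0), delta_pred = numeric(0)))
  list(pairs = pairs, effects = fragment_effects(pairs))
}
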