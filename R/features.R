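# 2D descriptor panels, the descriptor-cleanup and scaling rules, and Morgan
# fingerprints. Descriptors come from two sources: OpenBabel's
# physicochemical properties (logP, TPSA, MR, ...) and structural/fragment
# counts computed on the molecular graph or by SMARTS matching. The panel is
# deliberately 2D-only; no conformers are ever generated.

.fragment_smarts <- c(
  fr_hydroxyl        = "[OX2H]",
  fr_phenol          = "[OX2H][cX3]",
  fr_primary_amine   = "[NX3;H2;!$(NC=O)]",
  fr_secondary_amine = "[NX3;H1;!$(NC=O)]",
  fr_carboxylic_acid = "[CX3](=O)[OX2H1]",
  fr_ester           = "[CX3](=O)[OX2][#6]",
  fr_ether           = "[OD2]([#6])[#6]",
  fr_amide           = "[NX3][CX3](=[OX1])",
  fr_nitro           = "[NX3+](=O)[O-]",
  fr_ketone          = "[#6][CX3](=O)[#6]",
  fr_aldehyde        = "[CX3H1](=O)",
  fr_nitrile         = "[NX1]#[CX2]",
  fr_halogen         = "[F,Cl,Br,I]",
  fr_aromatic_N      = "[nX2]",
  fr_methyl          = "[CX4H3]"
)

.count_smarts <- c(
  aliphatic_carbons = "[C]",
  hbd               = "[$([OX2H]),$([NX3;H1]),$([NX3;H2]),$([NX2;H1])]",
  hba               = "[#7,#8]",
  halogens          = "[F,Cl,Br,I]"
)

.records_smiles <- function(records) {
  if (inherits(records, "synthetic_library")) records <- records$records
  if (is.data.frame(records)) {
    stopifnot("smiles" %in% names(records))
    sm <- records$smiles
    names(sm) <- if ("id" %in% names(records)) records$id else
      paste0("mol", seq_along(sm))
    sm
  } else {
    stopifnot(is.character(records))
    if (is.null(names(records))) names(records) <- paste0("mol", seq_along(records))
    records
  }
}

#' Compute a 2D descriptor panel
#'
#' Computes the requested panel for every molecule and applies the cleanup
#' rules: descriptors whose name matches the solubility blocklist
#' (case-insensitive substrings "solubility", "logs", "esol") are removed;
#' descriptors with non-numeric (boolean/string) output are removed; and any
#' descriptor returning a missing or non-finite value for *any* molecule is
#' removed for all molecules, so that every molecule is described by the same
#' set of valid descriptors. Dropped columns are recorded in the
#' `"drop_log"` attribute.
#'
#' @param records record data.frame, `synthetic_library`, or SMILES vector.
#' @param panel `"all"` (default), `"physchem"` (OpenBabel logP, TPSA, MR,
#'   MW, H-bond counts), `"counts"` (graph/SMARTS structural counts,
#'   including the five ground-truth counts of the synthetic generator), or
#'   `"fragments"` (SMARTS fragment counts, the vocabulary of the
#'   counterfactual attribution).
#' @param extra optional named list of functions `f(smiles) -> vector`,
#'   appended as additional descriptor columns before cleanup.
#' @return numeric matrix (molecules x descriptors) with molecule ids as row
#'   names; attribute `drop_log` lists removed columns by cause.
#' @export
compute_descriptors <- function(records,
                                panel = c("all", "physchem", "counts",
                                          "fragments"),
                                extra = NULL) {
  panel <- match.arg(panel)
  if (length(records) == 0L ||
      (is.data.frame(records) && nrow(records) == 0L))
    stop("compute_descriptors: no molecules")
  smiles <- .records_smiles(records)
  cols <- list()

  if (panel %in% c("all", "physchem")) {
    pr <- ob_props(smiles)
    for (nm in c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA"))
      cols[[nm]] <- as.numeric(pr[[nm]])
  }
  if (panel %in% c("all", "counts")) {
    graphs <- mol_graphs(smiles)
    cols$heavy_atoms <- vapply(graphs, `[[`, numeric(1), "n_heavy")
    cols$aromatic_rings <- vapply(graphs, aromatic_ring_count, numeric(1))
    cols$aromatic_atoms <- vapply(graphs, function(g) sum(g$atoms$arom),
                                  numeric(1))
    cols$ring_atoms <- vapply(graphs, function(g) sum(g$atoms$ring),
                              numeric(1))
    cols$n_rings <- vapply(graphs, function(g) {
      if (!nrow(g$bonds) || !any(g$bonds$ring)) return(0)
      sub <- igraph::graph_from_edgelist(
        cbind(g$bonds$a1[g$bonds$ring], g$bonds$a2[g$bonds$ring]),
        directed = FALSE)
      sub <- igraph::delete_vertices(sub, which(igraph::degree(sub) == 0))
      igraph::ecount(sub) - igraph::vcount(sub) + igraph::count_components(sub)
    }, numeric(1))
    cols$rotatable_bonds <- vapply(graphs, rotatable_bonds, numeric(1))
    cols$n_nitrogen <- vapply(graphs, function(g) sum(g$atoms$symbol == "N"),
                              numeric(1))
    cols$n_oxygen <- vapply(graphs, function(g) sum(g$atoms$symbol == "O"),
                            numeric(1))
    sc <- smarts_counts(smiles, .count_smarts)
    for (nm in colnames(sc)) cols[[nm]] <- as.numeric(sc[, nm])
  }
  if (panel %in% c("all", "fragments")) {
    fc <- smarts_counts(smiles, .fragment_smarts)
    for (nm in colnames(fc)) cols[[nm]] <- as.numeric(fc[, nm])
  }
  if (!is.null(extra)) {
    stopifnot(is.list(extra), !is.null(names(extra)))
    for (nm in names(extra)) cols[[nm]] <- extra[[nm]](unname(smiles))
  }

  drop_log <- list(blocklist = character(0), nonnumeric = character(0),
                   invalid = character(0))
  keep <- list()
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (grepl("solubility|logs|esol", nm, ignore.case = TRUE)) {
      drop_log$blocklist <- c(drop_log$blocklist, nm)
    } else if (!is.numeric(v) || is.logical(v)) {
      drop_log$nonnumeric <- c(drop_log$nonnumeric, nm)
    } else if (any(!is.finite(v))) {
      drop_log$invalid <- c(drop_log$invalid, nm)
    } else {
      keep[[nm]] <- as.numeric(v)
    }
  }
  if (length(keep) == 0L)
    stop("compute_descriptors: all columns dropped (blocklist: ",
         length(drop_log$blocklist), ", non-numeric: ",
         length(drop_log$nonnumeric), ", invalid: ",
         length(drop_log$invalid), ")")
  m <- do.call(cbind, keep)
  rownames(m) <- names(smiles)
  attr(m, "drop_log") <- drop_log
  m
}

#' Fit a mean/SD feature scaler on a training matrix
#'
#' Standard mean-centered unit-variance scaling. SDs use the population
#' (divide-by-N) convention. Zero-variance columns are dropped and recorded.
#'
#' @param train numeric training feature matrix.
#' @return object of class `feature_scaler`.
#' @export
fit_scaler <- function(train) {
  stopifnot(is.matrix(train), nrow(train) >= 1, !is.null(colnames(train)))
  mu <- colMeans(train)
  sd_pop <- sqrt(colMeans(sweep(train, 2, mu)^2))
  dropped <- colnames(train)[sd_pop <= 0]
  keep <- sd_pop > 0
  structure(list(mean = mu[keep], sd = sd_pop[keep], dropped = dropped),
            class = "feature_scaler")
}

#' Apply a fitted scaler to a feature matrix
#'
#' Transforms with the *training* statistics only; the matrix must contain
#' exactly the scaler's columns (dropped zero-variance columns are removed).
#'
#' @param scaler a `feature_scaler`.
#' @param m numeric feature matrix.
#' @return scaled matrix restricted to the scaler's retained columns.
#' @export
apply_scaler <- function(scaler, m) {
  stopifnot(inherits(scaler, "feature_scaler"), is.matrix(m))
  want <- names(scaler$mean)
  have <- colnames(m)
  missing_cols <- setdiff(want, have)
  extra_cols <- setdiff(have, c(want, scaler$dropped))
  if (length(missing_cols) || length(extra_cols))
    stop("apply_scaler: column mismatch (missing: ",
         paste(missing_cols, collapse = ", "), "; unknown: ",
         paste(extra_cols, collapse = ", "), ")")
  out <- sweep(sweep(m[, want, drop = FALSE], 2, scaler$mean), 2, scaler$sd,
               `/`)
  attr(out, "drop_log") <- NULL
  out
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat("<feature_scaler> ", length(x$mean), " columns",
      if (length(x$dropped)) paste0(" (dropped zero-variance: ",
                                    paste(x$dropped, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

# ---- Morgan fingerprints ----------------------------------------------------

.atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                    P = 15, S = 16, Cl = 17, Br = 35, I = 53)

# deterministic polynomial hash over integer tuples, kept below 2^31 so all
# arithmetic stays exact in doubles
.hash_tuple <- function(v) {
  h <- 0
  for (x in v) h <- (h * 1000003 + (x %% 2147483647)) %% 2147483647
  h
}

#' Morgan (circular) fingerprint
#'
#' Radius-2, 2048-bit hashed circular fingerprint computed on the canonical
#' form of the molecule, so equivalent SMILES give identical fingerprints.
#' Initial atom invariants are (atomic number, degree, implicit H count,
#' formal charge, ring membership, aromaticity); each iteration hashes the
#' atom's invariant with the sorted (bond order, neighbour invariant) pairs.
#' Bit positions use the package's own deterministic hash and are therefore
#' not interchangeable with other toolkits' Morgan bits.
#'
#' @param smiles character vector of SMILES (canonicalized internally).
#' @param nbits fingerprint length.
#' @param radius number of neighbourhood-expansion iterations.
#' @return list of `morgan_fp` objects (fields `bits`, 1-based set-bit
#'   positions; `nbits`; `radius`); a single object when one SMILES is given.
#' @export
morgan_fp <- function(smiles, nbits = 2048L, radius = 2L) {
  stopifnot(is.character(smiles), nbits >= 2, radius >= 0)
  can <- ob_canonical(smiles)
  if (anyNA(can)) stop("morgan_fp: unparseable SMILES: ",
                       paste(smiles[is.na(can)], collapse = ", "))
  graphs <- mol_graphs(can)
  fps <- lapply(graphs, .morgan_one, nbits = as.integer(nbits),
                radius = as.integer(radius))
  if (length(fps) == 1L) fps[[1]] else fps
}

.morgan_one <- function(g, nbits, radius) {
  n <- g$n_heavy
  at <- g$atoms
  z <- .atomic_number[at$symbol]
  z[is.na(z)] <- 0
  inv <- vapply(seq_len(n), function(i) {
    .hash_tuple(c(z[i], at$degree[i], at$nH[i], at$charge[i],
                  as.integer(at$ring[i]), as.integer(at$arom[i])))
  }, numeric(1))
  nbr <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]; o <- g$bonds$order[k]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  all_inv <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      newinv <- vapply(seq_len(n), function(i) {
        if (is.null(nbr[[i]])) return(.hash_tuple(c(r, inv[i])))
        codes <- sort(vapply(seq_len(nrow(nbr[[i]])), function(k) {
          .hash_tuple(c(nbr[[i]][k, 2], inv[nbr[[i]][k, 1]]))
        }, numeric(1)))
        .hash_tuple(c(r, inv[i], codes))
      }, numeric(1))
      inv <- newinv
      all_inv <- c(all_inv, inv)
    }
  }
  bits <- sort(unique(as.integer(all_inv %% nbits) + 1L))
  structure(list(bits = bits, nbits = nbits, radius = radius),
            class = "morgan_fp")
}

#' @export
print.morgan_fp <- function(x, ...) {
  cat("<morgan_fp> radius ", x$radius, ", ", x$nbits, " bits, popcount ",
      length(x$bits), "\n", sep = "")
  invisible(x)
}

#' Fingerprints as a dense logical matrix (molecules x bits)
#' @param fps list of `morgan_fp` (or a single one).
#' @return logical matrix.
#' @export
fp_matrix <- function(fps) {
  if (inherits(fps, "morgan_fp")) fps <- list(fps)
  stopifnot(length(fps) > 0, all(vapply(fps, inherits, logical(1), "morgan_fp")))
  nbits <- fps[[1]]$nbits
  stopifnot(all(vapply(fps, function(f) f$nbits == nbits, logical(1))))
  m <- matrix(FALSE, length(fps), nbits)
  for (i in seq_along(fps)) m[i, fps[[i]]$bits] <- TRUE
  m
}

#' Export fingerprints as hexadecimal strings
#' @param fps list of `morgan_fp`.
#' @return character vector, one hex string per fingerprint.
#' @export
fp_hex <- function(fps) {
  if (inherits(fps, "morgan_fp")) fps <- list(fps)
  vapply(fps, function(f) {
    bytes <- integer(f$nbits / 8)
    for (b in f$bits) {
      byte <- (b - 1L) %/% 8L + 1L
      bytes[byte] <- bitwOr(bytes[byte], bitwShiftL(1L, (b - 1L) %% 8L))
    }
    paste(sprintf("%02x", bytes), collapse = "")
  }, character(1))
}
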