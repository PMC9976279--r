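# Light molecular-graph layer on top of ChemmineR / ChemmineOB (OpenBabel).
# All SMILES parsing, canonicalization, InChI generation and SMARTS matching go
# through OpenBabel; this file only adds the graph bookkeeping (degrees, ring
# bonds, implicit hydrogens) that the rest of the package needs.

# OpenBabel aborts a whole batch when any single SMILES is invalid, so batch
# calls are optimistic: one conversion for the common all-valid case, with a
# per-molecule fallback that attributes failures to rows.

#' Canonical SMILES via OpenBabel
#'
#' @param smiles character vector of SMILES strings.
#' @param neutralize logical; apply OpenBabel's +1/-1 charge neutralization
#'   before canonicalization.
#' @return character vector of canonical SMILES, `NA` where a string failed to
#'   parse.
#' @export
ob_canonical <- function(smiles, neutralize = FALSE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  opts <- if (neutralize) {
    data.frame(names = "neutralize", args = "")
  } else {
    data.frame(names = character(0), args = character(0))
  }
  one <- function(s) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(s, " x\n"), options = opts),
      error = function(e) ""
    )
    if (!nzchar(out)) return(NA_character_)
    sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
  }
  src <- paste0(smiles, " t", seq_along(smiles), "\n", collapse = "")
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", src, options = opts),
                  error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines) == length(smiles)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    res <- vapply(parts, `[`, character(1), 1L)
    # sanity: titles must come back in order, otherwise fall through
    titles <- trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1)))
    if (identical(titles, paste0("t", seq_along(smiles)))) return(res)
  }
  vapply(smiles, one, character(1), USE.NAMES = FALSE)
}

#' Molecular properties via OpenBabel
#'
#' Computes canonical SMILES, standard InChI, molecular weight, and the
#' OpenBabel 2D physicochemical descriptors (logP, TPSA, MR, H-bond counts,
#' fluorine count) for a vector of *parseable* SMILES. Pre-screen with
#' [ob_canonical()] when the input may contain invalid strings.
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame, one row per molecule, in input order.
#' @export
ob_props <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  src <- paste0(smiles, " t", seq_along(smiles), "\n", collapse = "")
  props <- ChemmineOB::forEachMol("SMILES", src, ChemmineOB::prop_OB,
                                  reduce = function(...) rbind(...))
  props <- as.data.frame(props)
  if (nrow(props) != length(smiles))
    stop("ob_props: ", length(smiles) - nrow(props), " molecule(s) failed to parse")
  rownames(props) <- NULL
  props$InChI <- trimws(props$InChI)
  props
}

#' Count SMARTS pattern matches
#'
#' @param smiles character vector of valid SMILES.
#' @param patterns named character vector of SMARTS patterns.
#' @return integer matrix, molecules x patterns.
#' @export
smarts_counts <- function(smiles, patterns) {
  stopifnot(is.character(smiles), is.character(patterns), !is.null(names(patterns)))
  if (length(smiles) == 0L)
    return(matrix(integer(0), 0, length(patterns), dimnames = list(NULL, names(patterns))))
  src <- paste0(smiles, " t", seq_along(smiles), "\n", collapse = "")
  res <- ChemmineOB::forEachMol("SMILES", src, function(m) {
    vapply(patterns, function(p) ChemmineOB::smartsSearch_OB(list(m), p), numeric(1))
  }, reduce = rbind)
  if (is.null(dim(res))) res <- matrix(res, ncol = length(patterns))
  if (nrow(res) != length(smiles))
    stop("smarts_counts: ", length(smiles) - nrow(res), " molecule(s) failed to parse")
  colnames(res) <- names(patterns)
  storage.mode(res) <- "integer"
  res
}

# standard valences for implicit-hydrogen assignment (organic subset);
# charge is added to the valence, which covers N+ (4), O- (1), N- (2)
.default_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

.atomic_mass <- c(H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453,
                  Br = 79.904, I = 126.904, Na = 22.990, K = 39.098,
                  Li = 6.941, Ca = 40.078, Mg = 24.305)

#' Build molecular graphs from SMILES
#'
#' Parses SMILES through OpenBabel and returns one graph per molecule: an atom
#' table (element, formal charge, implicit hydrogen count, degree, ring and
#' aromatic flags) and a bond table (endpoints, order, ring flag). Aromatic
#' atoms are perceived by `ChemmineR::rings()`; ring bonds are the non-bridge
#' edges of the connectivity graph.
#'
#' @param smiles character vector of valid SMILES (single component each).
#' @return list of `molgraph` objects, in input order.
#' @export
mol_graphs <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(list())
  src <- paste0(smiles, " t", seq_along(smiles), "\n", collapse = "")
  sdftxt <- ChemmineOB::convertFormat(
    "SMI", "SDF", src,
    options = data.frame(names = character(0), args = character(0)))
  if (!nzchar(sdftxt)) stop("mol_graphs: OpenBabel failed to parse the input batch")
  lines <- strsplit(sdftxt, "\n", fixed = TRUE)[[1]]
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(lines))
  if (length(sdfset) != length(smiles))
    stop("mol_graphs: ", length(smiles) - length(sdfset), " molecule(s) failed to parse")
  # per-molecule chunks, for the M CHG charge lines ChemmineR does not expose
  ends <- which(lines == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    chunk <- lines[starts[i]:ends[i]]
    out[[i]] <- .molgraph_one(sdfset[[i]], chunk, smiles[i])
  }
  out
}

.parse_chg <- function(chunk, n_atoms) {
  charge <- integer(n_atoms)
  for (ln in grep("^M  CHG", chunk, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charge[f[2 * j]] <- f[2 * j + 1]
  }
  charge
}

.molgraph_one <- function(sdf, chunk, smiles) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  symbol <- sub("_[0-9]+$", "", rownames(ab))
  charge <- .parse_chg(chunk, n)
  if (is.null(dim(bb)) && length(bb) >= 3) bb <- matrix(bb, nrow = 1)
  if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        ring = logical(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    bonds$ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  degree <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  bondsum <- integer(n)
  if (nrow(bonds)) {
    ord <- ifelse(bonds$order == 4L, 1.5, bonds$order)  # tolerate aromatic flag
    for (k in seq_len(nrow(bonds))) {
      bondsum[bonds$a1[k]] <- bondsum[bonds$a1[k]] + ord[k]
      bondsum[bonds$a2[k]] <- bondsum[bonds$a2[k]] + ord[k]
    }
  }
  defv <- .default_valence[symbol]
  defv[is.na(defv)] <- 0
  nH <- pmax(0, round(defv + charge - bondsum))
  ring_atom <- logical(n)
  if (nrow(bonds)) ring_atom[c(bonds$a1[bonds$ring], bonds$a2[bonds$ring])] <- TRUE
  arom <- .aromatic_atoms(sdf, n)
  mass <- .atomic_mass[symbol]
  mass[is.na(mass)] <- 0
  structure(list(
    smiles = smiles,
    atoms = data.frame(symbol = symbol, charge = charge, nH = nH,
                       degree = degree, ring = ring_atom, arom = arom),
    bonds = bonds,
    n_heavy = n,
    mw = sum(mass) + 1.008 * sum(nH)
  ), class = "molgraph")
}

.aromatic_atoms <- function(sdf, n) {
  arom <- logical(n)
  rr <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                 error = function(e) NULL)
  if (is.null(rr) || length(rr$RINGS) == 0) return(arom)
  isar <- unlist(rr$AROMATIC)
  for (j in seq_along(rr$RINGS)) {
    if (isTRUE(isar[j])) {
      idx <- as.integer(sub("^[A-Za-z]+_", "", rr$RINGS[[j]]))
      arom[idx] <- TRUE
    }
  }
  arom
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, ": ", x$n_heavy, " heavy atoms, ",
      nrow(x$bonds), " bonds, MW ", round(x$mw, 2), "\n", sep = "")
  invisible(x)
}

#' Count rotatable bonds
#'
#' Non-ring single bonds between two non-terminal heavy atoms, excluding
#' amide C-N bonds (the common toolkit default definition).
#'
#' @param graph a `molgraph`.
#' @return integer count.
#' @export
rotatable_bonds <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  b <- graph$bonds
  if (!nrow(b)) return(0L)
  deg <- graph$atoms$degree
  cand <- b$order == 1L & !b$ring & deg[b$a1] > 1L & deg[b$a2] > 1L
  if (!any(cand)) return(0L)
  # exclude amide C-N: a C=O carbon single-bonded to N
  carbonyl <- rep(FALSE, nrow(graph$atoms))
  dbl <- b$order == 2L
  for (k in which(dbl)) {
    s1 <- graph$atoms$symbol[b$a1[k]]; s2 <- graph$atoms$symbol[b$a2[k]]
    if (s1 == "C" && s2 == "O") carbonyl[b$a1[k]] <- TRUE
    if (s2 == "C" && s1 == "O") carbonyl[b$a2[k]] <- TRUE
  }
  amide <- cand &
    ((graph$atoms$symbol[b$a1] == "N" & carbonyl[b$a2]) |
     (graph$atoms$symbol[b$a2] == "N" & carbonyl[b$a1]))
  sum(cand & !amide)
}

#' Number of aromatic rings (cyclomatic count of the aromatic ring subgraph)
#' @param graph a `molgraph`.
#' @return integer count.
#' @export
aromatic_ring_count <- function(graph) {
  stopifnot(inherits(graph, "molgraph"))
  b <- graph$bonds
  ar <- graph$atoms$arom
  keep <- b$ring & ar[b$a1] & ar[b$a2]
  if (!any(keep)) return(0L)
  sub <- igraph::graph_from_edgelist(cbind(b$a1[keep], b$a2[keep]), directed = FALSE)
  sub <- igraph::delete_vertices(sub, which(igraph::degree(sub) == 0))
  igraph::ecount(sub) - igraph::vcount(sub) + igraph::count_components(sub)
}
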