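# Training/testing chemical-space audit: pairwise Tanimoto similarity
# distributions between sets, Bemis-Murcko scaffold counts and overlap, and
# the thresholded molecular similarity graph with a force-directed layout.

#' Tanimoto similarity of two fingerprints
#'
#' |A and B| / |A or B| over the set bits; defined as 0 when both
#' fingerprints are empty.
#'
#' @param a,b `morgan_fp` objects of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "morgan_fp"), inherits(b, "morgan_fp"))
  if (a$nbits != b$nbits)
    stop("tanimoto: fingerprint length mismatch (", a$nbits, " vs ",
         b$nbits, ")")
  u <- length(union(a$bits, b$bits))
  if (u == 0L) return(0)
  length(intersect(a$bits, b$bits)) / u
}

#' All-pairs Tanimoto similarity between two fingerprint lists
#'
#' @param fps_a,fps_b lists of `morgan_fp`; with `fps_b = NULL` the
#'   within-set matrix of `fps_a` is computed.
#' @return numeric matrix |A| x |B| of similarities.
#' @export
tanimoto_matrix <- function(fps_a, fps_b = NULL) {
  A <- fp_matrix(fps_a) * 1L
  B <- if (is.null(fps_b)) A else fp_matrix(fps_b) * 1L
  inter <- tcrossprod(A, B)
  pa <- rowSums(A); pb <- rowSums(B)
  uni <- outer(pa, pb, `+`) - inter
  out <- ifelse(uni > 0, inter / uni, 0)
  dimnames(out) <- NULL
  out
}

.set_fps <- function(x) {
  if (is.list(x) && length(x) && inherits(x[[1]], "morgan_fp")) return(x)
  if (inherits(x, "morgan_fp")) return(list(x))
  sm <- .records_smiles(x)
  fps <- morgan_fp(sm)
  if (inherits(fps, "morgan_fp")) fps <- list(fps)
  names(fps) <- names(sm)
  fps
}

#' Set-to-set Tanimoto similarity distribution
#'
#' All |A| x |B| pairwise similarities between two molecule sets (or the
#' |A|(|A|-1)/2 within-set pairs when `b` is omitted), with summary
#' statistics and a fixed-bin histogram (0.05-wide bins on [0, 1]).
#'
#' @param a,b record data.frames, SMILES vectors, or `morgan_fp` lists.
#' @return object of class `similarity_distribution` with fields `scores`,
#'   `summary` (mean, median, max, n) and `histogram`.
#' @export
set_to_set_distribution <- function(a, b = NULL) {
  fa <- .set_fps(a)
  within <- is.null(b)
  if (within) {
    stopifnot(length(fa) >= 2)
    m <- tanimoto_matrix(fa)
    scores <- m[upper.tri(m)]
  } else {
    fb <- .set_fps(b)
    stopifnot(length(fa) >= 1, length(fb) >= 1)
    scores <- as.numeric(tanimoto_matrix(fa, fb))
  }
  h <- graphics::hist(scores, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  structure(list(
    scores = scores,
    within_set = within,
    summary = list(mean = mean(scores), median = stats::median(scores),
                   max = max(scores), n = length(scores)),
    histogram = data.frame(lower = utils::head(h$breaks, -1),
                           upper = utils::tail(h$breaks, -1),
                           count = h$counts)
  ), class = "similarity_distribution")
}

#' @export
print.similarity_distribution <- function(x, ...) {
  s <- x$summary
  cat("<similarity_distribution> ", s$n,
      if (x$within_set) " within-set" else " set-to-set",
      " pairs: mean ", round(s$mean, 3), ", median ", round(s$median, 3),
      ", max ", round(s$max, 3), "\n", sep = "")
  invisible(x)
}

#' Bemis-Murcko scaffolds
#'
#' The ring systems plus the linkers between them, with side chains removed;
#' atoms double-bonded directly to the scaffold (e.g. exocyclic carbonyl
#' oxygens) are retained. Acyclic molecules have no scaffold and map to the
#' empty string.
#'
#' @param smiles character vector of valid SMILES.
#' @return character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules).
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  src <- paste0(smiles, " t", seq_along(smiles), "\n", collapse = "")
  sdftxt <- ChemmineOB::convertFormat(
    "SMI", "SDF", src,
    options = data.frame(names = character(0), args = character(0)))
  sdfset <- suppressWarnings(
    ChemmineR::read.SDFset(strsplit(sdftxt, "\n", fixed = TRUE)[[1]]))
  if (length(sdfset) != length(smiles))
    stop("murcko_scaffold: some SMILES failed to parse")
  out <- rep("", length(smiles))
  sdf_lines <- character(0)
  pending <- integer(0)
  for (i in seq_along(smiles)) {
    keep <- .murcko_atoms(sdfset[[i]])
    if (length(keep) == 0L) next
    sub <- ChemmineR::atomsubset(sdfset[[i]], keep)
    sdf_lines <- c(sdf_lines, ChemmineR::sdf2str(sub))
    pending <- c(pending, i)
  }
  if (length(pending)) {
    can <- ChemmineOB::convertFormat(
      "SDF", "CAN", paste0(sdf_lines, "\n", collapse = ""),
      options = data.frame(names = character(0), args = character(0)))
    lines <- strsplit(can, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    if (length(lines) != length(pending))
      stop("murcko_scaffold: scaffold canonicalization failed")
    out[pending] <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`,
                           character(1), 1L)
  }
  out
}

# atom rows of the Murcko framework: iteratively prune terminal atoms, then
# restore atoms double-bonded to the remaining core
.murcko_atoms <- function(sdf) {
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ChemmineR::atomblock(sdf))
  if (is.null(dim(bb)) && length(bb) >= 3) bb <- matrix(bb, nrow = 1)
  if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) return(integer(0))
  a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
  ord <- as.integer(bb[, 3])
  keep <- rep(TRUE, n)
  repeat {
    deg <- tabulate(c(a1[keep[a1] & keep[a2]], a2[keep[a1] & keep[a2]]),
                    nbins = n)
    prune <- keep & deg <= 1L
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  if (!any(keep)) return(integer(0))
  dbl <- ord == 2L
  restore <- c(a2[dbl & keep[a1] & !keep[a2]], a1[dbl & keep[a2] & !keep[a1]])
  sort(unique(c(which(keep), restore)))
}

#' Scaffold summary across molecule sets
#'
#' Unique Bemis-Murcko scaffolds per set and the pairwise overlap counts
#' between sets. Acyclic molecules fall into a shared "empty" scaffold
#' bucket that is reported separately and excluded from the unique counts
#' and overlaps.
#'
#' @param sets named list of record data.frames / SMILES vectors.
#' @return object of class `scaffold_summary`: per-set scaffold lists,
#'   `unique_counts`, `acyclic_counts`, and the `overlap` matrix.
#' @export
murcko_summary <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  scaf <- lapply(sets, function(s) murcko_scaffold(unname(.records_smiles(s))))
  uniq <- lapply(scaf, function(s) sort(unique(s[nzchar(s)])))
  k <- length(sets)
  ov <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    ov[i, j] <- length(intersect(uniq[[i]], uniq[[j]]))
  structure(list(
    scaffolds = uniq,
    unique_counts = vapply(uniq, length, integer(1)),
    acyclic_counts = vapply(scaf, function(s) sum(!nzchar(s)), integer(1)),
    overlap = ov
  ), class = "scaffold_summary")
}

#' @export
print.scaffold_summary <- function(x, ...) {
  cat("<scaffold_summary>\n  unique scaffolds: ",
      paste(names(x$unique_counts), x$unique_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  acyclic molecules: ",
      paste(names(x$acyclic_counts), x$acyclic_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Thresholded molecular similarity graph
#'
#' One node per molecule; an edge wherever the Tanimoto similarity is at or
#' above the threshold (inclusive), weighted by the similarity. A seeded
#' Fruchterman-Reingold force-directed layout is computed with the edge
#' weights as spring strengths; layout coordinates are advisory output.
#'
#' @param sets named list of record data.frames / SMILES vectors.
#' @param threshold edge-inclusion threshold in (0, 1].
#' @param layout_seed seed for the layout.
#' @return object of class `similarity_graph`: `graph` (igraph), `nodes`
#'   (id, set, degree), `edges` (id_a, id_b, weight), `layout` (n x 2
#'   coordinates).
#' @export
build_similarity_graph <- function(sets, threshold = 0.5, layout_seed = 1L) {
  stopifnot(is.list(sets), !is.null(names(sets)),
            threshold > 0, threshold <= 1)
  sm <- lapply(sets, .records_smiles)
  ids <- unlist(lapply(sm, names), use.names = FALSE)
  setlab <- rep(names(sets), vapply(sm, length, integer(1)))
  if (anyDuplicated(ids))
    ids <- paste(setlab, ids, sep = ":")
  fps <- .set_fps(unlist(sm, use.names = FALSE))
  m <- tanimoto_matrix(fps)
  n <- length(fps)
  pairs <- which(upper.tri(m) & m >= threshold, arr.ind = TRUE)
  edges <- data.frame(id_a = ids[pairs[, 1]], id_b = ids[pairs[, 2]],
                      weight = m[pairs])
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$set <- setlab
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(pairs[, 1], pairs[, 2]))
    igraph::E(g)$weight <- edges$weight
  }
  layout <- with_local_seed(layout_seed, {
    if (n == 1L) matrix(0, 1, 2)
    else igraph::layout_with_fr(g, weights = if (nrow(edges)) edges$weight
                                             else NULL)
  })
  stopifnot(all(is.finite(layout)))
  structure(list(
    graph = g,
    nodes = data.frame(id = ids, set = setlab,
                       degree = igraph::degree(g)),
    edges = edges,
    layout = layout,
    threshold = threshold
  ), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("<similarity_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (Tanimoto >= ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Export a similarity graph
#'
#' @param g a `similarity_graph`.
#' @param edge_csv path for the edge list CSV (id_a, id_b, weight).
#' @param graphml path for a GraphML file.
#' @export
write_similarity_graph <- function(g, edge_csv = NULL, graphml = NULL) {
  stopifnot(inherits(g, "similarity_graph"))
  if (!is.null(edge_csv))
    utils::write.csv(g$edges, edge_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(g$graph, graphml, format = "graphml")
  invisible(g)
}
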