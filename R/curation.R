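# Data-set curation: SMILES validation, salt stripping with charge
# neutralization, multi-component rejection, InChI deduplication, and the
# size/flexibility filters applied to every training and testing table.

# Counterions recognized for salt stripping. A multi-component SMILES is a
# salt when, after setting aside the highest-molecular-weight component as
# the parent, every remaining component is on this list; anything else is
# rejected as a solvate/mixture.
.counterion_smiles <- c(
  sodium = "[Na+]", potassium = "[K+]", lithium = "[Li+]",
  calcium = "[Ca+2]", magnesium = "[Mg+2]",
  chloride = "[Cl-]", bromide = "[Br-]", iodide = "[I-]",
  ammonium = "[NH4+]",
  acetate = "CC(=O)[O-]",
  sulfate = "[O-]S(=O)(=O)[O-]", hydrogensulfate = "OS(=O)(=O)[O-]",
  nitrate = "[O-][N+](=O)[O-]"
)

.solqspr_env <- new.env(parent = emptyenv())

.counterion_canonical <- function() {
  if (is.null(.solqspr_env$counterions)) {
    .solqspr_env$counterions <- ob_canonical(.counterion_smiles)
  }
  .solqspr_env$counterions
}

.has_formal_charge <- function(canonical_smiles) {
  grepl("\\[[^][]*[+-][^][]*\\]", canonical_smiles)
}

#' Standardize raw SMILES into curated molecule records
#'
#' Implements the compilation rules applied to every data set: each SMILES is
#' validated; salts are neutralized by removing the counterion components
#' (the parent is the highest-molecular-weight component, i.e. the lowest-MW
#' salt components are removed) and neutralizing the remaining +1/-1 charges;
#' multi-component strings whose extra components are not recognized
#' counterions are rejected as solvates/mixtures. The tautomer written in the
#' input SMILES is preserved: no tautomer canonicalization is applied.
#' Residual formal charges on single-component molecules (e.g. zwitterions)
#' are left untouched and flagged in the `charged` column.
#'
#' @param x data.frame with columns `id`, `smiles`, `logS` and optionally
#'   `source`; or a character vector of SMILES (ids are generated).
#' @return list with `records` (data.frame: id, smiles, inchi, logS, source,
#'   salt_stripped, charged) and `rejections` (data.frame: id, smiles,
#'   reason), where reason is `"unparseable"` or `"multicomponent"`.
#' @export
standardize_set <- function(x) {
  if (is.character(x)) {
    x <- data.frame(id = paste0("mol", seq_along(x)), smiles = x,
                    logS = NA_real_)
  }
  stopifnot(is.data.frame(x), all(c("id", "smiles") %in% names(x)))
  if (!"logS" %in% names(x)) x$logS <- NA_real_
  if (!"source" %in% names(x)) x$source <- ""
  if (anyDuplicated(x$id)) stop("standardize_set: duplicate ids in input")
  if (any(!nzchar(trimws(x$smiles)))) stop("standardize_set: empty SMILES string")

  n <- nrow(x)
  parent <- rep(NA_character_, n)       # pre-neutralization parent SMILES
  stripped <- logical(n)
  reason <- rep(NA_character_, n)

  multi <- grepl(".", x$smiles, fixed = TRUE)
  can0 <- rep(NA_character_, n)
  if (any(!multi)) can0[!multi] <- ob_canonical(x$smiles[!multi])
  parent[!multi] <- x$smiles[!multi]
  reason[!multi & is.na(can0)] <- "unparseable"

  wl <- .counterion_canonical()
  for (i in which(multi)) {
    comps <- strsplit(x$smiles[i], ".", fixed = TRUE)[[1]]
    ccan <- ob_canonical(comps)
    if (anyNA(ccan)) { reason[i] <- "unparseable"; next }
    mws <- vapply(mol_graphs(comps), `[[`, numeric(1), "mw")
    p <- which.max(mws)
    if (all(ccan[-p] %in% wl)) {
      parent[i] <- comps[p]
      stripped[i] <- TRUE
    } else {
      reason[i] <- "multicomponent"
    }
  }

  keep <- is.na(reason)
  rejections <- data.frame(id = x$id[!keep], smiles = x$smiles[!keep],
                           reason = reason[!keep])
  if (!any(keep)) {
    return(list(records = .empty_records(), rejections = rejections))
  }

  # canonicalize parents, neutralizing only where a counterion was stripped
  psm <- parent[keep]
  pstr <- stripped[keep]
  can <- rep(NA_character_, sum(keep))
  if (any(pstr)) can[pstr] <- ob_canonical(psm[pstr], neutralize = TRUE)
  if (any(!pstr)) can[!pstr] <- ob_canonical(psm[!pstr])

  props <- ob_props(can)
  records <- data.frame(
    id = x$id[keep],
    smiles = can,
    inchi = props$InChI,
    logS = x$logS[keep],
    source = x$source[keep],
    salt_stripped = pstr,
    charged = .has_formal_charge(can)
  )
  if ("set_label" %in% names(x)) records$set_label <- x$set_label[keep]
  list(records = records, rejections = rejections)
}

.empty_records <- function() {
  data.frame(id = character(0), smiles = character(0), inchi = character(0),
             logS = numeric(0), source = character(0),
             salt_stripped = logical(0), charged = logical(0))
}

#' Standardize a single SMILES string
#'
#' Convenience wrapper around [standardize_set()] for one molecule.
#'
#' @param raw_smiles a single SMILES string.
#' @param id record id.
#' @param logS experimental log10 molar solubility (optional).
#' @param source provenance tag (optional).
#' @return a one-row record data.frame, or an object of class
#'   `curation_rejection` with a `reason` field.
#' @export
standardize <- function(raw_smiles, id = "mol1", logS = NA_real_, source = "") {
  stopifnot(is.character(raw_smiles), length(raw_smiles) == 1L, nzchar(raw_smiles))
  res <- standardize_set(data.frame(id = id, smiles = raw_smiles, logS = logS,
                                    source = source))
  if (nrow(res$records) == 1L) return(res$records)
  structure(list(id = id, smiles = raw_smiles,
                 reason = res$rejections$reason[1]),
            class = "curation_rejection")
}

#' @export
print.curation_rejection <- function(x, ...) {
  cat("<rejected molecule> ", x$id, " (", x$smiles, "): ", x$reason, "\n",
      sep = "")
  invisible(x)
}

#' Remove duplicate molecules by InChI
#'
#' Duplicates are identified by exact standard-InChI string equality; the
#' first occurrence in input order is retained.
#'
#' @param records standardized record data.frame.
#' @return list with `records` and `removed_count`.
#' @export
deduplicate <- function(records) {
  stopifnot(is.data.frame(records), "inchi" %in% names(records))
  keep <- !duplicated(records$inchi)
  list(records = records[keep, , drop = FALSE],
       removed_count = sum(!keep))
}

#' Apply the size and flexibility filters
#'
#' Excludes very small (heavy atoms < 4), large (molecular weight > 1400) and
#' flexible (rotatable bonds > 20) molecules, exactly as strict inequalities;
#' boundary values are retained. When a molecule trips several filters only
#' the first matching reason is tallied (small, then large, then flexible).
#'
#' @param records standardized record data.frame.
#' @param min_heavy,max_mw,max_rotatable filter bounds.
#' @return list with `records` (retained rows) and `report` (a
#'   `curation_report` covering this filtering step).
#' @export
apply_filters <- function(records, min_heavy = 4, max_mw = 1400,
                          max_rotatable = 20) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n == 0L) {
    rep0 <- curation_report(input = 0L)
    return(list(records = records, report = rep0))
  }
  graphs <- mol_graphs(records$smiles)
  heavy <- vapply(graphs, `[[`, numeric(1), "n_heavy")
  mw <- vapply(graphs, `[[`, numeric(1), "mw")
  rot <- vapply(graphs, rotatable_bonds, numeric(1))
  reason <- rep(NA_character_, n)
  reason[heavy < min_heavy] <- "small"
  reason[is.na(reason) & mw > max_mw] <- "large"
  reason[is.na(reason) & rot > max_rotatable] <- "flexible"
  keep <- is.na(reason)
  rep <- curation_report(
    input = n,
    rejected_small = sum(reason == "small", na.rm = TRUE),
    rejected_large = sum(reason == "large", na.rm = TRUE),
    rejected_flexible = sum(reason == "flexible", na.rm = TRUE),
    retained = sum(keep),
    salt_stripped = sum(records$salt_stripped),
    charged_flagged = sum(records$charged)
  )
  list(records = records[keep, , drop = FALSE], report = rep)
}

#' Curation report
#'
#' Tally of what happened to every input record. The counts are conserved:
#' `input = retained + rejected_unparseable + rejected_multicomponent +
#' deduplicated + rejected_small + rejected_large + rejected_flexible`.
#'
#' @param input,rejected_unparseable,rejected_multicomponent,deduplicated,rejected_small,rejected_large,rejected_flexible,retained,salt_stripped,charged_flagged integer counts.
#' @return object of class `curation_report`.
#' @export
curation_report <- function(input = 0L, rejected_unparseable = 0L,
                            rejected_multicomponent = 0L, deduplicated = 0L,
                            rejected_small = 0L, rejected_large = 0L,
                            rejected_flexible = 0L, retained = 0L,
                            salt_stripped = 0L, charged_flagged = 0L) {
  rep <- list(input = as.integer(input),
              rejected_unparseable = as.integer(rejected_unparseable),
              rejected_multicomponent = as.integer(rejected_multicomponent),
              deduplicated = as.integer(deduplicated),
              rejected_small = as.integer(rejected_small),
              rejected_large = as.integer(rejected_large),
              rejected_flexible = as.integer(rejected_flexible),
              retained = as.integer(retained),
              salt_stripped = as.integer(salt_stripped),
              charged_flagged = as.integer(charged_flagged))
  class(rep) <- "curation_report"
  stopifnot(rep$input == rep$retained + rep$rejected_unparseable +
              rep$rejected_multicomponent + rep$deduplicated +
              rep$rejected_small + rep$rejected_large + rep$rejected_flexible)
  rep
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report:\n")
  for (f in names(unclass(x))) cat(sprintf("  %-24s %d\n", f, x[[f]]))
  invisible(x)
}

#' Full curation pipeline
#'
#' [standardize_set()], then [deduplicate()], then [apply_filters()], with a
#' single conserved [curation_report()] covering all steps.
#'
#' @param x input table (see [standardize_set()]).
#' @param ... filter bounds passed to [apply_filters()].
#' @return list with `records`, `report`, `rejections`.
#' @export
curate <- function(x, ...) {
  std <- standardize_set(x)
  dd <- deduplicate(std$records)
  fl <- apply_filters(dd$records, ...)
  rep <- curation_report(
    input = nrow(std$records) + nrow(std$rejections),
    rejected_unparseable = sum(std$rejections$reason == "unparseable"),
    rejected_multicomponent = sum(std$rejections$reason == "multicomponent"),
    deduplicated = dd$removed_count,
    rejected_small = fl$report$rejected_small,
    rejected_large = fl$report$rejected_large,
    rejected_flexible = fl$report$rejected_flexible,
    retained = fl$report$retained,
    salt_stripped = fl$report$salt_stripped,
    charged_flagged = fl$report$charged_flagged
  )
  list(records = fl$records, report = rep, rejections = std$rejections)
}

#' Serialize a curation report to JSON
#' @param report a `curation_report`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "curation_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
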