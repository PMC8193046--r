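# Structure parsing, canonical identity and stereoisomer-aware deduplication.
#
# Identity model: the canonical key of a molecule is the OpenBabel canonical
# SMILES computed after removing all tetrahedral and double-bond stereo
# descriptors. Two records are stereoisomer-redundant iff their keys agree.
# Tautomers and salt forms are NOT merged; only stereo redundancy is
# collapsed.

#' Parse a single SMILES record
#'
#' Parses a SMILES string, computes its stereo-agnostic canonical key and
#' heavy-atom count. Invalid input is rejected with an error naming the
#' record, never silently coerced.
#'
#' @param smiles SMILES string (non-empty).
#' @param id record identifier used in error messages and reports.
#' @return an object of class \code{capa_molecule}: a list with fields
#'   \code{id}, \code{smiles_input}, \code{canonical_key} (canonical SMILES
#'   with all stereo descriptors removed) and \code{heavy_atom_count}.
#' @examples
#' \donttest{
#' m <- parse_structure("CCO", "ethanol")
#' m$heavy_atom_count  # 3
#' }
#' @export
parse_structure <- function(smiles, id = "mol1") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("empty or missing SMILES for record '", id, "'")
  }
  key <- .ob_canonical(.strip_stereo_text(trimws(smiles)))
  if (!nzchar(key)) {
    stop("unparsable SMILES for record '", id, "': ", smiles)
  }
  g <- .mol_graph(key)
  structure(
    list(id = as.character(id), smiles_input = smiles, canonical_key = key,
         heavy_atom_count = nrow(g$atoms)),
    class = "capa_molecule"
  )
}

#' Parse a vector of SMILES records into a molecule table
#'
#' @param smiles character vector of SMILES.
#' @param ids record identifiers; defaults to \code{mol1..molN}. Duplicated
#'   ids keep their first occurrence's identity and are reported.
#' @param on_error \code{"stop"} aborts on the first unparsable record;
#'   \code{"reject"} collects bad records into the \code{rejects} attribute
#'   and continues.
#' @return a \code{data.frame} of class \code{capa_mols} with columns
#'   \code{id}, \code{smiles}, \code{canonical_key}, \code{heavy_atoms}; the
#'   \code{rejects} attribute holds a data.frame (id, smiles, reason) of
#'   records that failed to parse.
#' @export
parse_structures <- function(smiles, ids = NULL,
                             on_error = c("stop", "reject")) {
  on_error <- match.arg(on_error)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  ids <- as.character(ids)
  stopifnot(length(ids) == length(smiles))
  keys <- character(length(smiles))
  heavy <- integer(length(smiles))
  bad <- logical(length(smiles))
  reason <- character(length(smiles))
  for (i in seq_along(smiles)) {
    m <- tryCatch(parse_structure(smiles[i], ids[i]), error = function(e) e)
    if (inherits(m, "error")) {
      if (on_error == "stop") stop(conditionMessage(m), call. = FALSE)
      bad[i] <- TRUE; reason[i] <- conditionMessage(m)
    } else {
      keys[i] <- m$canonical_key; heavy[i] <- m$heavy_atom_count
    }
  }
  out <- data.frame(id = ids[!bad], smiles = smiles[!bad],
                    canonical_key = keys[!bad], heavy_atoms = heavy[!bad],
                    stringsAsFactors = FALSE)
  class(out) <- c("capa_mols", "data.frame")
  attr(out, "rejects") <- data.frame(id = ids[bad], smiles = smiles[bad],
                                     reason = reason[bad],
                                     stringsAsFactors = FALSE)
  out
}

#' Remove stereochemistry from a structure
#'
#' Strips all tetrahedral and double-bond stereo descriptors; the constitution
#' (heavy-atom multiset and bond multiset) is unchanged. Idempotent.
#'
#' @param x a SMILES string or a \code{capa_molecule}.
#' @return for SMILES input, the stereo-free canonical SMILES; for a
#'   \code{capa_molecule}, the molecule with \code{smiles_input} replaced by
#'   its stereo-free canonical form.
#' @export
strip_stereochemistry <- function(x) {
  if (inherits(x, "capa_molecule")) {
    out <- parse_structure(x$canonical_key, x$id)
    return(out)
  }
  key <- .ob_canonical(.strip_stereo_text(x))
  if (any(!nzchar(key))) stop("unparsable SMILES input")
  key
}

#' Deduplicate stereoisomer-redundant records
#'
#' Keeps the first-seen representative per stereo-agnostic canonical key,
#' preserving input order.
#'
#' @param mols a \code{capa_mols} table from \code{\link{parse_structures}}.
#' @return list with \code{unique} (a \code{capa_mols} table),
#'   \code{removed_count}, and \code{removed}: a data.frame (id,
#'   duplicate_of) mapping each removed record to its kept representative.
#' @export
deduplicate_stereoisomers <- function(mols) {
  stopifnot(inherits(mols, "data.frame"))
  if (nrow(mols) == 0L) {
    return(list(unique = mols, removed_count = 0L,
                removed = data.frame(id = character(0),
                                     duplicate_of = character(0),
                                     stringsAsFactors = FALSE)))
  }
  dup <- duplicated(mols$canonical_key)
  first_id <- setNames(mols$id[!dup], mols$canonical_key[!dup])
  removed <- data.frame(id = mols$id[dup],
                        duplicate_of = unname(first_id[mols$canonical_key[dup]]),
                        stringsAsFactors = FALSE)
  uni <- mols[!dup, , drop = FALSE]
  rownames(uni) <- NULL
  class(uni) <- class(mols)
  list(unique = uni, removed_count = sum(dup), removed = removed)
}

#' @export
print.capa_molecule <- function(x, ...) {
  cat("<molecule ", x$id, "> ", x$canonical_key,
      " (", x$heavy_atom_count, " heavy atoms)\n", sep = "")
  invisible(x)
}

#' Molecular formula of a parsed structure
#'
#' Hill-order molecular formula including implicit hydrogens.
#'
#' @param mol a \code{capa_molecule}.
#' @return character formula, e.g. \code{"C26H26N6O"}.
#' @export
molecular_formula <- function(mol) {
  stopifnot(inherits(mol, "capa_molecule"))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(mol$canonical_key, mol$id)))
  unname(ChemmineR::MF(sdf, addH = TRUE))
}

# ---- file readers -----------------------------------------------------------

#' Read a SMILES file
#'
#' One record per line, \code{SMILES[whitespace]ID}; lines starting with
#' \code{#} and blank lines are ignored. Records without an id get
#' \code{line<N>}.
#'
#' @param path file path.
#' @param on_error see \code{\link{parse_structures}}.
#' @return a \code{capa_mols} table.
#' @export
read_smiles_file <- function(path, on_error = c("stop", "reject")) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  parts <- strsplit(trimws(lines), "[ \t]+")
  smi <- vapply(parts, `[`, "", 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][2L] else paste0("line", lineno[i])
  }, "")
  parse_structures(smi, ids, on_error = match.arg(on_error))
}

#' Read a compound CSV with optional IC50 columns
#'
#' Expects columns \code{id} and \code{smiles}; optional per-target columns
#' \code{abcb1_ic50_um}, \code{abcc1_ic50_um}, \code{abcg2_ic50_um} where a
#' blank cell means not measured and \code{">X"} means censored above X.
#'
#' @param path file path.
#' @param on_error see \code{\link{parse_structures}}.
#' @return a \code{capa_mols} table; if IC50 columns are present they are
#'   carried along (as character, censoring preserved).
#' @export
read_compound_csv <- function(path, on_error = c("stop", "reject")) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "smiles")
  if (!all(need %in% names(df))) {
    stop("compound CSV must have columns 'id' and 'smiles'")
  }
  mols <- parse_structures(df$smiles, df$id, on_error = match.arg(on_error))
  extra <- intersect(c("abcb1_ic50_um", "abcc1_ic50_um", "abcg2_ic50_um"),
                     names(df))
  for (col in extra) {
    mols[[col]] <- as.character(df[[col]][match(mols$id, df$id)])
  }
  mols
}

#' Read an SDF (V2000) file
#'
#' The molecule name field is used as the record id.
#'
#' @param path file path.
#' @param on_error see \code{\link{parse_structures}}.
#' @return a \code{capa_mols} table.
#' @export
read_sdf_file <- function(path, on_error = c("stop", "reject")) {
  sdf <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdf)
  smi <- as.character(ChemmineR::sdf2smiles(sdf))
  parse_structures(smi, ids, on_error = match.arg(on_error))
}
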