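# The versioned substructure pattern registry and matching primitives.
#
# Match semantics (applied uniformly, OpenBabel aromaticity model):
#  * ring patterns are written as explicit SMARTS rings, so query ring atoms
#    can only map onto target atoms that close the same cycle -- substitution
#    and ring fusion are allowed, acyclic chain mimicry is not;
#  * aromatic ring queries use aromatic atoms, saturated ring queries use
#    aliphatic atoms;
#  * azole/azine positional isomers are strict (pyridine never matches a
#    pyrimidine ring, isoxazole never matches oxazole);
#  * terminal groups require their full methyl/hydrogen complement
#    (methoxy = O-CH3, amino = primary NH2, isopropyl/tert-butyl need all
#    terminal methyls).

.pattern_roles <- c("clear_positive", "secondary_positive",
                    "potential_positive", "clear_negative",
                    "basic_scaffold", "rejected_putative_positive")

#' Roles a substructure pattern can take
#' @return character vector of the six defined roles.
#' @export
pattern_roles <- function() .pattern_roles

#' Default positive roles used for positive-hit profiling
#' @return character vector: clear, secondary and potential positive.
#' @export
positive_roles <- function() {
  c("clear_positive", "secondary_positive", "potential_positive")
}

.new_library <- function(patterns, overrules, version) {
  stopifnot(all(c("name", "smarts", "role", "provenance") %in% names(patterns)))
  bad_role <- setdiff(unique(patterns$role), .pattern_roles)
  if (length(bad_role)) stop("unknown pattern role(s): ",
                             paste(bad_role, collapse = ", "))
  key <- paste(patterns$name, patterns$role)
  if (anyDuplicated(key)) {
    stop("duplicate (name, role) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  neg <- patterns$name[patterns$role == "clear_negative"]
  if (!all(overrules %in% neg)) {
    stop("overrules must be clear_negative names; offending: ",
         paste(setdiff(overrules, neg), collapse = ", "))
  }
  structure(list(patterns = patterns, overrules = overrules,
                 version = version),
            class = "capa_library")
}

#' Load a pattern registry file
#'
#' The registry is a tab-delimited text file with header
#' \code{name / smarts / role / provenance}. Every SMARTS is compiled on
#' load; offending entries are reported together.
#'
#' @param path registry file path.
#' @param overrules clear-negative names whose exclusion is suspended.
#' @param version version tag stored in the library.
#' @return a \code{capa_library}.
#' @export
read_pattern_registry <- function(path, overrules = character(0),
                                  version = "custom") {
  pat <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "")
  need <- c("name", "smarts", "role", "provenance")
  if (!all(need %in% names(pat))) {
    stop("registry must have columns: ", paste(need, collapse = ", "))
  }
  probe <- .mol_refs("c1ccccc1")
  bad <- vapply(pat$smarts, function(s) {
    inherits(tryCatch(.match_counts(probe, s), error = function(e) e), "error")
  }, logical(1))
  if (any(bad)) {
    stop("registry entries with invalid SMARTS: ",
         paste(pat$name[bad], collapse = ", "))
  }
  .new_library(pat, overrules, version)
}

#' Write a pattern registry file
#' @param lib a \code{capa_library}.
#' @param path output path.
#' @export
write_pattern_registry <- function(lib, path) {
  stopifnot(inherits(lib, "capa_library"))
  write.table(lib$patterns, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' The shipped C@PA pattern registry
#'
#' Returns the default pattern library: 8 clear positive hits, 32 clear
#' negative hits, 5 secondary positive hits, 15 derived potential positive
#' hits, 6 basic scaffolds and 16 rejected putative positive substructures,
#' with the clear-negative roles of pyrrolidine and oxazole suspended by
#' default (they were re-admitted as potential positives).
#'
#' @param version version tag; the shipped registry is \code{"capa-1.2"}.
#' @return a \code{capa_library}.
#' @examples
#' \donttest{
#' lib <- default_library()
#' role_counts(lib)
#' }
#' @export
default_library <- function(version = "capa-1.2") {
  path <- system.file("extdata", "capa_patterns.tsv", package = "capascreen",
                      mustWork = TRUE)
  read_pattern_registry(path, overrules = c("pyrrolidine", "oxazole"),
                        version = version)
}

#' Pattern counts per role
#' @param lib a \code{capa_library}.
#' @return named integer vector over the six roles.
#' @export
role_counts <- function(lib) {
  stopifnot(inherits(lib, "capa_library"))
  vapply(.pattern_roles, function(r) sum(lib$patterns$role == r), integer(1))
}

#' @export
print.capa_library <- function(x, ...) {
  cat("<pattern library ", x$version, "> ", nrow(x$patterns),
      " patterns\n", sep = "")
  rc <- role_counts(x)
  for (r in names(rc)) cat("  ", r, ": ", rc[r], "\n", sep = "")
  cat("  overrules: ", paste(x$overrules, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Subset of the registry by role, deduplicated by name (a name occurring in
# several requested roles is counted once).
.role_patterns <- function(lib, roles) {
  stopifnot(all(roles %in% .pattern_roles))
  sub <- lib$patterns[lib$patterns$role %in% roles, , drop = FALSE]
  sub[!duplicated(sub$name), , drop = FALSE]
}

#' Count embeddings of one pattern in one molecule
#'
#' Symmetry-deduplicated count of distinct substructure embeddings.
#'
#' @param smarts a SMARTS query string, or a pattern name resolved against
#'   \code{lib}.
#' @param mol a \code{capa_molecule}, a \code{capa_mols} table or a character
#'   vector of SMILES.
#' @param lib optional \code{capa_library} for name resolution.
#' @return integer vector of counts, one per molecule.
#' @export
count_matches <- function(smarts, mol, lib = NULL) {
  if (!is.null(lib) && smarts %in% lib$patterns$name) {
    smarts <- lib$patterns$smarts[match(smarts, lib$patterns$name)]
  }
  smi <- if (inherits(mol, "capa_molecule")) mol$canonical_key
         else if (inherits(mol, "data.frame")) mol$canonical_key
         else vapply(mol, function(s) parse_structure(s)$canonical_key, "")
  .match_counts(.mol_refs(smi), smarts)
}

#' Match matrix of library patterns over a molecule table
#'
#' @param mols a \code{capa_mols} table.
#' @param lib a \code{capa_library}.
#' @param roles roles to include; default all.
#' @return integer matrix, rows = molecules (named by id), columns = pattern
#'   names (deduplicated across the requested roles).
#' @export
match_matrix <- function(mols, lib, roles = pattern_roles()) {
  pat <- .role_patterns(lib, roles)
  refs <- .mol_refs(mols$canonical_key)
  M <- vapply(seq_len(nrow(pat)),
              function(i) .match_counts(refs, pat$smarts[i]),
              integer(nrow(mols)))
  if (nrow(mols) == 1L) M <- matrix(M, nrow = 1L)
  dimnames(M) <- list(mols$id, pat$name)
  M
}

#' Negative-pattern exclusion filter
#'
#' A molecule passes iff no enforced clear-negative pattern (i.e. outside the
#' overrule set) matches.
#'
#' @param mols a \code{capa_mols} table.
#' @param lib a \code{capa_library}.
#' @param overrules clear-negative names to suspend; defaults to the
#'   library's overrule set.
#' @return data.frame with columns \code{id}, \code{passed}, and
#'   \code{violations} (list column of matching enforced negative names,
#'   sorted).
#' @export
negative_filter <- function(mols, lib, overrules = lib$overrules) {
  neg <- .role_patterns(lib, "clear_negative")
  neg <- neg[!(neg$name %in% overrules), , drop = FALSE]
  refs <- .mol_refs(mols$canonical_key)
  hits <- lapply(seq_len(nrow(neg)),
                 function(i) .match_counts(refs, neg$smarts[i]) > 0L)
  viol <- lapply(seq_len(nrow(mols)), function(j) {
    v <- neg$name[vapply(hits, `[`, logical(1), j)]
    sort(v)
  })
  out <- data.frame(id = mols$id, stringsAsFactors = FALSE)
  out$passed <- lengths(viol) == 0L
  out$violations <- viol
  out
}

#' Positive-hit profile
#'
#' Which patterns of the requested positive roles occur in each molecule, and
#' how many distinct pattern names that is.
#'
#' @param mols a \code{capa_mols} table.
#' @param lib a \code{capa_library}.
#' @param roles roles counted as positive; default clear + secondary +
#'   potential ("extended positive hits" plus clear positives, 28 patterns).
#' @return data.frame with columns \code{id}, \code{hit_names} (list column,
#'   sorted) and \code{distinct_count}.
#' @export
positive_hit_profile <- function(mols, lib, roles = positive_roles()) {
  pat <- .role_patterns(lib, roles)
  refs <- .mol_refs(mols$canonical_key)
  hits <- lapply(seq_len(nrow(pat)),
                 function(i) .match_counts(refs, pat$smarts[i]) > 0L)
  hn <- lapply(seq_len(nrow(mols)), function(j) {
    sort(pat$name[vapply(hits, `[`, logical(1), j)])
  })
  out <- data.frame(id = mols$id, stringsAsFactors = FALSE)
  out$hit_names <- hn
  out$distinct_count <- lengths(hn)
  out
}

#' Library self-test against shipped exemplar pairs
#'
#' Each registry pattern ships with a hand-written exemplar molecule it must
#' match and a counter-exemplar it must reject.
#'
#' @param lib a \code{capa_library}.
#' @param examples_path exemplar table (name, role, exemplar, counter);
#'   defaults to the shipped file.
#' @return data.frame per (name, role): \code{exemplar_ok},
#'   \code{counter_ok}, \code{ok}.
#' @export
validate_library <- function(lib, examples_path = NULL) {
  if (is.null(examples_path)) {
    examples_path <- system.file("extdata", "pattern_examples.tsv",
                                 package = "capascreen", mustWork = TRUE)
  }
  ex <- read.delim(examples_path, stringsAsFactors = FALSE, quote = "")
  key_lib <- paste(lib$patterns$name, lib$patterns$role)
  key_ex <- paste(ex$name, ex$role)
  missing <- setdiff(key_lib, key_ex)
  if (length(missing)) stop("patterns without exemplar pair: ",
                            paste(missing, collapse = "; "))
  idx <- match(key_ex, key_lib)
  ex <- ex[!is.na(idx), , drop = FALSE]
  smarts <- lib$patterns$smarts[idx[!is.na(idx)]]
  ex$exemplar_ok <- vapply(seq_len(nrow(ex)), function(i) {
    .match_counts(.mol_refs(.ob_canonical(ex$exemplar[i])), smarts[i]) > 0L
  }, logical(1))
  ex$counter_ok <- vapply(seq_len(nrow(ex)), function(i) {
    .match_counts(.mol_refs(.ob_canonical(ex$counter[i])), smarts[i]) == 0L
  }, logical(1))
  ex$ok <- ex$exemplar_ok & ex$counter_ok
  ex[, c("name", "role", "exemplar_ok", "counter_ok", "ok")]
}
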