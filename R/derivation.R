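# Derivation of the potential positive hits from parent patterns:
#  * scaffold fragmentation: split fused (hetero)aromatic scaffolds into
#    their constituent monocyclic heteroaromatic rings;
#  * heterocyclic substructure hopping: ring expansion/contraction of
#    saturated 6/7-membered heterocycles conserving the heteroatom multiset;
#  * heteroaromatic substructure hopping: aromatic five-ring enumeration over
#    non-empty heteroatom sub-multisets (size 1-2) of the parent in 1,2- or
#    1,3-placement.
#
# The published derivation is curated, not exhaustive (e.g. isothiazole and
# pyrrole are natural enumerants yet absent from the published lists), so
# each hopping generator runs the raw enumeration and then intersects with
# its published target set; raw = TRUE exposes the unfiltered enumeration.

# ---- ring specs -------------------------------------------------------------

#' Construct a ring specification
#'
#' A ring is an ordered element sequence around a monocycle plus an aromatic
#' flag. Two rings are equal iff their sequences agree up to rotation and
#' reflection.
#'
#' @param elements character vector of element symbols around the ring.
#' @param aromatic logical flag.
#' @return object of class \code{ring_spec}.
#' @export
ring_spec <- function(elements, aromatic) {
  stopifnot(length(elements) >= 3L, length(elements) <= 8L,
            is.logical(aromatic), length(aromatic) == 1L)
  structure(list(elements = toupper(elements), aromatic = aromatic,
                 size = length(elements)),
            class = "ring_spec")
}

# Rotation/reflection-minimal key ("a:N,C,N,C,C").
.ring_key <- function(spec) {
  e <- spec$elements
  n <- length(e)
  variants <- character(0)
  for (s in seq_len(n)) {
    rot <- e[c(s:n, seq_len(s - 1L))]
    variants <- c(variants, paste(rot, collapse = ","),
                  paste(rev(rot), collapse = ","))
  }
  paste0(if (spec$aromatic) "a:" else "s:", min(variants))
}

#' @export
print.ring_spec <- function(x, ...) {
  cat("<ring ", if (x$aromatic) "aromatic " else "saturated ", x$size,
      "-membered: ", paste(x$elements, collapse = "-"), ">\n", sep = "")
  invisible(x)
}

# Known named rings: trivial name, element sequence, aromaticity and the
# SMARTS used when the ring is promoted to a registry pattern. Pyrrole-type
# nitrogens in single-N aromatic five-rings are written [nX3] so that
# pyridine-type nitrogens cannot stand in for them.
.known_rings <- local({
  df <- data.frame(
    name = c("pyridine", "pyridazine", "pyrimidine", "pyrazine",
             "pyrrole", "furan", "thiophene",
             "imidazole", "pyrazole", "oxazole", "isoxazole",
             "thiazole", "isothiazole",
             "1,2,4-oxadiazole", "1,3,4-oxadiazole",
             "1,2,4-thiadiazole", "1,3,4-thiadiazole",
             "pyrrolidine", "oxolane", "thiolane",
             "imidazolidine", "oxazolidine", "thiazolidine",
             "piperidine", "piperazine", "morpholine", "oxane", "thiane",
             "thiomorpholine",
             "homo-piperidine", "homo-piperazine", "homo-morpholine",
             "oxepane"),
    seq = c("N,C,C,C,C,C", "N,N,C,C,C,C", "N,C,N,C,C,C", "N,C,C,N,C,C",
            "N,C,C,C,C", "O,C,C,C,C", "S,C,C,C,C",
            "N,C,N,C,C", "N,N,C,C,C", "O,C,N,C,C", "O,N,C,C,C",
            "S,C,N,C,C", "S,N,C,C,C",
            "O,N,C,N,C", "O,C,N,N,C",
            "S,N,C,N,C", "S,C,N,N,C",
            "N,C,C,C,C", "O,C,C,C,C", "S,C,C,C,C",
            "N,C,N,C,C", "O,C,N,C,C", "S,C,N,C,C",
            "N,C,C,C,C,C", "N,C,C,N,C,C", "O,C,C,N,C,C", "O,C,C,C,C,C",
            "S,C,C,C,C,C", "S,C,C,N,C,C",
            "N,C,C,C,C,C,C", "N,C,C,N,C,C,C", "O,C,C,N,C,C,C",
            "O,C,C,C,C,C,C"),
    aromatic = c(rep(TRUE, 17), rep(FALSE, 16)),
    smarts = c("n1ccccc1", "n1ncccc1", "n1cnccc1", "n1ccncc1",
               "[nX3]1cccc1", "o1cccc1", "s1cccc1",
               "n1cncc1", "n1nccc1", "o1cncc1", "o1nccc1",
               "s1cncc1", "s1nccc1",
               "o1ncnc1", "o1cnnc1",
               "s1ncnc1", "s1cnnc1",
               "N1CCCC1", "O1CCCC1", "S1CCCC1",
               "N1CNCC1", "O1CNCC1", "S1CNCC1",
               "N1CCCCC1", "N1CCNCC1", "O1CCNCC1", "O1CCCCC1", "S1CCCCC1",
               "S1CCNCC1",
               "N1CCCCCC1", "N1CCNCCC1", "O1CCNCCC1",
               "O1CCCCCC1"),
    stringsAsFactors = FALSE
  )
  df$key <- vapply(seq_len(nrow(df)), function(i) {
    .ring_key(ring_spec(strsplit(df$seq[i], ",")[[1]], df$aromatic[i]))
  }, "")
  df
})

#' Name a ring specification
#'
#' @param spec a \code{ring_spec}.
#' @return the trivial name if the ring is known, otherwise a systematic
#'   label such as \code{"aromatic 5-ring [N,N,C,C,C]"}.
#' @export
ring_name <- function(spec) {
  key <- .ring_key(spec)
  hit <- match(key, .known_rings$key)
  if (!is.na(hit)) return(.known_rings$name[hit])
  canon <- sub("^[as]:", "", key)
  paste0(if (spec$aromatic) "aromatic " else "saturated ", spec$size,
         "-ring [", canon, "]")
}

# SMARTS for a ring spec: table lookup for known rings, mechanical encoding
# otherwise (lowercase atoms for aromatic, uppercase for saturated rings).
.ring_smarts <- function(spec) {
  key <- .ring_key(spec)
  hit <- match(key, .known_rings$key)
  if (!is.na(hit)) return(.known_rings$smarts[hit])
  e <- spec$elements
  sym <- if (spec$aromatic) tolower(e) else toupper(e)
  paste0(sym[1], "1", paste(sym[-1], collapse = ""), "1")
}

# Resolve parents given as trivial ring names or plain ring SMILES into specs.
.resolve_ring <- function(x) {
  hit <- match(x, .known_rings$name)
  if (!is.na(hit)) {
    return(ring_spec(strsplit(.known_rings$seq[hit], ",")[[1]],
                     .known_rings$aromatic[hit]))
  }
  g <- .mol_graph(x)
  rings <- .find_rings(nrow(g$atoms), g$bonds)
  if (length(rings) != 1L) {
    stop("parent '", x, "' is not a known ring name or a monocyclic SMILES")
  }
  ring <- rings[[1]]
  ring_spec(g$atoms$element[ring], all(g$atoms$aromatic[ring]))
}

.ring_pattern_row <- function(spec, provenance) {
  data.frame(name = ring_name(spec), smarts = .ring_smarts(spec),
             role = "potential_positive", provenance = provenance,
             stringsAsFactors = FALSE)
}

# Deduplicate pattern rows by ring identity (name), merging provenance.
.dedup_rows <- function(rows) {
  if (nrow(rows) == 0L) return(rows)
  out <- rows[!duplicated(rows$name), , drop = FALSE]
  for (i in seq_len(nrow(out))) {
    prov <- unique(rows$provenance[rows$name == out$name[i]])
    out$provenance[i] <- paste(prov, collapse = " + ")
  }
  rownames(out) <- NULL
  out
}

# ---- generators -------------------------------------------------------------

#' SMILES of the six basic scaffolds
#'
#' The fused (hetero)aromatic scaffolds identified among the class 7
#' compounds, used as fragmentation input.
#'
#' @return named character vector of scaffold SMILES.
#' @export
basic_scaffold_smiles <- function() {
  c("4-anilinopyrimidine" = "c1ccc(Nc2ccncn2)cc1",
    "quinazoline" = "c1ccc2c(c1)cncn2",
    "pyrrolo[3,2-d]pyrimidine" = "c1cc2ncncc2[nH]1",
    "pyrimido[5,4-b]indole" = "c1ccc2c(c1)[nH]c1ncncc21",
    "quinoline" = "c1ccc2ncccc2c1",
    "thieno[2,3-b]pyrimidine" = "c1ncnc2sccc12")
}

#' Scaffold fragmentation
#'
#' Splits each scaffold into its constituent simple (chordless) rings and
#' keeps the unique monocyclic aromatic rings containing at least one
#' heteroatom; pure carbocycles are discarded and exocyclic substituents are
#' stripped.
#'
#' @param scaffolds character vector of scaffold SMILES (default: the six
#'   basic scaffolds).
#' @return data.frame of pattern rows (name, smarts, role, provenance);
#'   acyclic inputs contribute nothing (with a warning).
#' @export
fragment_scaffolds <- function(scaffolds = basic_scaffold_smiles()) {
  rows <- list()
  for (s in scaffolds) {
    g <- .mol_graph(s)
    rings <- .find_rings(nrow(g$atoms), g$bonds)
    if (!length(rings)) {
      warning("acyclic scaffold skipped: ", s)
      next
    }
    for (ring in rings) {
      elems <- g$atoms$element[ring]
      if (!any(elems %in% c("N", "O", "S"))) next
      if (!all(g$atoms$aromatic[ring])) next
      spec <- ring_spec(elems, aromatic = TRUE)
      rows[[length(rows) + 1L]] <-
        .ring_pattern_row(spec, "scaffold fragmentation")
    }
  }
  if (!length(rows)) {
    return(data.frame(name = character(0), smarts = character(0),
                      role = character(0), provenance = character(0),
                      stringsAsFactors = FALSE))
  }
  .dedup_rows(do.call(rbind, rows))
}

#' Heterocyclic substructure hopping
#'
#' For each saturated 6- or 7-membered parent with 1-2 heteroatoms, generates
#' the saturated rings one atom smaller and larger (within sizes 5-7) that
#' preserve the heteroatom multiset; 1,4-diheteroatom parents contract to
#' 1,3-placement (the maximal separation the smaller ring allows).
#'
#' @param parents ring names or monocyclic SMILES; default the published
#'   parents (piperazine, homo-piperazine, piperidine, morpholine).
#' @param raw if TRUE return the full enumeration; otherwise intersect with
#'   the published target set (imidazolidine, homo-piperidine, pyrrolidine,
#'   homo-morpholine, oxazolidine).
#' @return data.frame of pattern rows.
#' @export
hop_heterocycle <- function(parents = c("piperazine", "homo-piperazine",
                                        "piperidine", "morpholine"),
                            raw = FALSE) {
  allow <- c("imidazolidine", "homo-piperidine", "pyrrolidine",
             "homo-morpholine", "oxazolidine")
  rows <- list()
  for (p in parents) {
    spec <- .resolve_ring(p)
    het_pos <- which(spec$elements != "C")
    n_het <- length(het_pos)
    if (spec$aromatic || !(spec$size %in% c(6L, 7L)) ||
        !(n_het %in% c(1L, 2L))) {
      warning("unsupported hopping parent skipped: ", p)
      next
    }
    het <- spec$elements[het_pos]
    d <- if (n_het == 2L) {
      raw_d <- abs(diff(het_pos))
      min(raw_d, spec$size - raw_d)
    } else NA_integer_
    for (target in intersect(c(spec$size - 1L, spec$size + 1L), 5:7)) {
      elems <- rep("C", target)
      elems[1L] <- het[1L]
      if (n_het == 2L) {
        d2 <- min(d, target %/% 2L)   # contraction pulls 1,4 to 1,3
        elems[1L + d2] <- het[2L]
      }
      rows[[length(rows) + 1L]] <-
        .ring_pattern_row(ring_spec(elems, FALSE),
                          paste0("heterocyclic substructure hopping (from ",
                                 ring_name(spec), ")"))
    }
  }
  out <- if (length(rows)) .dedup_rows(do.call(rbind, rows)) else
    data.frame(name = character(0), smarts = character(0),
               role = character(0), provenance = character(0))
  if (!raw) out <- out[out$name %in% allow, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Heteroaromatic substructure hopping
#'
#' For each aromatic five-membered parent with three heteroatoms, enumerates
#' the aromatic five-rings whose heteroatom multiset is a non-empty
#' sub-multiset (size 1-2) of the parent's heteroatoms, placed 1,2- or 1,3-.
#'
#' @param parents ring names or monocyclic SMILES; default 1,2,4-oxadiazole
#'   and 1,3,4-thiadiazole.
#' @param raw if TRUE return the full enumeration; otherwise intersect with
#'   the published target set (isoxazole, oxazole, imidazole, furan,
#'   thiazole, pyrazole, thiophene).
#' @return data.frame of pattern rows.
#' @export
hop_heteroaromatic <- function(parents = c("1,2,4-oxadiazole",
                                           "1,3,4-thiadiazole"),
                               raw = FALSE) {
  allow <- c("isoxazole", "oxazole", "imidazole", "furan", "thiazole",
             "pyrazole", "thiophene")
  rows <- list()
  for (p in parents) {
    spec <- .resolve_ring(p)
    het <- spec$elements[spec$elements != "C"]
    if (!spec$aromatic || spec$size != 5L || length(het) < 1L) {
      warning("unsupported hopping parent skipped: ", p)
      next
    }
    subsets <- lapply(seq_along(het), function(i) het[i])
    if (length(het) >= 2L) {
      for (i in seq_len(length(het) - 1L)) {
        for (j in (i + 1L):length(het)) {
          subsets[[length(subsets) + 1L]] <- het[c(i, j)]
        }
      }
    }
    for (sub in subsets) {
      if (length(sub) == 1L) {
        elems <- c(sub, rep("C", 4L))
        rows[[length(rows) + 1L]] <-
          .ring_pattern_row(ring_spec(elems, TRUE),
                            paste0("heteroaromatic substructure hopping ",
                                   "(from ", ring_name(spec), ")"))
      } else {
        for (d in 1:2) {
          elems <- rep("C", 5L)
          elems[1L] <- sub[1L]
          elems[1L + d] <- sub[2L]
          rows[[length(rows) + 1L]] <-
            .ring_pattern_row(ring_spec(elems, TRUE),
                              paste0("heteroaromatic substructure hopping ",
                                     "(from ", ring_name(spec), ")"))
        }
      }
    }
  }
  out <- if (length(rows)) .dedup_rows(do.call(rbind, rows)) else
    data.frame(name = character(0), smarts = character(0),
               role = character(0), provenance = character(0))
  if (!raw) out <- out[out$name %in% allow, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compile the potential positive hit set
#'
#' Union of the three generator outputs, deduplicated by ring identity
#' (thiophene arises from both fragmentation and heteroaromatic hopping and
#' is counted once). Derived rings that collide with clear-negative names
#' (pyrrolidine, oxazole) are retained and simultaneously registered in the
#' library's overrule set.
#'
#' @param frag,het,arom outputs of \code{\link{fragment_scaffolds}},
#'   \code{\link{hop_heterocycle}}, \code{\link{hop_heteroaromatic}}.
#' @param lib a \code{capa_library} whose overrules are extended.
#' @return list with \code{patterns} (the deduplicated pattern rows) and
#'   \code{library} (the updated library).
#' @export
compile_potential_positive <- function(frag, het, arom, lib) {
  stopifnot(inherits(lib, "capa_library"))
  rows <- .dedup_rows(rbind(frag, het, arom))
  rows <- rows[order(rows$name), , drop = FALSE]
  rownames(rows) <- NULL
  neg <- lib$patterns$name[lib$patterns$role == "clear_negative"]
  clash <- intersect(rows$name, neg)
  lib$overrules <- sort(unique(c(lib$overrules, clash)))
  list(patterns = rows, library = lib)
}

#' Run the complete derivation
#'
#' Fragmentation of the six basic scaffolds plus both hopping generators,
#' compiled into the potential positive hit set.
#'
#' @param lib a \code{capa_library}; defaults to the shipped registry.
#' @return see \code{\link{compile_potential_positive}}.
#' @export
derive_potential_positives <- function(lib = default_library()) {
  compile_potential_positive(fragment_scaffolds(),
                             hop_heterocycle(),
                             hop_heteroaromatic(),
                             lib)
}
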