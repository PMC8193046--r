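# Topological pharmacophore feature typing and slot-coverage checks.
#
# This is a 2D surrogate for the published 3D five-feature models (whose
# coordinates are not public): molecular feature groups are typed
# topologically and assigned to model slots by maximum bipartite matching.
# All results are coverage counts of the topological surrogate, not 3D
# alignments.
#
# Feature typing:
#  * aromatic group: a connected system of aromatic rings (a fused system
#    counts once -- an isoquinoline cannot fill two aromatic slots);
#  * purely carbocyclic aromatic systems are additionally typed hydrophobic
#    (a phenyl ring is a hydrophobic ring), so they may serve either slot;
#  * hydrophobic group: a maximal connected cluster of non-ring aliphatic
#    carbons of size >= min_cluster, or any such cluster bearing a halogen;
#  * acceptor atom: N/O with an available lone pair, excluding amide and
#    thioamide nitrogens, sulfonamide nitrogens, N-aryl (aniline-type)
#    nitrogens, and quaternary/positively charged atoms.

.acceptor_smarts <- paste0(
  "[$([nX2]),",
  "$([NX2;+0;!$([NX2]=[OX1])]),",
  "$([NX3;+0;!$([NX3][CX3]=[OX1]);!$([NX3][CX3]=[SX1]);",
  "!$([NX3][SX4](=[OX1])=[OX1]);!$([NX3]a)]),",
  "$([OX2;+0]),",
  "$([OX1;$([OX1]=[#6,#16])])]")

#' Topological pharmacophore feature profile
#'
#' @param mol a \code{capa_molecule} or a SMILES string.
#' @param min_cluster minimum number of carbons for an aliphatic cluster to
#'   count as hydrophobic (default 3).
#' @return object of class \code{capa_features}: \code{aromatic_groups},
#'   \code{hydrophobic_groups} (aliphatic clusters),
#'   \code{hydrophobic_aromatic_groups} (carbocyclic aromatic systems, a
#'   subset of the aromatic groups that may also serve hydrophobic slots),
#'   \code{acceptor_atoms}.
#' @examples
#' \donttest{
#' feature_profile("c1ccccc1")       # 1 aromatic (dual-typed), 0 acceptors
#' }
#' @export
feature_profile <- function(mol, min_cluster = 3L) {
  smi <- if (inherits(mol, "capa_molecule")) mol$canonical_key
         else parse_structure(mol)$canonical_key
  g <- .mol_graph(smi)
  n <- nrow(g$atoms)

  # aromatic ring systems: components over aromatic bonds
  arom_bonds <- g$bonds[g$bonds$aromatic, , drop = FALSE]
  arom_atoms <- which(g$atoms$aromatic)
  arom_sys <- .components(arom_atoms, arom_bonds)
  dual <- vapply(arom_sys, function(m) all(g$atoms$element[m] == "C"),
                 logical(1))

  # hydrophobic clusters: non-ring aliphatic carbons
  on_ring <- .ring_atoms(n, g$bonds)
  halogens <- c("F", "Cl", "Br", "I")
  hyd_atoms <- which(g$atoms$element == "C" & !g$atoms$aromatic & !on_ring)
  hyd_bonds <- g$bonds[g$bonds$a1 %in% hyd_atoms & g$bonds$a2 %in% hyd_atoms, ,
                       drop = FALSE]
  clusters <- .components(hyd_atoms, hyd_bonds)
  adj <- .adjacency(n, g$bonds)
  qualifies <- vapply(clusters, function(m) {
    if (length(m) >= min_cluster) return(TRUE)
    any(vapply(m, function(a) {
      any(g$atoms$element[adj[[a]]] %in% halogens)
    }, logical(1)))
  }, logical(1))

  acc <- .match_counts(.mol_refs(smi), .acceptor_smarts)

  structure(list(aromatic_groups = length(arom_sys),
                 hydrophobic_groups = sum(qualifies),
                 hydrophobic_aromatic_groups = sum(dual),
                 acceptor_atoms = acc),
            class = "capa_features")
}

#' @export
print.capa_features <- function(x, ...) {
  cat("<feature profile> aromatic: ", x$aromatic_groups,
      " (", x$hydrophobic_aromatic_groups, " also hydrophobic), ",
      "hydrophobic clusters: ", x$hydrophobic_groups,
      ", acceptors: ", x$acceptor_atoms, "\n", sep = "")
  invisible(x)
}

#' The two five-feature pharmacophore models
#'
#' \code{"multitarget"}: four aromatic/hydrophobic slots plus one acceptor
#' slot. \code{"abcc1"}: one aromatic, two aromatic/hydrophobic, one
#' hydrophobic and one acceptor slot.
#'
#' @param name \code{"multitarget"} or \code{"abcc1"}.
#' @return object of class \code{capa_model}: list of slot type sets.
#' @export
pharmacophore_model <- function(name = c("multitarget", "abcc1")) {
  name <- match.arg(name)
  slots <- switch(name,
    multitarget = c(rep(list(c("aromatic", "hydrophobic")), 4L),
                    list("acceptor")),
    abcc1 = c(list("aromatic"),
              rep(list(c("aromatic", "hydrophobic")), 2L),
              list("hydrophobic"), list("acceptor")))
  structure(list(name = name, slots = slots), class = "capa_model")
}

# Feature group instances from a profile: each group carries the slot types
# it can serve.
.feature_groups <- function(profile) {
  n_dual <- profile$hydrophobic_aromatic_groups
  n_ar_only <- profile$aromatic_groups - n_dual
  groups <- c(
    rep(list("aromatic"), max(n_ar_only, 0L)),
    rep(list(c("aromatic", "hydrophobic")), n_dual),
    rep(list("hydrophobic"), profile$hydrophobic_groups),
    rep(list("acceptor"), profile$acceptor_atoms)
  )
  groups
}

# Maximum bipartite matching (Kuhn's augmenting paths) between groups and
# slots; sizes here are tiny (<= a few dozen groups, 5 slots).
.max_assignment <- function(groups, slots) {
  ns <- length(slots)
  match_slot <- rep(NA_integer_, ns)
  can <- function(gi, si) length(intersect(groups[[gi]], slots[[si]])) > 0L
  n <- 0L
  for (gi in seq_along(groups)) {
    seen <- rep(FALSE, ns)
    aug <- function(g) {
      for (si in seq_len(ns)) {
        if (!seen[si] && can(g, si)) {
          seen[si] <<- TRUE
          if (is.na(match_slot[si]) || aug(match_slot[si])) {
            match_slot[si] <<- g
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (aug(gi)) n <- n + 1L
  }
  n
}

#' Slot coverage of a pharmacophore model
#'
#' Maximum number of model slots that can be filled by distinct molecular
#' feature groups whose type is allowed by the slot; each group fills at most
#' one slot (maximum bipartite assignment).
#'
#' @param profile a \code{capa_features} profile.
#' @param model a \code{capa_model}.
#' @return integer between 0 and the number of slots.
#' @export
coverage_check <- function(profile, model) {
  stopifnot(inherits(profile, "capa_features"), inherits(model, "capa_model"))
  .max_assignment(.feature_groups(profile), model$slots)
}
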