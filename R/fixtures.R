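# Packaged candidate fixtures and the seeded synthetic decoy-library
# generator with planted ground truth.
#
# The generator assembles molecules from a pool of pattern-free decoy
# scaffolds (verified clean against every screening-relevant pattern at build
# time), attaching exemplar fragments of registry patterns at open aromatic
# positions. Everything planted is recorded, so the entire cascade can be
# validated against exact ground truth without external data.

#' The ten purchased candidate compounds
#'
#' Identifiers, names, vendor metadata, SMILES, the published per-target
#' IC50 values where printed (compound 23: 4.01 / 14.8 / 9.27 µM against
#' ABCB1 / ABCC1 / ABCG2) and the 10 µM screening activity calls.
#'
#' @return data.frame with one row per candidate (ids 16-25).
#' @export
published_candidates <- function() {
  path <- system.file("extdata", "capa12_candidates.csv",
                      package = "capascreen", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE, colClasses = c(id = "character"))
}

# Decoy scaffolds: two substituent slots each; with empty slots they match no
# clear-negative and no positive-role pattern of the shipped registry (the
# generator self-checks this).
.decoy_scaffolds <- c(
  "Cc1cc%scc%sc1",
  "CCc1cc%scc%sc1",
  "CCCc1cc%scc%sc1",
  "Fc1cc%scc%sc1",
  "Clc1cc%scc%sc1",
  "CC(=O)c1cc%scc%sc1",
  "CC(=O)Nc1cc%scc%sc1",
  "NC(=O)c1cc%scc%sc1"
)

# Plantable fragments, written as substituent branches for an aromatic
# position; ring-closure digits 8/9 avoid collision with the scaffold.
.plant_fragments <- list(
  positive = c(
    piperazine = "N8CCNCC8",
    morpholine = "N8CCOCC8",
    piperidine = "N8CCCCC8",
    pyrrolidine = "N8CCCC8",
    imidazole = "n8ccnc8",
    pyrazole = "n8nccc8",
    isoxazole = "c8cc(C)on8",
    thiophene = "c8cccs8",
    pyrimidine = "c8ncccn8"
  ),
  negative = c(
    nitro = "[N+](=O)[O-]",
    dimethylamino = "N(C)C",
    `tert-butyl` = "C(C)(C)C",
    urea = "NC(=O)NC"
  )
)

#' Names of patterns the generator can plant
#' @return list with \code{positive} and \code{negative} name vectors.
#' @export
plantable_patterns <- function() {
  lapply(.plant_fragments, names)
}

#' Synthetic library configuration
#'
#' @param n_molecules library size (including stereo duplicates).
#' @param seed RNG seed; identical configs yield byte-identical libraries.
#' @param plant_rates named probabilities over plantable positive patterns;
#'   default plants piperazine, imidazole, isoxazole and morpholine.
#' @param stereo_pair_count number of stereoisomer duplicate pairs to plant.
#' @param negative_violation_rate probability a molecule receives a planted
#'   clear-negative fragment.
#' @param class_probs probabilities over activity classes 0-7 used to sample
#'   IC50 profiles.
#' @param active_range,inactive_range log-uniform IC50 ranges (µM) for
#'   active / inactive targets, straddling the 10 µM threshold.
#' @return list of class \code{plant_config}.
#' @export
plant_config <- function(n_molecules = 120L,
                         seed = 1L,
                         plant_rates = c(piperazine = 0.4, imidazole = 0.3,
                                         isoxazole = 0.2, morpholine = 0.3),
                         stereo_pair_count = 10L,
                         negative_violation_rate = 0.25,
                         class_probs = c(0.35, 0.1, 0.1, 0.1,
                                         0.08, 0.08, 0.08, 0.11),
                         active_range = c(0.2, 9),
                         inactive_range = c(12, 95)) {
  if (any(plant_rates < 0 | plant_rates > 1)) {
    stop("plant_rates must be probabilities in [0, 1]")
  }
  unknown <- setdiff(names(plant_rates), names(.plant_fragments$positive))
  if (length(unknown)) {
    stop("unknown plantable pattern name(s): ",
         paste(unknown, collapse = ", "))
  }
  if (negative_violation_rate < 0 || negative_violation_rate > 1) {
    stop("negative_violation_rate must lie in [0, 1]")
  }
  if (n_molecules < 2L * stereo_pair_count) {
    stop("n_molecules must be at least twice stereo_pair_count")
  }
  stopifnot(length(class_probs) == 8L, all(class_probs >= 0))
  structure(list(n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed),
                 plant_rates = plant_rates,
                 stereo_pair_count = as.integer(stereo_pair_count),
                 negative_violation_rate = negative_violation_rate,
                 class_probs = class_probs / sum(class_probs),
                 active_range = active_range,
                 inactive_range = inactive_range),
            class = "plant_config")
}

.sample_ic50 <- function(active, cfg) {
  rng <- if (active) cfg$active_range else cfg$inactive_range
  exp(runif(1, log(rng[1]), log(rng[2])))
}

#' Generate a seeded synthetic decoy library with planted ground truth
#'
#' @param config a \code{plant_config}.
#' @return list with \code{molecules} (a \code{capa_mols} table including
#'   \code{abcb1_ic50_um}/\code{abcc1_ic50_um}/\code{abcg2_ic50_um} columns)
#'   and \code{ground_truth}: per-molecule planted positive and negative
#'   pattern names, stereo duplicate pairs (data.frame id, duplicate_of) and
#'   sampled class indices.
#' @export
generate_library <- function(config = plant_config()) {
  stopifnot(inherits(config, "plant_config"))
  set.seed(config$seed)
  n_base <- config$n_molecules - config$stereo_pair_count
  pos_names <- names(config$plant_rates)
  neg_pool <- names(.plant_fragments$negative)

  smiles <- character(n_base)
  keys <- character(n_base)
  planted_pos <- vector("list", n_base)
  planted_neg <- vector("list", n_base)
  stereo_base <- sort(sample.int(n_base, config$stereo_pair_count))
  # the stereo tail bonds to the scaffold's first atom, which must be carbon
  c_lead <- .decoy_scaffolds[substr(.decoy_scaffolds, 1L, 1L) == "C"]

  for (i in seq_len(n_base)) {
    placed <- FALSE
    for (attempt in 1:50) {
      pool <- if (i %in% stereo_base) c_lead else .decoy_scaffolds
      scaf <- sample(pool, 1L)
      neg <- if (runif(1) < config$negative_violation_rate)
        sample(neg_pool, 1L) else character(0)
      pos <- pos_names[runif(length(pos_names)) < config$plant_rates]
      max_pos <- 2L - length(neg)
      if (length(pos) > max_pos) pos <- sample(pos, max_pos)
      frags <- c(.plant_fragments$positive[pos],
                 .plant_fragments$negative[neg])
      # a single fragment is sometimes planted at both open positions, which
      # widens the space of distinct constitutions without changing the
      # planted pattern set
      if (length(frags) == 1L && runif(1) < 0.5) frags <- rep(frags, 2L)
      slots <- c(if (length(frags) >= 1L) paste0("(", frags[1L], ")") else "",
                 if (length(frags) >= 2L) paste0("(", frags[2L], ")") else "")
      smi <- sprintf(scaf, slots[1L], slots[2L])
      if (i %in% stereo_base) smi <- paste0("CC[C@H](O)", smi)
      key <- .ob_canonical(.strip_stereo_text(smi))
      if (nzchar(key) && !(key %in% keys)) {
        smiles[i] <- smi
        keys[i] <- key
        planted_pos[[i]] <- pos
        planted_neg[[i]] <- neg
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("fragment planting failed for molecule ", i,
                      " (could not build a unique valid structure)")
  }

  ids <- sprintf("syn%03d", seq_len(n_base))
  dup_smiles <- sub("[C@H]", "[C@@H]", smiles[stereo_base], fixed = TRUE)
  dup_ids <- sprintf("syn%03d_dup", stereo_base)

  all_smiles <- c(smiles, dup_smiles)
  all_ids <- c(ids, dup_ids)
  mols <- parse_structures(all_smiles, all_ids, on_error = "stop")

  # planted-truth self-check: every planted fragment must match its pattern,
  # and no unplanted enforced negative may appear
  lib <- default_library()
  gt_pos <- c(planted_pos, planted_pos[stereo_base])
  gt_neg <- c(planted_neg, planted_neg[stereo_base])
  check <- match_matrix(mols, lib,
                        roles = c(positive_roles(), "clear_negative"))
  pos_all <- .role_patterns(lib, positive_roles())$name
  neg_all <- lib$patterns$name[lib$patterns$role == "clear_negative"]
  for (k in seq_len(nrow(mols))) {
    want <- c(gt_pos[[k]], gt_neg[[k]])
    got <- colnames(check)[check[k, ] > 0L]
    if (!all(want %in% got)) {
      stop("self-check failed: planted pattern not matched in ",
           mols$id[k], " (", mols$smiles[k], ")")
    }
    extra_neg <- setdiff(intersect(got, neg_all),
                         c(gt_neg[[k]], lib$overrules))
    extra_pos <- setdiff(intersect(got, pos_all), gt_pos[[k]])
    if (length(extra_neg) || length(extra_pos)) {
      stop("self-check failed: unplanned pattern match (",
           paste(c(extra_neg, extra_pos), collapse = ","), ") in ",
           mols$id[k])
    }
  }

  # activity profiles per base molecule; stereo duplicates inherit them
  classes_base <- sample(0:7, n_base, replace = TRUE,
                         prob = config$class_probs)
  prof <- t(vapply(classes_base, function(cl) {
    act <- .class_map[[as.character(cl)]]
    c(abcb1 = .sample_ic50("ABCB1" %in% act, config),
      abcc1 = .sample_ic50("ABCC1" %in% act, config),
      abcg2 = .sample_ic50("ABCG2" %in% act, config))
  }, c(abcb1 = 0, abcc1 = 0, abcg2 = 0)))
  classes <- c(classes_base, classes_base[stereo_base])
  prof <- rbind(prof, prof[stereo_base, , drop = FALSE])

  ord <- match(mols$id, all_ids)
  mols$abcb1_ic50_um <- prof[ord, "abcb1"]
  mols$abcc1_ic50_um <- prof[ord, "abcc1"]
  mols$abcg2_ic50_um <- prof[ord, "abcg2"]

  list(
    molecules = mols,
    ground_truth = list(
      planted_positive = setNames(gt_pos[ord], mols$id),
      planted_negative = setNames(gt_neg[ord], mols$id),
      stereo_pairs = data.frame(id = dup_ids,
                                duplicate_of = ids[stereo_base],
                                stringsAsFactors = FALSE),
      class_index = setNames(classes[ord], mols$id),
      seed = config$seed
    )
  )
}
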