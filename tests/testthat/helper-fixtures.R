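# Shared fixtures, built once per test run.

lib_default <- default_library()

candidate_table <- published_candidates()
candidate_mols <- parse_structures(candidate_table$smiles, candidate_table$id)

# one moderately sized synthetic library reused by several files
syn_config <- plant_config(n_molecules = 60L, stereo_pair_count = 5L,
                           seed = 11L)
syn <- generate_library(syn_config)

# brute-force oracle for candidate ranking: repeatedly extract the maximum
# (count desc, id asc) from the passed records
rank_oracle <- function(report, top_k) {
  rec <- report$records
  rec <- rec[!is.na(rec$negative_passed) & rec$negative_passed, , drop = FALSE]
  ids <- rec$id
  counts <- rec$distinct_positive_count
  out <- character(0)
  while (length(ids) && length(out) < top_k) {
    best <- which(counts == max(counts))
    pick <- best[order(ids[best])[1]]
    out <- c(out, ids[pick])
    ids <- ids[-pick]; counts <- counts[-pick]
  }
  out
}

# brute-force oracle for slot coverage: enumerate all injective assignments
# of feature groups to slots (feasible for <= 6 groups, 5 slots)
coverage_oracle <- function(groups, slots) {
  ng <- length(groups); ns <- length(slots)
  if (ng == 0L || ns == 0L) return(0L)
  best <- 0L
  assign_next <- function(gi, used, filled) {
    if (filled > best) best <<- filled
    if (gi > ng) return(invisible())
    # skip this group
    assign_next(gi + 1L, used, filled)
    for (si in seq_len(ns)) {
      if (!used[si] && length(intersect(groups[[gi]], slots[[si]]))) {
        used[si] <- TRUE
        assign_next(gi + 1L, used, filled + 1L)
        used[si] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, ns), 0L)
  best
}

feature_groups_of <- function(profile) {
  c(rep(list("aromatic"),
        profile$aromatic_groups - profile$hydrophobic_aromatic_groups),
    rep(list(c("aromatic", "hydrophobic")),
        profile$hydrophobic_aromatic_groups),
    rep(list("hydrophobic"), profile$hydrophobic_groups),
    rep(list("acceptor"), profile$acceptor_atoms))
}
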