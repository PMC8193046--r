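# Activity class 0-7 assignment from per-target IC50 profiles and per-class
# substructure occurrence statistics.
#
# Boundary convention: a target is active iff IC50 < threshold (strictly);
# an IC50 at or above the threshold is inactive. Censored values ">X" with
# X >= threshold are inactive; ">X" with X < threshold is contradictory and
# rejected. The class index encodes the active-target subset:
#   0 none; 1 ABCB1; 2 ABCC1; 3 ABCG2; 4 ABCB1+ABCC1; 5 ABCB1+ABCG2;
#   6 ABCC1+ABCG2; 7 all three.

.targets <- c("ABCB1", "ABCC1", "ABCG2")

.class_map <- list(`0` = character(0),
                   `1` = "ABCB1", `2` = "ABCC1", `3` = "ABCG2",
                   `4` = c("ABCB1", "ABCC1"),
                   `5` = c("ABCB1", "ABCG2"),
                   `6` = c("ABCC1", "ABCG2"),
                   `7` = c("ABCB1", "ABCC1", "ABCG2"))

#' Parse an IC50 cell
#'
#' @param x numeric, or character possibly of the form \code{">X"} (censored
#'   above X) or blank/NA (not measured).
#' @return list(value, censored, missing).
#' @export
parse_ic50 <- function(x) {
  if (is.numeric(x)) {
    if (is.na(x)) return(list(value = NA_real_, censored = FALSE, missing = TRUE))
    if (x <= 0) stop("IC50 values must be positive, got ", x)
    return(list(value = x, censored = FALSE, missing = FALSE))
  }
  x <- trimws(as.character(x))
  if (is.na(x) || !nzchar(x)) {
    return(list(value = NA_real_, censored = FALSE, missing = TRUE))
  }
  censored <- startsWith(x, ">")
  val <- suppressWarnings(as.numeric(sub("^>", "", x)))
  if (is.na(val)) stop("unparsable IC50 value: '", x, "'")
  if (val <= 0) stop("IC50 values must be positive, got ", x)
  list(value = val, censored = censored, missing = FALSE)
}

#' Assign an activity class from a per-target IC50 profile
#'
#' @param abcb1,abcc1,abcg2 IC50 in micromolar; numeric, \code{">X"}
#'   censored-above strings, or NA (not measured).
#' @param threshold_um activity threshold in micromolar (default 10): active
#'   strictly below, inactive at or above.
#' @return list of class \code{capa_class}: \code{class_index} (0-7),
#'   \code{active_targets}, \code{provisional} (TRUE when any target is
#'   unmeasured, so the label is a lower bound).
#' @examples
#' \donttest{
#' assign_class(4.01, 14.8, 9.27)   # active ABCB1 + ABCG2, class 5, not 7
#' }
#' @export
assign_class <- function(abcb1, abcc1, abcg2, threshold_um = 10) {
  stopifnot(is.numeric(threshold_um), threshold_um > 0)
  vals <- list(ABCB1 = parse_ic50(abcb1), ABCC1 = parse_ic50(abcc1),
               ABCG2 = parse_ic50(abcg2))
  if (all(vapply(vals, `[[`, logical(1), "missing"))) {
    stop("unclassifiable profile: no target measured")
  }
  active <- character(0)
  provisional <- FALSE
  for (t in .targets) {
    v <- vals[[t]]
    if (v$missing) { provisional <- TRUE; next }
    if (v$censored) {
      if (v$value < threshold_um) {
        stop("contradictory censoring for ", t, ": '>", v$value,
             "' with threshold ", threshold_um)
      }
      next  # censored above the threshold: inactive
    }
    if (v$value < threshold_um) active <- c(active, t)
  }
  idx <- which(vapply(.class_map, function(s) setequal(s, active), logical(1)))
  structure(list(class_index = as.integer(names(.class_map)[idx]),
                 active_targets = active, provisional = provisional),
            class = "capa_class")
}

#' @export
print.capa_class <- function(x, ...) {
  cat("class ", x$class_index,
      if (length(x$active_targets))
        paste0(" (", paste(x$active_targets, collapse = "+"), ")")
      else " (inactive)",
      if (x$provisional) " [provisional]", "\n", sep = "")
  invisible(x)
}

#' Classify a profile table
#'
#' Vectorised \code{\link{assign_class}} over a data.frame with columns
#' \code{abcb1_ic50_um}, \code{abcc1_ic50_um}, \code{abcg2_ic50_um} (and
#' optionally \code{id}). Records that fail to classify are collected, not
#' fatal.
#'
#' @param profiles data.frame of IC50 columns.
#' @param threshold_um activity threshold (µM).
#' @return data.frame with \code{id}, \code{class_index}, \code{active_targets}
#'   (collapsed with "+"), \code{provisional}; failed rows carry NA class and
#'   the error in \code{note}.
#' @export
classify_profiles <- function(profiles, threshold_um = 10) {
  ids <- if ("id" %in% names(profiles)) as.character(profiles$id)
         else paste0("row", seq_len(nrow(profiles)))
  n <- nrow(profiles)
  out <- data.frame(id = ids, class_index = rep(NA_integer_, n),
                    active_targets = rep(NA_character_, n),
                    provisional = rep(NA, n),
                    note = rep("", n), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(profiles))) {
    res <- tryCatch(
      assign_class(profiles$abcb1_ic50_um[i], profiles$abcc1_ic50_um[i],
                   profiles$abcg2_ic50_um[i], threshold_um),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$note[i] <- conditionMessage(res)
    } else {
      out$class_index[i] <- res$class_index
      out$active_targets[i] <- paste(res$active_targets, collapse = "+")
      out$provisional[i] <- res$provisional
    }
  }
  out
}

#' Per-class substructure occurrence table
#'
#' Counts, for every pattern and activity class, the number of molecules of
#' that class containing the pattern (presence/absence, not embedding
#' counts).
#'
#' @param mols a \code{capa_mols} table.
#' @param profiles data.frame of IC50 columns aligned with \code{mols} by
#'   \code{id} (or by position if no id column).
#' @param lib a \code{capa_library}.
#' @param roles pattern roles to tabulate; default all.
#' @param threshold_um activity threshold (µM).
#' @return list with \code{table} (integer matrix patterns x classes 0-7),
#'   \code{class_sizes} (integer vector length 8) and \code{skipped}
#'   (ids of unclassifiable records).
#' @export
class_distribution <- function(mols, profiles, lib, roles = pattern_roles(),
                               threshold_um = 10) {
  cls <- classify_profiles(profiles, threshold_um)
  if ("id" %in% names(profiles)) {
    cls <- cls[match(mols$id, cls$id), , drop = FALSE]
  } else {
    stopifnot(nrow(profiles) == nrow(mols))
  }
  ok <- !is.na(cls$class_index)
  M <- match_matrix(mols[ok, , drop = FALSE], lib, roles)
  classes <- cls$class_index[ok]
  tab <- matrix(0L, ncol(M), 8L,
                dimnames = list(colnames(M), as.character(0:7)))
  for (c in 0:7) {
    sel <- classes == c
    if (any(sel)) tab[, c + 1L] <- colSums(M[sel, , drop = FALSE] > 0L)
  }
  sizes <- vapply(0:7, function(c) sum(classes == c), integer(1))
  names(sizes) <- as.character(0:7)
  list(table = tab, class_sizes = sizes, skipped = mols$id[!ok])
}

#' Flag candidate positive/negative patterns from an occurrence table
#'
#' A pattern is a positive candidate when it occurs in at least
#' \code{min_class7_frac} of class 7 molecules and in at most
#' \code{max_other_frac} of classes 0-6 (pooled); the negative flag mirrors
#' the rule. The two output sets are disjoint by construction.
#'
#' @param table occurrence matrix (patterns x classes 0-7).
#' @param class_sizes integer vector of class sizes (length 8).
#' @param min_class7_frac,max_other_frac positive-flag thresholds in [0, 1].
#' @return list(positive_candidates, negative_candidates, rules).
#' @export
flag_hits <- function(table, class_sizes, min_class7_frac = 0.5,
                      max_other_frac = 0.1) {
  if (min_class7_frac < 0 || min_class7_frac > 1 ||
      max_other_frac < 0 || max_other_frac > 1) {
    stop("flag thresholds must lie in [0, 1]")
  }
  stopifnot(ncol(table) == 8L, length(class_sizes) == 8L)
  n7 <- class_sizes[8L]
  n_other <- sum(class_sizes[1:7])
  f7 <- if (n7 > 0) table[, 8L] / n7 else rep(0, nrow(table))
  fo <- if (n_other > 0) rowSums(table[, 1:7, drop = FALSE]) / n_other
        else rep(0, nrow(table))
  pos <- rownames(table)[f7 >= min_class7_frac & fo <= max_other_frac]
  neg <- rownames(table)[fo >= min_class7_frac & f7 <= max_other_frac]
  neg <- setdiff(neg, pos)
  list(positive_candidates = pos, negative_candidates = neg,
       rules = list(min_class7_frac = min_class7_frac,
                    max_other_frac = max_other_frac))
}
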