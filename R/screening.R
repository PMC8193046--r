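# The end-to-end screening cascade: stereoisomer deduplication, negative
# pattern exclusion (with overrules), extended positive-hit profiling,
# hit-count distribution and ranked candidate report. Stage order is fixed;
# each molecule appears exactly once in the report records.

#' Screening run configuration
#'
#' All knobs of the cascade, made explicit so every report can embed the
#' effective configuration.
#'
#' @param overrules clear-negative names whose exclusion is suspended.
#' @param positive_roles_used roles counted in the positive-hit profile. The
#'   default follows the compiled 28-pattern positive list (clear +
#'   secondary + potential); restrict to
#'   \code{c("secondary_positive", "potential_positive")} for the 20
#'   extended-only patterns.
#' @param threshold_um IC50 activity threshold (µM) for classification steps.
#' @param min_class7_frac,max_other_frac flagging rule thresholds.
#' @param top_k default number of ranked candidates to report.
#' @param seed optional integer recorded for provenance.
#' @return list of class \code{capa_config}.
#' @export
run_config <- function(overrules = c("pyrrolidine", "oxazole"),
                       positive_roles_used = positive_roles(),
                       threshold_um = 10,
                       min_class7_frac = 0.5,
                       max_other_frac = 0.1,
                       top_k = 10L,
                       seed = NULL) {
  stopifnot(all(positive_roles_used %in% pattern_roles()))
  if (top_k < 0) stop("top_k must be non-negative")
  structure(list(overrules = overrules,
                 positive_roles_used = positive_roles_used,
                 threshold_um = threshold_um,
                 min_class7_frac = min_class7_frac,
                 max_other_frac = max_other_frac,
                 top_k = as.integer(top_k),
                 seed = seed),
            class = "capa_config")
}

#' Run the screening cascade
#'
#' Dedup, then negative exclusion on the unique set, then positive-hit
#' profiling on the survivors. Deterministic for fixed inputs and config.
#'
#' @param mols a \code{capa_mols} table (its \code{rejects} attribute, if
#'   any, is carried into the report).
#' @param lib a \code{capa_library}.
#' @param config a \code{capa_config}; defaults to \code{run_config()}.
#' @return object of class \code{capa_screen}: list with \code{records}
#'   (one row per input molecule: id, dedup_status, duplicate_of,
#'   negative_passed, negative_violations, positive_hits,
#'   distinct_positive_count), \code{counts} (input, unique,
#'   passed_negative, with_positive), \code{histogram} (table of
#'   distinct-positive-hit counts >= 1 over negative-passed records),
#'   \code{n_zero_positive}, \code{rejects}, \code{config},
#'   \code{library_version}.
#' @export
run_screen <- function(mols, lib, config = run_config()) {
  stopifnot(inherits(lib, "capa_library"), inherits(config, "capa_config"))
  rejects <- attr(mols, "rejects")
  if (is.null(rejects)) {
    rejects <- data.frame(id = character(0), smiles = character(0),
                          reason = character(0), stringsAsFactors = FALSE)
  }
  n <- nrow(mols)
  rec <- data.frame(id = mols$id, dedup_status = rep("kept", n),
                    duplicate_of = rep(NA_character_, n),
                    negative_passed = rep(NA, n), stringsAsFactors = FALSE)
  rec$negative_violations <- vector("list", n)
  rec$positive_hits <- vector("list", n)
  rec$distinct_positive_count <- rep(NA_integer_, n)

  dd <- deduplicate_stereoisomers(mols)
  if (nrow(dd$removed)) {
    i <- match(dd$removed$id, rec$id)
    rec$dedup_status[i] <- "removed"
    rec$duplicate_of[i] <- dd$removed$duplicate_of
  }

  uni <- dd$unique
  nf <- negative_filter(uni, lib, overrules = config$overrules)
  i <- match(nf$id, rec$id)
  rec$negative_passed[i] <- nf$passed
  rec$negative_violations[i] <- nf$violations

  surv <- uni[nf$passed, , drop = FALSE]
  if (nrow(surv)) {
    pp <- positive_hit_profile(surv, lib, roles = config$positive_roles_used)
    j <- match(pp$id, rec$id)
    rec$positive_hits[j] <- pp$hit_names
    rec$distinct_positive_count[j] <- pp$distinct_count
    counts_pos <- pp$distinct_count
  } else {
    counts_pos <- integer(0)
  }

  hist_tab <- table(factor(counts_pos[counts_pos > 0L]))
  structure(list(
    records = rec,
    counts = c(input = nrow(mols), unique = nrow(uni),
               passed_negative = nrow(surv),
               with_positive = sum(counts_pos > 0L)),
    histogram = hist_tab,
    n_zero_positive = sum(counts_pos == 0L),
    rejects = rejects,
    config = config,
    library_version = lib$version
  ), class = "capa_screen")
}

#' @export
print.capa_screen <- function(x, ...) {
  cat("<screening report> library ", x$library_version, "\n", sep = "")
  cat("  input: ", x$counts["input"],
      "  unique: ", x$counts["unique"],
      "  passed negative filter: ", x$counts["passed_negative"],
      "  with >=1 positive hit: ", x$counts["with_positive"], "\n", sep = "")
  if (length(x$histogram)) {
    cat("  distinct positive-hit distribution:\n")
    for (k in names(x$histogram)) {
      cat("    ", k, " hit(s): ", x$histogram[[k]], " molecule(s)\n", sep = "")
    }
  }
  if (x$n_zero_positive > 0) {
    cat("  without positive hit: ", x$n_zero_positive, "\n", sep = "")
  }
  if (nrow(x$rejects)) cat("  rejects: ", nrow(x$rejects), "\n", sep = "")
  invisible(x)
}

#' Rank screening candidates
#'
#' Negative-passed records sorted by distinct positive-hit count
#' (descending), ties broken lexicographically by id. The report surfaces
#' which patterns matched ("manner" of hits) for human review; the automated
#' ranking uses the number only.
#'
#' @param report a \code{capa_screen}.
#' @param top_k number of ids to return.
#' @return character vector of molecule ids.
#' @export
rank_candidates <- function(report, top_k = report$config$top_k) {
  stopifnot(inherits(report, "capa_screen"))
  if (top_k < 0) stop("top_k must be non-negative")
  rec <- report$records
  rec <- rec[!is.na(rec$negative_passed) & rec$negative_passed, , drop = FALSE]
  ord <- order(-rec$distinct_positive_count, rec$id, method = "radix")
  head(rec$id[ord], top_k)
}

#' Write a screening report as JSON
#'
#' The JSON embeds the effective configuration and registry version
#' (reproducibility contract) alongside per-record outcomes.
#'
#' @param report a \code{capa_screen}.
#' @param path output path.
#' @export
write_screening_report <- function(report, path) {
  stopifnot(inherits(report, "capa_screen"))
  rec <- report$records
  out <- list(
    schema = "capa-screen-report/1",
    library_version = report$library_version,
    config = unclass(report$config),
    counts = as.list(report$counts),
    histogram = as.list(report$histogram),
    n_zero_positive = report$n_zero_positive,
    records = lapply(seq_len(nrow(rec)), function(i) {
      list(id = rec$id[i],
           dedup_status = rec$dedup_status[i],
           duplicate_of = rec$duplicate_of[i],
           negative_passed = rec$negative_passed[i],
           negative_violations = rec$negative_violations[[i]],
           positive_hits = rec$positive_hits[[i]],
           distinct_positive_count = rec$distinct_positive_count[i])
    }),
    rejects = report$rejects
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Screening records as a flat table
#'
#' @param report a \code{capa_screen}.
#' @return data.frame, one row per molecule, list columns collapsed with ";".
#' @export
screening_records_tsv <- function(report) {
  rec <- report$records
  data.frame(
    id = rec$id,
    dedup_status = rec$dedup_status,
    duplicate_of = rec$duplicate_of,
    negative_passed = rec$negative_passed,
    negative_violations = vapply(rec$negative_violations, paste,
                                 "", collapse = ";"),
    positive_hits = vapply(rec$positive_hits, paste, "", collapse = ";"),
    distinct_positive_count = rec$distinct_positive_count,
    stringsAsFactors = FALSE
  )
}
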