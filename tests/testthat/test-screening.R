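test_that("the cascade reports every input exactly once with stage gating", {
  rep <- run_screen(syn$molecules, lib_default)
  rec <- rep$records
  expect_equal(nrow(rec), nrow(syn$molecules))
  expect_equal(sort(rec$id), sort(syn$molecules$id))
  # removed records carry no downstream fields
  rem <- rec[rec$dedup_status == "removed", ]
  expect_true(all(is.na(rem$negative_passed)))
  expect_true(all(is.na(rem$distinct_positive_count)))
  # negative-failed records carry no positive fields
  failed <- rec[!is.na(rec$negative_passed) & !rec$negative_passed, ]
  expect_true(all(is.na(failed$distinct_positive_count)))
  # stage counts non-increasing
  expect_true(rep$counts["input"] >= rep$counts["unique"])
  expect_true(rep$counts["unique"] >= rep$counts["passed_negative"])
  expect_true(rep$counts["passed_negative"] >= rep$counts["with_positive"])
  # histogram + zero-hit survivors account for all passed records
  expect_equal(sum(rep$histogram) + rep$n_zero_positive,
               unname(rep$counts["passed_negative"]))
})

test_that("cascade results equal planted ground truth exactly", {
  rep <- run_screen(syn$molecules, lib_default)
  gt <- syn$ground_truth
  expect_equal(unname(rep$counts["input"]), syn_config$n_molecules)
  expect_equal(unname(rep$counts["unique"]),
               syn_config$n_molecules - syn_config$stereo_pair_count)
  # negative failures = unique molecules with a planted negative
  dd <- deduplicate_stereoisomers(syn$molecules)
  planted_neg <- vapply(gt$planted_negative[dd$unique$id], length, 1L) > 0
  expect_equal(unname(rep$counts["passed_negative"]), sum(!planted_neg))
  # per-molecule positive hits = planted positives
  rec <- rep$records
  for (i in which(!is.na(rec$negative_passed) & rec$negative_passed)) {
    expect_setequal(rec$positive_hits[[i]],
                    gt$planted_positive[[rec$id[i]]])
  }
  # histogram equals the planted distinct-count distribution
  surv <- dd$unique$id[!planted_neg]
  want <- table(factor(lengths(gt$planted_positive[surv])))
  want <- want[names(want) != "0"]
  expect_equal(as.vector(rep$histogram), as.vector(want))
  # violations are exactly the planted negatives
  for (i in which(!is.na(rec$negative_passed) & !rec$negative_passed)) {
    expect_setequal(rec$negative_violations[[i]],
                    gt$planted_negative[[rec$id[i]]])
  }
})

test_that("the pipeline is deterministic and sensitive to overrules", {
  a <- run_screen(syn$molecules, lib_default)
  b <- run_screen(syn$molecules, lib_default)
  expect_identical(screening_records_tsv(a), screening_records_tsv(b))
  # shrinking the overrule set can only move records from passed to failed
  strict <- run_screen(syn$molecules, lib_default,
                       run_config(overrules = character(0)))
  rec_a <- a$records; rec_s <- strict$records
  passed_a <- rec_a$id[!is.na(rec_a$negative_passed) & rec_a$negative_passed]
  passed_s <- rec_s$id[!is.na(rec_s$negative_passed) & rec_s$negative_passed]
  expect_true(all(passed_s %in% passed_a))
})

test_that("ranking matches the brute-force oracle with lexicographic ties", {
  rep <- run_screen(syn$molecules, lib_default)
  for (k in c(0L, 3L, 10L, 1000L)) {
    expect_equal(rank_candidates(rep, k), rank_oracle(rep, k), info = k)
  }
  expect_error(rank_candidates(rep, -1), "non-negative")

  # stated tie-break on a constructed report
  toy <- rep
  toy$records <- data.frame(id = c("a", "b", "c"), dedup_status = "kept",
                            duplicate_of = NA, negative_passed = TRUE,
                            stringsAsFactors = FALSE)
  toy$records$negative_violations <- list(character(0), character(0),
                                          character(0))
  toy$records$positive_hits <- list("x", "y", "z")
  toy$records$distinct_positive_count <- c(3L, 1L, 3L)
  expect_equal(rank_candidates(toy, 3), c("a", "c", "b"))
})

test_that("empty input yields an empty report with zero counts", {
  empty <- syn$molecules[0, , drop = FALSE]
  class(empty) <- class(syn$molecules)
  rep <- run_screen(empty, lib_default)
  expect_equal(unname(rep$counts), rep(0L, 4))
  expect_equal(nrow(rep$records), 0L)
  expect_length(rank_candidates(rep, 5), 0)
})

test_that("reports embed configuration and serialise to JSON/TSV", {
  cfg <- run_config(top_k = 3L, seed = 99L)
  rep <- run_screen(candidate_mols, lib_default, cfg)
  expect_equal(rep$config$seed, 99L)
  expect_equal(rep$library_version, "capa-1.2")
  path <- tempfile(fileext = ".json")
  write_screening_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$library_version, "capa-1.2")
  expect_equal(parsed$config$overrules,
               list("pyrrolidine", "oxazole"))
  expect_length(parsed$records, 10)
  tsv <- screening_records_tsv(rep)
  expect_equal(nrow(tsv), 10L)
  expect_true(all(tsv$negative_passed))
})

test_that("unparsable records surface in the rejects section", {
  mols <- parse_structures(c("CCO", "C1CC"), c("ok", "bad"),
                           on_error = "reject")
  rep <- run_screen(mols, lib_default)
  expect_equal(rep$rejects$id, "bad")
  expect_equal(nrow(rep$records), 1L)
})
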