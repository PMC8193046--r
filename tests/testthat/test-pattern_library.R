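test_that("the shipped registry loads with the expected structure", {
  expect_s3_class(lib_default, "capa_library")
  expect_equal(lib_default$version, "capa-1.2")
  expect_setequal(lib_default$overrules, c("pyrrolidine", "oxazole"))
  # overrules are clear-negative names
  neg <- lib_default$patterns$name[lib_default$patterns$role == "clear_negative"]
  expect_true(all(lib_default$overrules %in% neg))
})

test_that("every pattern matches its exemplar and rejects its counter-exemplar", {
  chk <- validate_library(lib_default)
  expect_true(all(chk$ok),
              info = paste(chk$name[!chk$ok], collapse = ", "))
})

test_that("embedding counts follow the documented match semantics", {
  # tert-butyl: one symmetry-deduplicated embedding
  expect_equal(count_matches("tert-butyl", "CC(C)(C)c1ccccc1",
                             lib = lib_default), 1L)
  # ring fusion allowed: the pyridine inside quinoline/isoquinoline counts
  expect_gt(count_matches("pyridine", "c1ccc2ncccc2c1", lib = lib_default), 0L)
  # positional strictness: pyridine does not match a pyrimidine ring
  expect_equal(count_matches("pyridine", "c1ccncn1", lib = lib_default), 0L)
  # saturated ring queries reject aromatic rings
  expect_equal(count_matches("pyrrolidine", "c1cc[nH]c1", lib = lib_default), 0L)
  # methoxy needs the terminal methyl: aryl-O-CH2 bridges do not match
  expect_equal(count_matches("methoxy", "c1ccc2OCOc2c1", lib = lib_default), 0L)
})

test_that("matching is invariant under input-SMILES atom renumbering", {
  alt <- c("N1(c2ccccc2)CCNCC1", "c1ccccc1N1CCNCC1")
  mols <- parse_structures(alt, c("m1", "m2"))
  M <- match_matrix(mols, lib_default)
  expect_equal(unname(M[1, ]), unname(M[2, ]))
})

test_that("negative filter reports sorted enforced violations", {
  mols <- parse_structures(
    c("O=[N+]([O-])c1ccccc1", "CN1CCCC1", "CCN"),
    c("nitrobenzene", "nmp", "eta"))
  nf <- negative_filter(mols, lib_default)
  expect_false(nf$passed[1])
  expect_true("nitro" %in% nf$violations[[1]])
  # pyrrolidine is overruled by default ...
  expect_true(nf$passed[2])
  # ... but enforced when the overrule set is empty
  nf0 <- negative_filter(mols, lib_default, overrules = character(0))
  expect_false(nf0$passed[2])
  expect_true("pyrrolidine" %in% nf0$violations[[2]])
  expect_true(nf$passed[3])
  expect_equal(nf$violations[[1]], sort(nf$violations[[1]]))
})

test_that("negative filter is monotone in negatives and overrules", {
  mols <- syn$molecules
  base <- negative_filter(mols, lib_default)
  # removing overrules can only shrink the pass set
  strict <- negative_filter(mols, lib_default, overrules = character(0))
  expect_true(all(mols$id[strict$passed] %in% mols$id[base$passed]))
  # adding a clear negative can only shrink the pass set
  lib2 <- lib_default
  lib2$patterns <- rbind(lib2$patterns,
                         data.frame(name = "any benzene", smarts = "c1ccccc1",
                                    role = "clear_negative",
                                    provenance = "test", stringsAsFactors = FALSE))
  harsher <- negative_filter(mols, lib2)
  expect_true(all(mols$id[harsher$passed] %in% mols$id[base$passed]))
})

test_that("positive-hit profiling returns the requested roles only", {
  mols <- parse_structures(c("c1ccccc1", "CN1CCN(C)CC1"), c("benzene", "pip"))
  pp <- positive_hit_profile(mols, lib_default)
  expect_equal(pp$distinct_count[1], 0L)
  expect_equal(pp$hit_names[[2]], "piperazine")
  # extended-only restriction drops clear positives
  mor <- parse_structures("CN1CCOCC1", "mor")
  full <- positive_hit_profile(mor, lib_default)
  ext <- positive_hit_profile(mor, lib_default,
                              roles = c("secondary_positive",
                                        "potential_positive"))
  expect_true("morpholine" %in% full$hit_names[[1]])
  expect_false("morpholine" %in% ext$hit_names[[1]])
})

test_that("registry i/o round-trips and rejects corrupt entries", {
  tmp <- tempfile(fileext = ".tsv")
  write_pattern_registry(lib_default, tmp)
  lib2 <- read_pattern_registry(tmp, overrules = lib_default$overrules,
                                version = lib_default$version)
  expect_equal(lib2$patterns$smarts, lib_default$patterns$smarts)

  bad <- lib_default$patterns
  bad$smarts[3] <- "c1ccc(("
  badfile <- tempfile(fileext = ".tsv")
  write.table(bad, badfile, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_pattern_registry(badfile),
               bad$name[3], fixed = TRUE)
})
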