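test_that("ring specs are equal up to rotation and reflection", {
  a <- ring_spec(c("O", "N", "C", "C", "C"), TRUE)   # 1,2
  b <- ring_spec(c("N", "O", "C", "C", "C"), TRUE)   # reflected
  c3 <- ring_spec(c("C", "C", "O", "N", "C"), TRUE)  # rotated
  expect_equal(ring_name(a), "isoxazole")
  expect_equal(ring_name(b), "isoxazole")
  expect_equal(ring_name(c3), "isoxazole")
  expect_equal(ring_name(ring_spec(c("O", "C", "N", "C", "C"), TRUE)),
               "oxazole")
  expect_equal(ring_name(ring_spec(c("N", "C", "C", "N", "C", "C"), FALSE)),
               "piperazine")
})

test_that("scaffold fragmentation extracts monocyclic heteroaromatics", {
  frag <- fragment_scaffolds()
  expect_setequal(frag$name, c("pyrimidine", "pyrrole", "pyridine",
                               "thiophene"))
  # quinoline alone decomposes to pyridine; the benzo ring is discarded
  q <- fragment_scaffolds("c1ccc2ncccc2c1")
  expect_equal(q$name, "pyridine")
  # pure carbocycle contributes nothing
  expect_equal(nrow(fragment_scaffolds("c1ccccc1")), 0L)
  # acyclic input warns and contributes nothing
  expect_warning(none <- fragment_scaffolds("CCNCC"), "acyclic")
  expect_equal(nrow(none), 0L)
})

test_that("heterocyclic hopping derives the published saturated rings", {
  expect_setequal(hop_heterocycle()$name,
                  c("imidazolidine", "homo-piperidine", "pyrrolidine",
                    "homo-morpholine", "oxazolidine"))
  expect_setequal(hop_heterocycle("piperidine")$name,
                  c("homo-piperidine", "pyrrolidine"))
  expect_setequal(hop_heterocycle("morpholine")$name,
                  c("homo-morpholine", "oxazolidine"))
  expect_setequal(hop_heterocycle(c("piperazine", "homo-piperazine"))$name,
                  "imidazolidine")
  expect_warning(hop_heterocycle("pyridine"), "unsupported")
})

test_that("raw heterocyclic hopping conserves the heteroatom multiset and sizes", {
  for (p in c("piperazine", "piperidine", "morpholine")) {
    parent <- ring_spec(strsplit(c(piperazine = "N,C,C,N,C,C",
                                   piperidine = "N,C,C,C,C,C",
                                   morpholine = "O,C,C,N,C,C")[[p]], ",")[[1]],
                        FALSE)
    raw <- hop_heterocycle(p, raw = TRUE)
    for (i in seq_len(nrow(raw))) {
      # re-parse the generated SMARTS as a ring SMILES
      spec <- capascreen:::.resolve_ring(raw$smarts[i])
      expect_true(spec$size %in% c(5L, 7L))
      expect_equal(sort(spec$elements[spec$elements != "C"]),
                   sort(parent$elements[parent$elements != "C"]))
    }
  }
})

test_that("heteroaromatic hopping enumerates sub-multiset five-rings", {
  expect_setequal(hop_heteroaromatic()$name,
                  c("isoxazole", "oxazole", "imidazole", "furan", "thiazole",
                    "pyrazole", "thiophene"))
  expect_setequal(hop_heteroaromatic("1,2,4-oxadiazole")$name,
                  c("isoxazole", "oxazole", "furan", "imidazole", "pyrazole"))
  # the raw enumeration also contains the curated-out rings
  raw <- hop_heteroaromatic(raw = TRUE)
  expect_true(all(c("pyrrole", "isothiazole") %in% raw$name))
  # heteroatom sub-multiset property on the raw output
  for (i in seq_len(nrow(raw))) {
    spec <- capascreen:::.resolve_ring(raw$name[i])
    het <- spec$elements[spec$elements != "C"]
    expect_true(length(het) %in% 1:2)
    expect_true(all(het %in% c("O", "N", "S")))
  }
  expect_warning(hop_heteroaromatic("c1ccccc1"), "unsupported")
})

test_that("compilation dedups by ring identity and registers overrules", {
  res <- derive_potential_positives(lib_default)
  expect_equal(nrow(res$patterns), 15L)
  expect_equal(sum(res$patterns$name == "thiophene"), 1L)
  expect_true(all(c("pyrrolidine", "oxazole") %in% res$library$overrules))
  # regenerated set equals the shipped potential positives
  shipped <- lib_default$patterns$name[
    lib_default$patterns$role == "potential_positive"]
  expect_setequal(res$patterns$name, shipped)
})

test_that("compilation is order-independent and idempotent", {
  frag <- fragment_scaffolds()
  het <- hop_heterocycle()
  arom <- hop_heteroaromatic()
  a <- compile_potential_positive(frag, het, arom, lib_default)
  b <- compile_potential_positive(arom, frag, het, lib_default)
  expect_equal(a$patterns$name, b$patterns$name)
  c2 <- compile_potential_positive(a$patterns[0, ], a$patterns, a$patterns[0, ],
                                   a$library)
  expect_equal(c2$patterns$name, a$patterns$name)
  expect_equal(c2$library$overrules, a$library$overrules)
})

test_that("generated patterns parse and follow library ring semantics", {
  res <- derive_potential_positives(lib_default)
  probe <- parse_structures(c("CN1CCN(C)CC1", "Cn1ccnc1"), c("p", "i"))
  M <- match_matrix(probe, lib_default, roles = "potential_positive")
  expect_gt(M["i", "imidazole"], 0)
  # every generated SMARTS compiles and hits its own exemplar ring
  for (i in seq_len(nrow(res$patterns))) {
    expect_no_error(count_matches(res$patterns$smarts[i], "CN1CCN(C)CC1"))
  }
})
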