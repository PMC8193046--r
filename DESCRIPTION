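Package: capascreen
Title: Substructure Pattern Analysis for Multitarget ABC Transporter Inhibitor Screening
Version: 1.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computer-aided pattern analysis (C@PA) toolkit for the virtual
    screening of pan-ABC transporter (ABCB1/P-gp, ABCC1/MRP1, ABCG2/BCRP)
    inhibitors. Ships a curated, versioned SMARTS registry of positive and
    negative substructure patterns with explicit roles, scaffold fragmentation
    and substructure-hopping generators that derive the extended positive hit
    set, the stereoisomer-deduplication / negative-exclusion / positive-hit
    profiling screening cascade, activity class 0-7 assignment from per-target
    IC50 profiles with per-class substructure occurrence statistics, and a
    topological pharmacophore feature-coverage check. Includes a seeded
    synthetic decoy-library generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
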