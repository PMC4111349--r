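Package: itshybrid
Title: Diagnosing Hybrid Origin from Multi-Copy ITS rDNA Polymorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing hybrid origin and incomplete concerted
    evolution from intragenomic polymorphism of the nuclear ribosomal
    internal transcribed spacers (ITS1-5.8S-ITS2). Detects polymorphic
    sites under IUPAC ambiguity semantics, classifies hybrid additivity
    against parental ribotype pools, computes uncorrected p and Kimura
    2-parameter distances with ambiguity averaging, delimits ribotypes,
    builds statistical-parsimony haplotype networks and NeighborNet split
    networks with column-bootstrap supports, maps substitutions onto an
    RNA secondary-structure template (compensatory, hemi-compensatory and
    non-compensatory classification), screens clone libraries for
    putative non-functional (pseudogene) copies and PCR chimeras, and
    performs companion landmark geometric morphometrics of leaf shape
    (generalized Procrustes analysis, bilateral symmetrization, relative
    warps, permutation tests). A seeded synthetic-data module generates
    parental ribotype pools, dosage-weighted hybrid copy mixtures, clone
    libraries with planted artifacts, and landmark datasets so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    phangorn,
    stats,
    utils
Suggests:
    ape,
    vegan,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
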