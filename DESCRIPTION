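Package: quenchkit
Title: Design and Evaluation Toolkit for Nanobody Quenchbodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for designing and evaluating
    nanobody-based quenchbodies: fluorophore-tryptophan quench-distance
    statistics over structural trajectories (centre-of-mass distances,
    contact-time fractions under a photo-induced electron transfer
    cutoff), CDR tryptophan-engineering plans, trimer-codon randomised
    library construction, multi-round selection sequencing analysis with
    blank-control enrichment scoring, and plate-assay analysis
    (fold-sense, single-site Hill fits, ANOVA/Tukey detection limits,
    dye-labelling stoichiometry). Includes seeded synthetic-data
    generators for surrogate trajectories, selection reads and plate
    titrations so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    minpack.lm,
    jsonlite,
    optparse,
    graphics,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
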