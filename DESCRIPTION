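Package: idrsim
Title: Coarse-Grained Ensembles and Sequence Analytics for Intrinsically
    Disordered Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Residue-level coarse-grained simulation and analysis of
    intrinsically disordered protein regions (IDRs). Implements a
    one-bead-per-residue force field (Wang-Frenkel pair potential plus
    Debye-Hueckel screened electrostatics), a single-chain Langevin
    dynamics engine, ensemble observables (radius of gyration,
    end-to-end distance, asphericity, internal scaling exponent), a
    Gaussian-chain null model for normalized dimensions, synthetic IDR
    sequence design (composition, charge patterning, sticker-spacer
    constructs), proteome-scale sliding-window profiles with
    compact/expanded subregion calling and amino-acid enrichment,
    homolog conservation statistics over multiple sequence alignments,
    and a bidirectional recurrent network surrogate for fast
    sequence-to-ensemble prediction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
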