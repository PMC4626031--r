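Package: mitotaur
Title: Cattle Mitogenome Variant Profiling, Haplogroup Classification and
    Coalescence Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the population-genetic analysis of complete taurine
    cattle mitochondrial genomes. Represents sequence variants relative to the
    Bovine Reference Sequence in the standard nucleotide-position notation,
    classifies mitogenomes into the taurine haplogroup tree (P, Q, T and
    subclades) from editable defining-mutation motifs, builds
    backbone-constrained most-parsimonious mutation trees with recurrent and
    back-mutation annotation, estimates clade coalescence times with the rho
    statistic (with its heuristic genealogy-based standard error) and with
    clock-constrained maximum likelihood under HKY85 with discrete-gamma rate
    heterogeneity, converts mutational divergence to years with a
    coding-region molecular clock, and computes haplotype diversity and
    related summaries. A coalescent/star-phylogeny sequence simulator with a
    truth manifest makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ape,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
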