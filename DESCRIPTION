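Package: introKASP
Title: Chromosome-Specific KASP Marker Design and Wild-Relative
    Introgression Detection
Version: 0.1.0
Authors@R:
    person("WRC", "Tools", email = "wrc.tools@example.org", role = c("aut", "cre"))
Description: A desk-scale reimplementation of the computational chain used to
    detect wild-relative (Triticum timopheevii) chromosome segments
    introgressed into hexaploid wheat. Covers chromosome-specific SNP
    selection from resequencing alignments (alignment filtering, duplicate
    removal, a count-based candidate caller, and a KASP-suitability filter
    with 50-bp flanking-window criteria), off-target homology screening by
    seed-and-extend local alignment, allele-specific (KASP) assay design,
    marker-panel spacing and gap-filling analytics, genotype-matrix to
    introgression-segment calling with a cross-line unique-segment catalog
    and summary statistics, and a synthetic-data generator (toy polyploid
    genomes, planted variants of known filter classes, pre-aligned reads,
    and a backcross/self breeding-scheme simulator with homoeologous
    pairing and transmission bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
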