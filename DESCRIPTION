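Package: compara
Title: Comparative Transcriptomics: Orthology, Ka/Ks, GO Profiling and
    Marker Mining for Two-Species EST Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing two de novo transcriptome assemblies:
    reciprocal-best-hit ortholog identification with paralog-exclusion
    filters (shared best protein match, unique gene name), codon-level
    Ka/Ks estimation by the Nei-Gojobori (1986) and Yang-Nielsen (2000)
    approximate methods with Fisher-exact significance classification,
    GO level-3 functional profiling and hypergeometric enrichment, and
    transcriptome marker mining (pileup-based SNP calling with depth and
    minor-allele-frequency filters; perfect microsatellite detection
    with canonical motif classes). Includes a synthetic dual-transcriptome
    generator (codon substitution model, decoy paralogs, planted SNPs,
    SSR tracts and enriched GO terms) so the whole pipeline can be
    exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
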