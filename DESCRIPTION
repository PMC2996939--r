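Package: phosnp
Title: Effects of Nonsynonymous SNPs on Protein Phosphorylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteome-wide analysis of how single nucleotide polymorphisms
    affect protein phosphorylation sites, modelled on natural variation in
    Arabidopsis thaliana. Maps genomic SNPs through gene models onto codons and
    proteins, classifies synonymous and non-synonymous substitutions,
    quantifies substitution enrichment at phosphorylated versus
    non-phosphorylated S/T/Y residues with Fisher's exact tests and
    Benjamini-Hochberg correction, calls gains and losses of experimental and
    predicted phosphosites (substitution- and prediction-score-based), detects
    phosphorylation hotspots by sliding-window scans against Monte-Carlo
    background proteomes with Bonferroni control, tests hotspot-domain overlap
    by permutation, and performs hypergeometric term-enrichment analysis. A
    fully seeded synthetic-data generator produces genomes, gene models,
    phosphosite sets, SNP panels, domains and annotations with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
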