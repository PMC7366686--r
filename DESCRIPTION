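Package: alsdiag
Title: Species-Diagnostic SNPs and Target-Site Herbicide-Resistance Genotyping
    from IUPAC-Coded Sanger Alignments
Version: 0.1.0
Authors@R:
    person("alsdiag", "maintainers", email = "maintainers@alsdiag.invalid",
           role = c("aut", "cre"))
Description: Heterozygote-aware analysis of aligned Sanger amplicon sequences
    for weedy Amaranthus and similar diploid plants. Reads FASTA alignments in
    which two-base IUPAC ambiguity codes encode heterozygotes, computes
    per-species site summaries, variable and parsimony-informative site
    statistics, and species-diagnostic SNPs; extracts acetolactate synthase
    (ALS) codons from a resistance catalog and calls amino-acid substitutions
    with zygosity, phasing and novelty flags; assigns multi-locus haplotype
    groups; summarizes patristic distances within and between species on a
    supplied tree; and ships a deterministic synthetic-data generator with
    ground-truth records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
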