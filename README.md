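# alsdiag

Heterozygote-aware analysis of aligned diploid Sanger amplicons for weedy
*Amaranthus* and similar taxa: species-diagnostic SNP discovery, target-site
ALS herbicide-resistance genotyping, multi-locus haplotype grouping, and
patristic distance summaries — plus a deterministic simulator with ground
truth so the whole pipeline is testable without external data.

## Who this is for

Quarantine and weed-science labs that sequence ITS/ALS amplicons from plants
or intercepted seeds and need to answer, from one alignment with IUPAC
ambiguity codes:

1. *Which species is this?* — positions where the target species' resolved
   allele set is disjoint from every other species' alleles.
2. *Does it carry a resistant ALS allele, and is it homozygous?* — calls at
   the standardized ALS codons (Ala122, Pro197, Trp574, Ser653, ...).
3. *Which resistant lineage is it?* — multi-locus haplotype groups and
   within- vs between-species patristic distances.

## The model in brief

A two-base IUPAC code at one position of a diploid Sanger read is a
heterozygote carrying both bases. For a codon genotype `g ∈ IUPAC³` with
`h` heterozygous positions there are `2^(h−1)` phase-consistent unordered
allele pairs `(c₁, c₂)`; the caller selects the pair by **wild-type
preference** (pairs containing a synonymous wild codon, then pairs whose
mutant amino acid is previously reported, then lexicographic with an
`ambiguous_phasing` flag), translates both alleles under the standard code,
and emits `from_aa → to_aa` with zygosity iff some allele is nonsynonymous.
A site is *diagnostic* for species `s` iff

```
alleles(s) ∩ ⋃_{s' ≠ s} alleles(s') = ∅ ,   alleles(·) = union of IUPAC expansions (gaps, N excluded)
```

Parsimony-informative sites count a heterozygote as one occurrence of each
of its two bases. Patristic distance is the branch-length path sum between
two leaves of a supplied tree. Details and rationale: the methods vignette
(`vignettes/alsdiag-methods.Rmd`).

## Worked example

The package ships a transcription of a published 25-sample × 4-codon ALS
resistance genotype table (plain text under `inst/extdata/`):

```r
library(alsdiag)
aln <- resistance_example_alignment()
res <- call_dataset(aln)          # default_catalog(): codons 122/197/574/653
res$summary
#>           species n_resistant n_calls n_het_calls n_samples_multi
#> 1    A. arenicola           1       2           2               1
#> 2      A. palmeri           8       8           7               0
#> 3 A. tuberculatus          16      21          16               5
#> 4           Total          25      31          25               6
head(res$calls[, c("sample_id", "aa_number", "from_aa", "to_aa",
                   "zygosity", "genotype", "flags")], 3)
#>   sample_id aa_number from_aa to_aa     zygosity genotype flags
#> 1    09-014       197       P     T heterozygous      MCT novel
#> 2     11963       574       W     L heterozygous      TKG      
#> 3     12008       122       A     N heterozygous      RMT novel
```

Reading the summary: 25 of the 25 samples carry at least one resistant ALS
allele (16 *A. tuberculatus*, 8 *A. palmeri*, 1 *A. arenicola*), for 31
amino-acid substitution calls in total, 25 of them heterozygous (80.6%); 5
*A. tuberculatus* samples carry two substitutions. Calls flagged `novel` are
absent from the shipped previously-reported list (here Ala122Asn, Pro197Thr,
Pro197Ile, Ser653Lys).

Diagnostic SNPs from the companion per-species site-summary fixture:

```r
s <- site_summaries(species_snp_example_alignment())
d <- find_diagnostic_sites(s, "A. tuberculatus")
head(subset(d, verdict == "diagnostic"), 2)
#>   reference_position target_alleles other_alleles    verdict majority_diagnostic
#> 1                351              T             A diagnostic                TRUE
#> 3                465              T             C diagnostic                TRUE
```

Position 351 separates *A. tuberculatus* (T) from all five similar species
(A); 1482 does not (`C|T` vs `C|T` — its heterozygotes overlap).

Simulate → call → score against ground truth:

```r
sim <- simulate_dataset(sim_config(seed = 42))
calls <- call_dataset(sim$alignment)$calls
truth_compare(sim$truth, calls, "calls")
#> $precision ... 1  $recall ... 1  $zygosity_accuracy ... 1
```

## Command line

```sh
Rscript exec/alsdiag simulate --seed 7 --out sim/
Rscript exec/alsdiag call-resistance --fasta sim/alignment.fasta \
    --metadata sim/metadata.tsv --first-position 349 --out calls/
Rscript exec/alsdiag diagnostics --fasta aln.fasta --metadata md.tsv \
    --target "A. tuberculatus" --out diag/
```

Subcommands: `call-resistance`, `diagnostics`, `snp-stats`, `haplogroups`,
`distances`, `simulate`. Logs go to stderr; data artifacts (TSV/JSON, with
the full run configuration embedded) go under `--out`.

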