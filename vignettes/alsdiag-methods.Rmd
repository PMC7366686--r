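---
title: "Methods: heterozygote-aware SNP diagnostics and ALS resistance genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterozygote-aware SNP diagnostics and ALS resistance genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alsdiag)
```

## The problem

Weedy amaranths (*Amaranthus*) are hard to identify morphologically,
especially as seeds intercepted in grain shipments, and two of the worst
agricultural species (*A. palmeri*, *A. tuberculatus*) carry target-site
resistance to acetolactate-synthase (ALS) inhibiting herbicides. Both
problems reduce to reading aligned Sanger amplicons of nuclear markers (ITS,
two ALS regions) from diploid individuals:

* **species diagnosis** — find positions where one species' alleles never
  overlap any other species' alleles;
* **resistance genotyping** — read the genotype at a catalog of ALS codons
  (Ala122, Pro197, Ala205, Asp376, Arg377, Trp574, Ser653, Gly654) and call
  amino-acid substitutions with zygosity;
* **population structure** — group samples by multi-locus haplotypes and
  summarise within- vs between-species patristic distances on a supplied
  tree.

The single modelling commitment underlying everything is the **diploid
Sanger convention**: a two-base IUPAC ambiguity code at one position (K =
G/T, M = A/C, ...) is a heterozygote carrying both bases. Every statistic in
the package is defined so that this convention is handled explicitly rather
than by discarding ambiguous characters.

## Resolved allele sets, gaps, and N

For a set of samples at one position, the *resolved allele set* is the union
of the IUPAC expansions of the observed codes. Gaps (`-`) and `N` contribute
nothing: `N` means "no information" in Sanger data, and including its
four-base expansion would both destroy any diagnostic verdict and inflate
variable-site counts. This exclusion applies uniformly to site summaries,
variable/PIS statistics, diagnosticity and pairwise species differences.

* A site is **variable** when the resolved alleles across all samples number
  at least two — a single heterozygote suffices.
* A site is **parsimony-informative** (PIS) when at least two bases each
  occur in at least two samples, where a heterozygous sample contributes one
  occurrence of *each* of its two bases. The field has no standard
  convention for PIS over ambiguity codes; this both-bases rule is
  symmetric, keeps PIS ⊆ variable by construction, and is what the tests
  enforce. Note this changes counts relative to tools that drop ambiguity
  codes, which is why whole-alignment variable/PIS counts printed elsewhere
  are not comparison targets.
* A site is **diagnostic** for a target species when its resolved allele set
  is non-empty and disjoint from the union over all other species. This is
  deliberately strict — one shared heterozygote destroys it, matching the
  "unique SNP" use-case where a single mistyped interception matters. A
  relaxed *majority* verdict (disjointness after dropping codes observed in
  only one sample) is reported in a separate, clearly labelled column for
  operational use; it is never substituted for the strict verdict.

## Codon calling and the phasing rule

A codon genotype is three IUPAC characters read through the coordinate map.
With *h* heterozygous positions the genotype is consistent with
2^(h−1) unordered allele pairs (h = 0 gives the homozygous pair). Codes
expanding to three or four bases exceed a diploid genotype and make the
codon an explicit no-call (reason logged), as does any gap — ITS/ALS
alignments do contain indels, and a gap inside a codon is missing data, not
an error.

When h ≥ 2 the pair is not identified by the data, and the caller must
choose. The shipped rule, in order:

1. prefer pairs containing a synonymous **wild-type codon** (the catalog
   ships these per codon, e.g. {GCA, GCT} for Ala122, {AGC, AGT} for
   Ser653, pooled across species since different wild codons segregate in
   different species);
2. among wild-containing pairs whose amino-acid outcomes differ, prefer the
   one whose mutant amino acid is on the catalog's previously-reported
   list;
3. otherwise pick the lexicographically smallest pair and flag
   `ambiguous_phasing`. If no pair contains a wild codon the call carries
   `no_wild_allele`.

The rationale for wild-type preference is biological: resistant ALS alleles
are dominant and arise on a susceptible background, so a heterozygote
carrying one wild allele is the parsimonious reading — and this single rule
reproduces every substitution identity in the package's 25-sample worked
example, including Ser653Lys from genotype A,R,S (pairings AGC+AAG vs
AGG+AAC; only the first contains a wild codon) and Pro197Ile from M,Y,C.
When all surviving pairings agree on the amino acids (e.g. A,R,Y at Ser653:
AGC+AAT and AGT+AAC are both Ser/Asn) no ambiguity flag is raised, because
the *call* is phase-invariant even though the nucleotide pair is not.

A call is emitted iff at least one allele encodes a non-wild amino acid;
synonymous variants (e.g. the third-position AGT/AGY Ser653 genotypes, which
we read as synonymous polymorphism reports rather than typos) yield no call.
Zygosity is homozygous iff both alleles encode the same non-wild amino acid.
Substitutions absent from the catalog's previously-reported list are flagged
`novel`; that list is shipped data (editable JSON), not code. Stop codons
are reported with `to_aa = "*"` and flagged, never dropped.

### A known identifiability limit

For mutant codons two or more edits from every wild codon, a second
wild-containing pairing can exist with a *different* mutant amino acid
(wild GCA + mutant AAT gives genotype R,M,W, where GCT+AAA — Ala + Lys — is
equally consistent). No phasing rule can resolve this from one codon's
Sanger trace. The test suite therefore asserts exact recovery of injected
substitutions in the identifiable regime (homozygotes, and heterozygotes
with a unique wild-containing pairing — which covers every known-resistant
target in the catalog, all one edit from wild) and asserts an emitted,
ambiguity-flagged call otherwise.

## Coordinates

All positions are 1-based and closed, in an opaque reference frame supplied
by configuration (the frame in which the ALS literature reports positions
349..2016 for these amplicons). Codon starts are **never derived from
amino-acid numbers** by an offset formula: the published positions for these
amplicons are not consistent with any single CDS offset (codon 122 at
349–351 implies one frame, codon 574 at 1717–1719 another). The two codons
shipped with offset-derived coordinates (205, 654) are therefore disabled by
default and marked as unverified; 376/377 fall outside the amplicons
entirely and ship without coordinates. The coordinate map itself is built
from a designated gap-bearing reference sample (non-gap columns numbered
consecutively) or supplied as an explicit table.

## Haplotype groups

Over a configurable locus set (default 1770, 1776, 1782, 1794 — the four
polymorphic positions inside the 1770–1794 ALS interval that structures
*A. tuberculatus*; the mapping of group letters such as ATCG onto this
position order is an assumption recorded here), a sample with an
unambiguous genotype forms its own group labelled by the concatenated
bases. Any sample with a two-base code goes into one pooled
`heterozygous` class with all 2^h phase-consistent haplotypes listed —
pooling is deliberate: assigning heterozygotes to a "nearest" homozygous
group would require a phasing model (EM/likelihood) that is out of scope,
and the listed compatible haplotypes let users refine downstream. Gaps or
3-/4-fold codes at any locus give group `other` with a reason.

## Patristic distances

Distances are patristic only — path sums of branch lengths on a supplied
tree (no p-distance substitute is ever used silently, and no tree is
inferred). Means are taken over all unordered within-species and
between-species leaf pairs; singleton species contribute no within pairs. A
one-species tree is accepted and reports `NaN` for the empty between-species
class. The production path uses `ape`'s node-distance machinery; the test
suite checks it against an independent brute-force path enumeration to
1e-9 on random trees of up to 20 leaves.

## The synthetic-data generator

Raw study alignments in this field are frequently unreleased, so the
generator is first-class, tested code that emulates exactly the structure
the analysis assumes — not a coalescent simulator. It plants:

* fixed interspecific SNPs (target species one base, all others another);
* intraspecific polymorphism: per sample, heterozygous with probability
  `het_freq` (written as the IUPAC collapse), else homozygous minor with
  probability `minor_freq`, else major;
* resistance injections at catalog codons: heterozygotes are wild+mutant
  diplotypes, the mutant codon being the minimal-edit codon for the target
  amino acid (deterministic tie-break);
* haplotype groups: two haplotypes drawn per scoped sample from configured
  frequencies;
* a species-clustered tree with within-species depths well below
  between-species depths (defaults 0.0008 vs 0.013, the order of magnitude
  separating intra- from interspecific patristic means in ALS/ITS data).

Defaults state a border-interception sampling design: six similar species,
sample sizes of the magnitude seen in quarantine surveys (29/29/8/2/1/1
across species, split over provinces), moderate injection frequencies.
Everything is driven by one seed; per-stage substreams are derived from it
so adding a stage never perturbs earlier draws, and identical configs give
byte-identical files. Ground truth (per-sample haplogroup, injected
substitutions with zygosity, planted diagnostic sites) is emitted alongside
and compared exactly by `truth_compare()`.

What a green synthetic test does **not** establish: robustness to alignment
error, sequencing noise beyond heterozygote encoding, indel-rich regions,
paralogy, or recombination — none of which are simulated.

## The worked example and the heterozygous fraction

The package ships a transcription of a published 25-sample × 4-codon
resistance genotype table as plain text; `resistance_example_alignment()`
inflates it into a full alignment. Running the caller on it yields 25
resistant samples (16 *A. tuberculatus*, 8 *A. palmeri*, 1 *A. arenicola*),
31 substitution calls, and 5 two-substitution *A. tuberculatus* samples —
the acceptance surface.

Of those 31 calls, 6 are homozygous (Trp574Leu in two samples, Ala122Asn in
three, Ser653Thr in one), so the computed heterozygous fraction is
25/31 = 80.6%. The source reports 77.4% (= 24/31). A strict recount of the
printed genotypes under any phasing rule cannot reach 24 heterozygotes
unless one of the six homozygous genotypes above is read differently; the
likeliest explanation is a hand-count discrepancy in the source. The
package reports the computed fraction alongside the printed value and does
not treat either as a pass/fail target.

The per-species SNP table fixture is site-level only: each column is filled
independently to match the printed per-species code counts (a few printed
rows imply one more sample than the table header — those extra samples
carry gaps elsewhere so no printed count is disturbed), so its per-sample
haplotypes are meaningless by construction.

## Numerical and interface choices

* Counts and verdicts are exact integer/set operations; the only tolerance
  in the package is the 1e-9 oracle agreement for patristic means.
* Ties everywhere break lexicographically (phasing pairs, sorted outputs),
  so reruns are byte-identical; reports embed the full run configuration
  and catalog rather than a hash.
* Metadata TSV always overrides FASTA-header metadata: one source of truth.
* Frequencies (e.g. per-species resistant fractions) are only computed when
  the user supplies denominators; the worked example's genotype table does
  not contain them.

## Limitations

Single-gene, target-site resistance only; no phenotype prediction,
non-target-site mechanisms, or other herbicide-target genes. No alignment,
tree inference, or support values — trees are inputs. Diagnostic verdicts
are only as good as the species labels in the metadata.
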