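# resistance: translation, pair enumeration, phasing, codon calls, dataset

catalog <- default_catalog()
spec_of <- function(aa) catalog[catalog$aa_number == aa, , drop = FALSE]

test_that("codon translation uses the standard code", {
  expect_equal(translate_codon("TGG"), "W")
  expect_equal(translate_codon("TTG"), "L")
  expect_equal(translate_codon("AAT"), "N")
  expect_equal(translate_codon("TAA"), "*")
  expect_error(translate_codon("TKG"), "unambiguous")
})

test_that("shipped catalog carries the documented entries", {
  expect_setequal(spec_of(574L)$wild_codons[[1L]], "TGG")
  expect_true(all(c("GCA", "GCT") %in% spec_of(122L)$wild_codons[[1L]]))
  expect_true(all(c("T", "N") %in% spec_of(653L)$known_resistant[[1L]]))
  expect_false("K" %in% spec_of(653L)$known_resistant[[1L]])
  # wild codons all translate to the wild amino acid (validated invariant)
  expect_s3_class(validate_catalog(catalog), "als_catalog")
  # amplicon-external codons are present but disabled and coordinate-free
  expect_true(all(is.na(catalog$codon_start[catalog$aa_number %in%
                                              c(376L, 377L)])))
  expect_false(any(catalog$enabled[catalog$aa_number %in%
                                     c(205L, 376L, 377L, 654L)]))
})

test_that("catalog JSON round-trips through read/write", {
  f <- withr::local_tempfile(fileext = ".json")
  write_catalog(catalog, f)
  back <- read_catalog(f)
  expect_equal(back$aa_number, catalog$aa_number)
  expect_equal(back$codon_start, catalog$codon_start)
  for (i in seq_len(nrow(catalog))) {
    expect_setequal(back$wild_codons[[i]], catalog$wild_codons[[i]])
    expect_setequal(back$known_resistant[[i]], catalog$known_resistant[[i]])
  }
})

test_that("allele-pair enumeration matches the 64x64 brute-force oracle", {
  expect_equal(genotype_to_allele_pairs("TKG"), list(c("TGG", "TTG")))
  expect_equal(genotype_to_allele_pairs("AAA"), list(c("AAA", "AAA")))
  # two het positions: exactly the oracle's pair set (2^(2-1) = 2 pairs)
  got <- genotype_to_allele_pairs("RMT")
  want <- oracle_allele_pairs("RMT")
  expect_setequal(vapply(got, paste, "", collapse = "|"),
                  vapply(want, paste, "", collapse = "|"))
  # systematic sweep over random genotypes with 0-3 het positions
  set.seed(404)
  codes2 <- c("R", "Y", "S", "W", "K", "M")
  for (i in 1:40) {
    g <- paste(sample(c("A", "C", "G", "T", codes2), 3L, replace = TRUE),
               collapse = "")
    got <- vapply(genotype_to_allele_pairs(g), paste, "", collapse = "|")
    want <- vapply(oracle_allele_pairs(g), paste, "", collapse = "|")
    expect_setequal(got, want)
    h <- sum(strsplit(g, "")[[1L]] %in% codes2)
    expect_length(got, max(1L, 2L^(h - 1L)))
  }
  expect_error(genotype_to_allele_pairs("A-G"), "gap")
  expect_error(genotype_to_allele_pairs("ANG"), "diploid")
})

test_that("wild-preferring phasing reproduces the printed substitutions", {
  # codon 197 genotype MYC: only (ATC,CCC) contains a wild codon -> Pro197Ile
  sel <- select_phasing(genotype_to_allele_pairs("MYC"), spec_of(197L))
  expect_setequal(sel$pair, c("ATC", "CCC"))
  expect_length(sel$flags, 0L)
  aa <- vapply(sel$pair, translate_codon, "")
  expect_setequal(aa, c("I", "P"))
  # codon 653 genotype ARS: wild-containing pairing (AGC,AAG) -> Ser653Lys
  sel <- select_phasing(genotype_to_allele_pairs("ARS"), spec_of(653L))
  expect_setequal(sel$pair, c("AAG", "AGC"))
  expect_length(sel$flags, 0L)
  # codon 653 genotype ARY: both pairings wild-containing, both give Ser/Asn
  # -> no ambiguity flag
  sel <- select_phasing(genotype_to_allele_pairs("ARY"), spec_of(653L))
  expect_length(sel$flags, 0L)
  expect_setequal(vapply(sel$pair, translate_codon, ""), c("S", "N"))
  # homozygous mutant: single pair, no wild allele anywhere
  sel <- select_phasing(genotype_to_allele_pairs("AAT"), spec_of(122L))
  expect_identical(sel$flags, "no_wild_allele")
})

test_that("phasing is invariant for genotypes with <= 1 ambiguous position", {
  set.seed(505)
  codes2 <- c("R", "Y", "S", "W", "K", "M")
  for (i in 1:30) {
    g <- sample(c("A", "C", "G", "T"), 3L, replace = TRUE)
    slot <- sample(3L, 1L)
    if (i %% 2L) g[slot] <- sample(codes2, 1L)
    pairs <- genotype_to_allele_pairs(g)
    expect_length(pairs, 1L)  # only one pairing exists
    sel <- select_phasing(pairs, spec_of(574L))
    expect_identical(sel$pair, pairs[[1L]])
  }
})

# small alignment exposing one codon through a shifted coordinate map
codon_aln <- function(genotype, aa_number, species = "A. tuberculatus") {
  spec <- spec_of(aa_number)
  start <- spec$codon_start[[1L]]
  aln <- als_alignment("s1", species, "pop",
                       paste0("AC", paste(genotype, collapse = ""), "GT"))
  aln$coord_map <- data.frame(alignment_column = 1:7,
                              reference_position = (start - 2L):(start + 4L))
  aln
}

test_that("call_codon: worked-example genotypes and no-call rules", {
  # homozygous Trp574Leu
  call <- call_codon(codon_aln(c("T", "T", "G"), 574L), "s1", spec_of(574L))
  expect_equal(call$to_aa, "L")
  expect_equal(call$zygosity, "homozygous")
  # synonymous Ser653 heterozygote AGY: both alleles Ser -> no call
  none <- call_codon(codon_aln(c("A", "G", "Y"), 653L), "s1", spec_of(653L))
  expect_equal(nrow(none), 0L)
  expect_null(attr(none, "no_call_reason"))
  # homozygous Ala122Asn, flagged novel
  call <- call_codon(codon_aln(c("A", "A", "T"), 122L), "s1", spec_of(122L))
  expect_equal(call[, c("from_aa", "to_aa", "zygosity")],
               data.frame(from_aa = "A", to_aa = "N",
                          zygosity = "homozygous"))
  expect_match(call$flags, "novel")
  # gap and >2-fold ambiguity are explicit no-calls, not errors
  g <- call_codon(codon_aln(c("A", "-", "T"), 122L), "s1", spec_of(122L))
  expect_equal(nrow(g), 0L)
  expect_match(attr(g, "no_call_reason"), "gap")
  n4 <- call_codon(codon_aln(c("A", "N", "T"), 122L), "s1", spec_of(122L))
  expect_match(attr(n4, "no_call_reason"), "ambiguity")
})

test_that("every synonymous wild genotype yields no call, for all codons", {
  for (i in which(catalog$enabled)) {
    spec <- catalog[i, , drop = FALSE]
    wilds <- spec$wild_codons[[1L]]
    for (w in wilds) {
      g <- strsplit(w, "")[[1L]]
      expect_equal(nrow(call_codon(codon_aln(g, spec$aa_number), "s1", spec)),
                   0L, info = paste(spec$aa_number, w))
    }
    # heterozygote of two synonymous wild codons is also silent
    if (length(wilds) == 2L) {
      het <- mapply(function(a, b) collapse_to_iupac(c(a, b)),
                    strsplit(wilds[[1L]], "")[[1L]],
                    strsplit(wilds[[2L]], "")[[1L]])
      expect_equal(nrow(call_codon(codon_aln(het, spec$aa_number), "s1",
                                   spec)), 0L)
    }
  }
})

test_that("call_dataset aggregates and sorts; all-wild data give 0 calls", {
  aln <- resistance_example_alignment()
  res <- call_dataset(aln)
  expect_false(is.unsorted(res$calls$sample_id))
  expect_equal(res$summary$n_calls[res$summary$species == "Total"],
               nrow(res$calls))
  expect_true(all(res$summary$n_het_calls <= res$summary$n_calls))
  # frequencies appear only when totals are supplied
  expect_null(res$summary$frequency)
  res2 <- call_dataset(aln, species_totals = c(
    "A. tuberculatus" = 29, "A. palmeri" = 29, "A. arenicola" = 1))
  expect_equal(
    res2$summary$frequency[res2$summary$species == "A. tuberculatus"],
    16 / 29, tolerance = 1e-12)

  # all-wild alignment: no calls anywhere
  wild <- aln
  first <- wild$coord_map$reference_position[[1L]]
  for (i in which(catalog$enabled)) {
    st <- catalog$codon_start[[i]] - first + 1L
    for (k in seq_len(nrow(wild$samples)))
      substr(wild$samples$sequence[[k]], st, st + 2L) <-
        catalog$wild_codons[[i]][[1L]]
  }
  expect_equal(nrow(call_dataset(wild)$calls), 0L)
})

test_that("stop codons are reported with to_aa '*' and flagged", {
  # codon 574 genotype TRG: pairing (TAG,TGG) contains wild -> W/* het
  call <- call_codon(codon_aln(c("T", "R", "G"), 574L), "s1", spec_of(574L))
  expect_equal(call$to_aa, "*")
  expect_match(call$flags, "stop_codon")
})

test_that("injection round trip recovers substitution and zygosity", {
  # Exact recovery is guaranteed in the identifiable regime: homozygous
  # mutants, and heterozygotes whose phase-consistent pair set has a unique
  # wild-containing pairing (always true for the catalog's known-resistant
  # targets, which sit one edit from a wild codon). Multi-edit heterozygous
  # mutants can admit a second wild-containing pairing with a different
  # mutant amino acid; those must still yield a call, flagged ambiguous.
  set.seed(606)
  enabled <- catalog[catalog$enabled, , drop = FALSE]
  aas <- setdiff(unique(Biostrings::GENETIC_CODE), "*")
  for (i in 1:200) {
    spec <- enabled[sample(nrow(enabled), 1L), , drop = FALSE]
    to <- sample(setdiff(aas, spec$wild_aa), 1L)
    wild <- sample(spec$wild_codons[[1L]], 1L)
    mut <- alsdiag:::mutant_codon(wild, to)
    zyg <- sample(c("homozygous", "heterozygous"), 1L)
    g <- if (zyg == "homozygous") strsplit(mut, "")[[1L]] else
      mapply(function(a, b) collapse_to_iupac(c(a, b)),
             strsplit(wild, "")[[1L]], strsplit(mut, "")[[1L]])
    call <- call_codon(codon_aln(g, spec$aa_number), "s1", spec)
    expect_equal(nrow(call), 1L, info = paste(spec$aa_number, wild, to, zyg))
    pairs <- genotype_to_allele_pairs(g)
    wild_pairings <- sum(vapply(pairs, function(p)
      any(p %in% spec$wild_codons[[1L]]), logical(1L)))
    if (zyg == "homozygous" || wild_pairings == 1L) {
      expect_equal(call$to_aa, to)
      expect_equal(call$zygosity, zyg)
    } else {
      expect_true(call$to_aa == to ||
                    grepl("ambiguous_phasing", call$flags))
    }
  }
  # the identifiable regime proper: every known-resistant target, both
  # zygosities, recovered exactly
  for (i in seq_len(nrow(enabled))) {
    spec <- enabled[i, , drop = FALSE]
    for (to in spec$known_resistant[[1L]]) for (wild in spec$wild_codons[[1L]])
      for (zyg in c("homozygous", "heterozygous")) {
        mut <- alsdiag:::mutant_codon(wild, to)
        g <- if (zyg == "homozygous") strsplit(mut, "")[[1L]] else
          mapply(function(a, b) collapse_to_iupac(c(a, b)),
                 strsplit(wild, "")[[1L]], strsplit(mut, "")[[1L]])
        call <- call_codon(codon_aln(g, spec$aa_number), "s1", spec)
        expect_equal(call$to_aa, to)
        expect_equal(call$zygosity, zyg)
      }
  }
})
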