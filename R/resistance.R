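# Target-site resistance genotyping for ALS. A codon genotype is three IUPAC
# characters; two-base codes mark heterozygous positions of a diploid. The
# caller enumerates the phase-consistent allele pairs, picks one under a
# wild-type-preferring rule, translates, and emits a substitution call when
# (and only when) an allele changes the amino acid.

#' Translate an unambiguous codon
#'
#' Standard genetic code (via `Biostrings::GENETIC_CODE`); stops are `"*"`.
#'
#' @param codon Three-character string over `A,C,G,T`.
#' @return Single-letter amino acid.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop(sprintf("translate_codon needs 3 unambiguous bases, got '%s'", codon),
         call. = FALSE)
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' The shipped ALS resistance-codon catalog
#'
#' One entry per ALS codon implicated in target-site resistance, on the
#' reference coordinate frame used throughout the ALS amplicon literature for
#' Amaranthus (codon 122 at 349-351, 197 at 574-576, 574 at 1717-1719, 653 at
#' 1954-1956). Codons 205 and 654 ship with offset-derived coordinates but are
#' disabled by default; 376 and 377 fall outside the sequenced amplicons and
#' have no coordinates. `known_resistant` is the editable
#' previously-reported-in-*Amaranthus* list used for novelty flagging, not a
#' claim about other genera.
#'
#' @return An `als_catalog`: data.frame with columns `aa_number`,
#'   `codon_start`, `wild_aa`, `wild_codons` (list), `known_resistant` (list),
#'   `enabled`, `note`.
#' @export
default_catalog <- function() {
  spec <- function(aa_number, codon_start, wild_aa, wild_codons,
                   known_resistant, enabled = TRUE, note = "") {
    data.frame(aa_number = aa_number, codon_start = codon_start,
               wild_aa = wild_aa,
               wild_codons = I(list(wild_codons)),
               known_resistant = I(list(known_resistant)),
               enabled = enabled, note = note, stringsAsFactors = FALSE)
  }
  cat <- rbind(
    spec(122L, 349L, "A", c("GCA", "GCT"), "T"),
    spec(197L, 574L, "P", c("CCC", "CCT"), "S"),
    spec(205L, 598L, "A", "GCT", "V", enabled = FALSE,
         note = "coordinate derived by offset from codon 197; unverified"),
    spec(376L, NA_integer_, "D", "GAT", "E", enabled = FALSE,
         note = "outside the sequenced amplicons"),
    spec(377L, NA_integer_, "R", "CGT", character(0), enabled = FALSE,
         note = "outside the sequenced amplicons"),
    spec(574L, 1717L, "W", "TGG", "L"),
    spec(653L, 1954L, "S", c("AGC", "AGT"), c("T", "N")),
    spec(654L, 1957L, "G", "GGT", "E", enabled = FALSE,
         note = "coordinate derived by offset from codon 653; unverified")
  )
  validate_catalog(cat)
}

#' @rdname default_catalog
#' @param catalog A catalog data.frame to validate.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(all(c("aa_number", "codon_start", "wild_aa", "wild_codons",
                  "known_resistant", "enabled") %in% names(catalog)))
  for (i in seq_len(nrow(catalog))) {
    wc <- catalog$wild_codons[[i]]
    aa <- vapply(wc, translate_codon, "")
    if (!all(aa == catalog$wild_aa[[i]]))
      stop(sprintf("codon %d: wild codon(s) %s do not translate to %s",
                   catalog$aa_number[[i]],
                   paste(wc[aa != catalog$wild_aa[[i]]], collapse = ","),
                   catalog$wild_aa[[i]]), call. = FALSE)
  }
  if (anyDuplicated(catalog$aa_number))
    stop("duplicate aa_number in catalog", call. = FALSE)
  class(catalog) <- c("als_catalog", "data.frame")
  catalog
}

#' Read or write a catalog as a JSON config
#' @param path JSON file.
#' @return `read_catalog()`: an `als_catalog`; `write_catalog()`: `path`.
#' @export
read_catalog <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rows <- lapply(raw, function(e) data.frame(
    aa_number = as.integer(e$aa_number),
    codon_start = if (is.null(e$codon_start) || is.na(e$codon_start))
      NA_integer_ else as.integer(e$codon_start),
    wild_aa = e$wild_aa,
    wild_codons = I(list(toupper(unlist(e$wild_codons)))),
    known_resistant = I(list(as.character(unlist(e$known_resistant)))),
    enabled = isTRUE(e$enabled),
    note = if (is.null(e$note)) "" else e$note,
    stringsAsFactors = FALSE))
  validate_catalog(do.call(rbind, rows))
}

#' @rdname read_catalog
#' @param catalog An `als_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  entries <- lapply(seq_len(nrow(catalog)), function(i) list(
    aa_number = catalog$aa_number[[i]],
    codon_start = catalog$codon_start[[i]],
    wild_aa = catalog$wild_aa[[i]],
    wild_codons = as.list(catalog$wild_codons[[i]]),
    known_resistant = as.list(catalog$known_resistant[[i]]),
    enabled = catalog$enabled[[i]],
    note = catalog$note[[i]]))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Enumerate phase-consistent allele pairs of a codon genotype
#'
#' A diploid genotype with h heterozygous positions is consistent with
#' `2^(h-1)` unordered codon pairs (one when h = 0). Positions expanding to
#' three or four bases exceed what a diploid can carry and are rejected.
#'
#' @param genotype Character vector of 3 IUPAC characters, or a 3-character
#'   string.
#' @return List of unordered pairs, each a sorted character vector of two
#'   codons; or `NULL` with attribute handling left to the caller when the
#'   genotype contains a gap.
#' @export
genotype_to_allele_pairs <- function(genotype) {
  g <- .as_genotype(genotype)
  if (any(g == "-"))
    stop("genotype contains a gap; codon is uncallable", call. = FALSE)
  exp <- lapply(g, expand_iupac)
  if (any(lengths(exp) > 2L))
    stop("3-/4-fold ambiguity exceeds a diploid genotype", call. = FALSE)
  het <- which(lengths(exp) == 2L)
  a1 <- vapply(exp, `[[`, "", 1L)
  if (!length(het)) {
    cod <- paste(a1, collapse = "")
    return(list(c(cod, cod)))
  }
  # phase choices: allele 1 takes first or second base at each het position
  choices <- expand.grid(rep(list(c(1L, 2L)), length(het)))
  pairs <- apply(choices, 1L, function(pick) {
    x <- a1; y <- a1
    for (k in seq_along(het)) {
      x[het[[k]]] <- exp[[het[[k]]]][pick[[k]]]
      y[het[[k]]] <- exp[[het[[k]]]][3L - pick[[k]]]
    }
    sort(c(paste(x, collapse = ""), paste(y, collapse = "")))
  }, simplify = FALSE)
  unique(pairs)
}

.as_genotype <- function(genotype) {
  if (length(genotype) == 1L && nchar(genotype) == 3L)
    genotype <- strsplit(genotype, "", fixed = TRUE)[[1L]]
  if (length(genotype) != 3L)
    stop("codon genotype must have 3 characters", call. = FALSE)
  toupper(genotype)
}

#' Choose one allele pair from the phase-consistent set
#'
#' The interpretive rule of the whole caller: prefer pairs containing a
#' synonymous wild-type codon; among those, prefer a pair whose mutant amino
#' acid is on the catalog's previously-reported list; when the surviving
#' candidates still disagree on the amino-acid outcome, pick the
#' lexicographically smallest pair and flag `ambiguous_phasing`. Pairs
#' disagreeing only in nucleotides (same amino acids) are not flagged. If no
#' pair contains a wild codon the call is flagged `no_wild_allele`.
#'
#' @param pairs From [genotype_to_allele_pairs()].
#' @param spec One catalog row (data.frame of one row or list) with
#'   `wild_codons`, `wild_aa`, `known_resistant`.
#' @return List: `pair` (the two codons), `flags` (character vector).
#' @export
select_phasing <- function(pairs, spec) {
  stopifnot(length(pairs) >= 1L)
  wild <- .spec_field(spec, "wild_codons")
  known <- .spec_field(spec, "known_resistant")
  wild_aa <- .spec_field(spec, "wild_aa")
  flags <- character(0)

  has_wild <- vapply(pairs, function(p) any(p %in% wild), logical(1L))
  cand <- if (any(has_wild)) pairs[has_wild] else {
    flags <- c(flags, "no_wild_allele")
    pairs
  }
  aa_outcome <- function(p) {
    aa <- sort(vapply(p, translate_codon, ""))
    paste(aa, collapse = "/")
  }
  outcomes <- vapply(cand, aa_outcome, "")
  if (length(unique(outcomes)) > 1L) {
    mutant_known <- vapply(cand, function(p) {
      aa <- vapply(p, translate_codon, "")
      any(aa[aa != wild_aa] %in% known)
    }, logical(1L))
    if (any(mutant_known)) {
      cand <- cand[mutant_known]
      outcomes <- outcomes[mutant_known]
    }
    if (length(unique(outcomes)) > 1L)
      flags <- c(flags, "ambiguous_phasing")
  }
  ord <- order(vapply(cand, paste, "", collapse = "|"))
  list(pair = cand[[ord[[1L]]]], flags = flags)
}

.spec_field <- function(spec, field) {
  v <- if (is.data.frame(spec)) spec[[field]][[1L]] else spec[[field]]
  unlist(v)
}

#' Call one catalog codon for one sample
#'
#' Extracts the 3-position genotype through the coordinate map, phases it,
#' translates both alleles, and emits a call iff at least one allele encodes
#' an amino acid other than the wild type. Synonymous variants yield no call.
#' Gaps or >2-fold ambiguity in the codon yield a no-call with a reason,
#' never an error.
#'
#' @param alignment An `als_alignment` with a coordinate map.
#' @param sample_id Sample to call.
#' @param spec One catalog row.
#' @return data.frame of 0 or 1 call row (columns as in [call_dataset()]),
#'   with attribute `"no_call_reason"` set when the codon was uncallable.
#' @export
call_codon <- function(alignment, sample_id, spec) {
  start <- .spec_field(spec, "codon_start")
  aa_number <- .spec_field(spec, "aa_number")
  empty <- data.frame()
  if (is.na(start)) {
    attr(empty, "no_call_reason") <- sprintf(
      "codon %d has no reference coordinates", aa_number)
    return(empty)
  }
  cols <- ref_to_col(alignment, start + 0:2)
  i <- match(sample_id, alignment$samples$sample_id)
  if (is.na(i)) stop(sprintf("unknown sample '%s'", sample_id), call. = FALSE)
  g <- strsplit(alignment$samples$sequence[[i]], "", fixed = TRUE)[[1L]][cols]

  if (any(g == "-")) {
    attr(empty, "no_call_reason") <- sprintf(
      "sample %s codon %d: gap in codon", sample_id, aa_number)
    return(empty)
  }
  if (any(lengths(lapply(g, expand_iupac)) > 2L)) {
    attr(empty, "no_call_reason") <- sprintf(
      "sample %s codon %d: >2-fold ambiguity", sample_id, aa_number)
    return(empty)
  }
  pairs <- genotype_to_allele_pairs(g)
  sel <- select_phasing(pairs, spec)
  aa <- vapply(sel$pair, translate_codon, "")
  wild_aa <- .spec_field(spec, "wild_aa")
  mutant <- aa[aa != wild_aa]
  if (!length(mutant)) return(empty)  # wild or synonymous: no call

  to_aa <- sort(unique(mutant))[[1L]]
  flags <- sel$flags
  if (length(unique(mutant)) > 1L) flags <- union(flags, "ambiguous_phasing")
  if (to_aa == "*") flags <- union(flags, "stop_codon")
  if (!to_aa %in% .spec_field(spec, "known_resistant") && to_aa != "*")
    flags <- union(flags, "novel")
  s <- alignment$samples[i, ]
  data.frame(
    sample_id = s$sample_id, species = s$species, origin = s$origin,
    aa_number = aa_number, from_aa = wild_aa, to_aa = to_aa,
    zygosity = if (length(mutant) == 2L && aa[[1L]] == aa[[2L]])
      "homozygous" else "heterozygous",
    allele1 = sel$pair[[1L]], allele2 = sel$pair[[2L]],
    genotype = paste(g, collapse = ""),
    flags = paste(sort(flags), collapse = ","),
    stringsAsFactors = FALSE)
}

#' Call every enabled catalog codon for every sample
#'
#' @param alignment An `als_alignment` with coordinate map and species labels.
#' @param catalog An `als_catalog`; only `enabled` rows are called.
#' @param species_totals Optional named numeric vector of per-species sampled
#'   totals; when given, per-species resistant frequencies are reported.
#' @return List with
#'   `calls` (data.frame sorted by sample then codon: sample_id, species,
#'   origin, aa_number, from_aa, to_aa, zygosity, allele1, allele2, genotype,
#'   flags), `summary` (per-species data.frame: n_resistant, n_calls,
#'   n_het_calls, n_samples_multi, and `frequency` when totals are given,
#'   plus a `Total` row), and `no_calls` (character vector of no-call
#'   reasons).
#' @export
call_dataset <- function(alignment, catalog = default_catalog(),
                         species_totals = NULL) {
  if (!nrow(catalog)) stop("catalog is empty", call. = FALSE)
  active <- catalog[catalog$enabled, , drop = FALSE]
  calls <- list(); reasons <- character(0)
  for (sid in alignment$samples$sample_id) {
    for (i in seq_len(nrow(active))) {
      res <- call_codon(alignment, sid, active[i, , drop = FALSE])
      why <- attr(res, "no_call_reason")
      if (!is.null(why)) reasons <- c(reasons, why)
      if (nrow(res)) calls[[length(calls) + 1L]] <- res
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(0), species = character(0),
               origin = character(0), aa_number = integer(0),
               from_aa = character(0), to_aa = character(0),
               zygosity = character(0), allele1 = character(0),
               allele2 = character(0), genotype = character(0),
               flags = character(0), stringsAsFactors = FALSE)
  calls <- calls[order(calls$sample_id, calls$aa_number), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls,
       summary = .resistance_summary(calls, species_totals),
       no_calls = reasons)
}

.resistance_summary <- function(calls, species_totals = NULL) {
  species <- sort(unique(calls$species))
  rows <- lapply(species, function(sp) {
    cs <- calls[calls$species == sp, , drop = FALSE]
    per_sample <- table(cs$sample_id)
    data.frame(species = sp,
               n_resistant = length(per_sample),
               n_calls = nrow(cs),
               n_het_calls = sum(cs$zygosity == "heterozygous"),
               n_samples_multi = sum(per_sample >= 2L),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), n_resistant = integer(0),
               n_calls = integer(0), n_het_calls = integer(0),
               n_samples_multi = integer(0))
  total <- data.frame(species = "Total",
                      n_resistant = sum(out$n_resistant),
                      n_calls = sum(out$n_calls),
                      n_het_calls = sum(out$n_het_calls),
                      n_samples_multi = sum(out$n_samples_multi))
  out <- rbind(out, total)
  if (!is.null(species_totals)) {
    out$frequency <- NA_real_
    hit <- out$species %in% names(species_totals)
    out$frequency[hit] <- out$n_resistant[hit] /
      as.numeric(species_totals[out$species[hit]])
    out$frequency[out$species == "Total"] <-
      total$n_resistant / sum(as.numeric(species_totals))
  }
  out
}
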