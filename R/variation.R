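# Heterozygote-aware site statistics: per-species site summaries in the
# "C8/T4/Y12" dialect, variable and parsimony-informative sites, diagnostic
# SNPs, and pairwise species differences. Throughout, a two-base ambiguity
# code contributes BOTH of its resolved bases; gaps and N contribute nothing.

#' Per-position, per-species allele summaries
#'
#' For every mapped reference position, counts the raw IUPAC codes observed in
#' each species (gaps and N excluded) and records the species' resolved allele
#' set -- the union of the expansions of its observed codes.
#'
#' @param alignment An `als_alignment` with a coordinate map and non-empty
#'   species labels.
#' @param positions Optional subset of reference positions (default: all
#'   mapped positions).
#' @return An object of class `als_site_summaries`: list with
#'   `counts` (data.frame `reference_position`, `species`, `code`, `count`)
#'   and `alleles` (data.frame `reference_position`, `species`, `alleles`,
#'   the resolved set as a sorted `"A|T"` string; empty string when all
#'   samples are gap/N).
#' @export
site_summaries <- function(alignment, positions = NULL) {
  s <- alignment$samples
  if (any(!nzchar(s$species)))
    stop("every sample needs a species label (see apply_metadata)",
         call. = FALSE)
  if (is.null(alignment$coord_map))
    stop("alignment has no coordinate map", call. = FALSE)
  cm <- alignment$coord_map
  if (is.null(positions)) positions <- cm$reference_position
  cols <- ref_to_col(alignment, positions)
  m <- seq_matrix(alignment)
  species <- sort(unique(s$species))

  counts <- list(); alleles <- list(); k <- 0L
  for (j in seq_along(cols)) {
    col <- m[, cols[[j]]]
    for (sp in species) {
      codes <- col[s$species == sp]
      codes <- codes[!codes %in% c("-", "N")]
      k <- k + 1L
      if (length(codes)) {
        tab <- table(codes)
        counts[[k]] <- data.frame(reference_position = positions[[j]],
                                  species = sp, code = names(tab),
                                  count = as.integer(tab),
                                  stringsAsFactors = FALSE)
      }
      res <- .resolve_column(codes)
      alleles[[k]] <- data.frame(reference_position = positions[[j]],
                                 species = sp,
                                 alleles = paste(sort(res), collapse = "|"),
                                 stringsAsFactors = FALSE)
    }
  }
  structure(list(counts = do.call(rbind, counts),
                 alleles = do.call(rbind, alleles),
                 species = species),
            class = "als_site_summaries")
}

#' @export
print.als_site_summaries <- function(x, ...) {
  cat(sprintf("<als_site_summaries> %d positions x %d species\n",
              length(unique(x$alleles$reference_position)),
              length(x$species)))
  invisible(x)
}

# allele set (character vector) for one position x species
.allele_set <- function(summaries, position, species) {
  a <- summaries$alleles
  v <- a$alleles[a$reference_position == position & a$species == species]
  if (!length(v) || !nzchar(v)) character(0) else strsplit(v, "|", fixed = TRUE)[[1L]]
}

#' Format site summaries in the compact per-species dialect
#'
#' One row per position, one column per species, cells like `"C8/T4/Y12"`
#' (code followed by its sample count, `/`-separated).
#'
#' @param summaries From [site_summaries()].
#' @return data.frame, first column `reference_position`.
#' @export
format_site_summaries <- function(summaries) {
  cnt <- summaries$counts
  pos <- sort(unique(summaries$alleles$reference_position))
  out <- data.frame(reference_position = pos)
  for (sp in summaries$species) {
    out[[sp]] <- vapply(pos, function(p) {
      rows <- cnt[cnt$reference_position == p & cnt$species == sp, ,
                  drop = FALSE]
      if (!nrow(rows)) return("")
      rows <- rows[order(-rows$count, rows$code), ]
      paste0(rows$code, rows$count, collapse = "/")
    }, "")
  }
  out
}

# per-column resolved alleles for each sample: list of character vectors
.column_expansions <- function(col) {
  keep <- !col %in% c("-", "N")
  lapply(col[keep], function(ch) .IUPAC_MAP[[ch]])
}

#' Variable and parsimony-informative sites
#'
#' A site is *variable* when its samples resolve to two or more distinct
#' bases -- a single heterozygote suffices. A site is *parsimony-informative*
#' (PIS) when at least two bases each occur in at least two samples, where a
#' heterozygous sample contributes one occurrence of each of its two bases.
#' PIS is always a subset of the variable sites.
#'
#' @param alignment An `als_alignment`.
#' @return Integer vector of positions (reference positions when the
#'   alignment has a coordinate map, alignment columns otherwise), sorted.
#' @export
variable_sites <- function(alignment) {
  .site_scan(alignment, function(exp) length(unique(unlist(exp))) >= 2L)
}

#' @rdname variable_sites
#' @export
parsimony_informative_sites <- function(alignment) {
  .site_scan(alignment, function(exp) {
    occ <- table(unlist(exp))
    sum(occ >= 2L) >= 2L
  })
}

.site_scan <- function(alignment, predicate) {
  if (nrow(alignment$samples) == 0L)
    stop("alignment is empty", call. = FALSE)
  m <- seq_matrix(alignment)
  if (!is.null(alignment$coord_map)) {
    cols <- alignment$coord_map$alignment_column
    labels <- alignment$coord_map$reference_position
  } else {
    cols <- seq_len(ncol(m))
    labels <- cols
  }
  hit <- vapply(cols, function(j) predicate(.column_expansions(m[, j])),
                logical(1L))
  sort(as.integer(labels[hit]))
}

#' Find species-diagnostic SNPs
#'
#' A position is diagnostic for `target_species` when the target's resolved
#' allele set is non-empty and disjoint from the union of every other
#' species' resolved alleles -- strict disjointness, so one shared
#' heterozygote destroys it. A relaxed *majority* verdict is reported
#' alongside: disjointness recomputed after dropping codes observed in only
#' one sample.
#'
#' @param summaries From [site_summaries()].
#' @param target_species Species label present in the summaries.
#' @return data.frame sorted by position: `reference_position`,
#'   `target_alleles`, `other_alleles`, `verdict`
#'   (`"diagnostic"`/`"not_diagnostic"`), `majority_diagnostic` (logical).
#' @export
find_diagnostic_sites <- function(summaries, target_species) {
  if (!target_species %in% summaries$species)
    stop(sprintf("species '%s' not present", target_species), call. = FALSE)
  if (length(summaries$species) < 2L)
    stop("need >= 2 species", call. = FALSE)
  a <- summaries$alleles
  pos <- sort(unique(a$reference_position))
  cnt <- summaries$counts

  majority_set <- function(p, sp_in) {
    rows <- cnt[cnt$reference_position == p & cnt$count >= 2L &
                  (cnt$species %in% sp_in), , drop = FALSE]
    .resolve_column(rows$code)
  }
  others <- setdiff(summaries$species, target_species)
  res <- lapply(pos, function(p) {
    tgt <- .allele_set(summaries, p, target_species)
    oth <- unique(unlist(lapply(others, function(sp)
      .allele_set(summaries, p, sp))))
    strict <- length(tgt) > 0L && length(oth) > 0L &&
      !any(tgt %in% oth)
    mtgt <- majority_set(p, target_species)
    moth <- majority_set(p, others)
    maj <- length(mtgt) > 0L && length(moth) > 0L && !any(mtgt %in% moth)
    data.frame(reference_position = p,
               target_alleles = paste(sort(tgt), collapse = "|"),
               other_alleles = paste(sort(oth), collapse = "|"),
               verdict = if (strict) "diagnostic" else "not_diagnostic",
               majority_diagnostic = maj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Positions where two species' allele sets are disjoint
#'
#' Symmetric in its species arguments; positions where either species has no
#' observed base (all gap/N) are never reported.
#'
#' @param summaries From [site_summaries()].
#' @param species_a,species_b Species labels.
#' @return data.frame `reference_position`, `alleles_a`, `alleles_b`.
#' @export
pairwise_difference_table <- function(summaries, species_a, species_b) {
  for (sp in c(species_a, species_b))
    if (!sp %in% summaries$species)
      stop(sprintf("species '%s' not present", sp), call. = FALSE)
  pos <- sort(unique(summaries$alleles$reference_position))
  rows <- lapply(pos, function(p) {
    sa <- .allele_set(summaries, p, species_a)
    sb <- .allele_set(summaries, p, species_b)
    if (length(sa) && length(sb) && !any(sa %in% sb))
      data.frame(reference_position = p,
                 alleles_a = paste(sort(sa), collapse = "|"),
                 alleles_b = paste(sort(sb), collapse = "|"),
                 stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(reference_position = integer(0),
                      alleles_a = character(0), alleles_b = character(0)))
  do.call(rbind, rows)
}
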