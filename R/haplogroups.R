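# Multi-locus haplotype grouping. Within A. tuberculatus the ALS interval
# 1770-1794 carries four polymorphic positions whose homozygous combinations
# (e.g. ATCA, ATCG, TAAG) structure the species; heterozygous individuals are
# pooled rather than forced into a nearest homozygous group.

#' Define a haplotype locus set
#'
#' @param positions Strictly increasing reference positions; default the four
#'   polymorphic ALS positions in the 1770-1794 interval.
#' @param species_scope Optional species label restricting which samples are
#'   grouped (default: all samples).
#' @return List of class `als_locus_set`.
#' @export
haplo_locus_set <- function(positions = c(1770L, 1776L, 1782L, 1794L),
                            species_scope = NULL) {
  positions <- as.integer(positions)
  if (any(diff(positions) <= 0L))
    stop("locus positions must be strictly increasing", call. = FALSE)
  structure(list(positions = positions, species_scope = species_scope),
            class = "als_locus_set")
}

#' Assign one sample to a haplotype group
#'
#' An unambiguous genotype over the loci is its own (homozygous) group label,
#' the concatenated bases. Any two-base ambiguity code puts the sample in the
#' pooled `"heterozygous"` class with all phase-consistent haplotype strings
#' listed. A gap or a 3-/4-fold code at any locus yields group `"other"`.
#'
#' @param alignment An `als_alignment` with a coordinate map.
#' @param sample_id Sample to assign.
#' @param locus_set From [haplo_locus_set()]; unmapped loci are a
#'   configuration error.
#' @return data.frame row: `sample_id`, `species`, `origin`, `genotype`,
#'   `group`, `compatible_haplotypes` (comma-joined), `reason`.
#' @export
assign_haplogroup <- function(alignment, sample_id,
                              locus_set = haplo_locus_set()) {
  cols <- ref_to_col(alignment, locus_set$positions)
  i <- match(sample_id, alignment$samples$sample_id)
  if (is.na(i)) stop(sprintf("unknown sample '%s'", sample_id), call. = FALSE)
  s <- alignment$samples[i, ]
  g <- strsplit(s$sequence, "", fixed = TRUE)[[1L]][cols]
  genotype <- paste(g, collapse = "")
  row <- function(group, compatible, reason = "")
    data.frame(sample_id = s$sample_id, species = s$species,
               origin = s$origin, genotype = genotype, group = group,
               compatible_haplotypes = paste(compatible, collapse = ","),
               reason = reason, stringsAsFactors = FALSE)
  if (any(g == "-"))
    return(row("other", character(0), "gap at haplotype locus"))
  exp <- lapply(g, expand_iupac)
  if (any(lengths(exp) > 2L))
    return(row("other", character(0), ">2-fold ambiguity at haplotype locus"))
  if (all(lengths(exp) == 1L))
    return(row(genotype, genotype))
  combos <- do.call(expand.grid, c(exp, stringsAsFactors = FALSE))
  haps <- sort(apply(combos, 1L, paste, collapse = ""))
  row("heterozygous", haps)
}

#' Haplotype-group membership and cross-tabulation
#'
#' @inheritParams assign_haplogroup
#' @return List with `assignments` (one row per scoped sample, from
#'   [assign_haplogroup()]) and `table` (counts per `group` x `species` x
#'   `origin`, sorted by group then origin). Scoping to a species with no
#'   samples warns and returns empty tables.
#' @export
haplogroup_table <- function(alignment, locus_set = haplo_locus_set()) {
  s <- alignment$samples
  ids <- if (is.null(locus_set$species_scope)) s$sample_id else
    s$sample_id[s$species == locus_set$species_scope]
  if (!length(ids)) {
    warning("no samples in species scope '", locus_set$species_scope, "'",
            call. = FALSE)
    return(list(assignments = data.frame(), table = data.frame()))
  }
  assignments <- do.call(rbind, lapply(ids, assign_haplogroup,
                                       alignment = alignment,
                                       locus_set = locus_set))
  agg <- stats::aggregate(list(n = assignments$sample_id),
                          by = list(group = assignments$group,
                                    species = assignments$species,
                                    origin = assignments$origin),
                          FUN = length)
  agg <- agg[order(agg$group, agg$origin), , drop = FALSE]
  rownames(agg) <- NULL
  list(assignments = assignments, table = agg)
}
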