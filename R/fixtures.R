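# Worked-example fixtures: the no-randomness "paper-fixture" mode of the data
# generator. Two published summary tables are transcribed as plain-text TSVs
# under inst/extdata and re-inflated into alignments here, so acceptance tests
# and synthetic tests share one harness.

.extdata <- function(file)
  system.file("extdata", file, package = "alsdiag", mustWork = TRUE)

#' The 25-sample ALS resistance worked example
#'
#' Re-inflates the transcribed worked-example genotype table (25 diploid
#' samples x 4 catalog codons, heterozygotes as IUPAC codes) into a full
#' alignment on the ALS reference frame 349..2016: catalog codons carry the
#' recorded genotypes, every other catalog codon carries a wild codon, and
#' remaining columns are a fixed neutral background. Per-sample haplotype
#' structure outside the recorded codons is synthetic filler.
#'
#' @return An `als_alignment` with coordinate map (first reference
#'   position 349).
#' @export
resistance_example_alignment <- function() {
  tab <- utils::read.table(.extdata("resistance_worked_example.tsv"),
                           header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "")
  first <- 349L; last <- 2016L
  width <- last - first + 1L
  background <- rep(c("A", "C", "G", "T"), length.out = width)
  catalog <- default_catalog()
  put <- function(chars, start, codon) {
    i <- start - first + 1L
    chars[i:(i + 2L)] <- strsplit(codon, "", fixed = TRUE)[[1L]]
    chars
  }
  for (i in which(!is.na(catalog$codon_start)))
    background <- put(background, catalog$codon_start[[i]],
                      catalog$wild_codons[[i]][[1L]])
  genotype_cols <- c(`122` = "codon122", `197` = "codon197",
                     `574` = "codon574", `653` = "codon653")
  starts <- catalog$codon_start[match(as.integer(names(genotype_cols)),
                                      catalog$aa_number)]
  seqs <- vapply(seq_len(nrow(tab)), function(r) {
    chars <- background
    for (k in seq_along(genotype_cols))
      chars <- put(chars, starts[[k]], tab[[genotype_cols[[k]]]][[r]])
    paste(chars, collapse = "")
  }, "")
  aln <- als_alignment(sample_id = tab$sample_id, species = tab$species,
                       origin = tab$origin, sequence = seqs,
                       region_name = "ALS")
  set_coord_map(aln, reference_sample = tab$sample_id[[1L]],
                first_reference_position = first)
}

#' The per-species SNP worked example
#'
#' Re-inflates the transcribed per-species site-summary table (41 ALS
#' positions x 6 similar species, cells like `"C8/T4/Y12"`) into an alignment
#' whose [site_summaries()] reproduce every printed cell. Cells without
#' explicit counts split the species' sample count evenly (one unnumbered
#' code takes the remainder). A few printed rows imply one more sample than
#' the table header (a transcription artifact of the source); those extra
#' samples carry gaps at every other position so no printed count is
#' disturbed. Because each column is filled independently, per-sample
#' haplotypes in this fixture are not meaningful -- it is a site-level
#' fixture.
#'
#' @param region `"ALS-CAD"`, `"ALS-BE"`, or `"both"` (default).
#' @return An `als_alignment` (columns are the transcribed positions only)
#'   with an explicit coordinate map.
#' @export
species_snp_example_alignment <- function(region = "both") {
  tab <- utils::read.table(.extdata("species_snp_worked_example.tsv"),
                           header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (region != "both") tab <- tab[tab$region == region, , drop = FALSE]
  raw_names <- names(tab)[-(1:2)]
  species <- trimws(sub("\\([0-9]+\\)$", "", raw_names))
  declared_n <- as.integer(sub("^.*\\(([0-9]+)\\)$", "\\1", raw_names))
  names(tab)[-(1:2)] <- species
  positions <- as.integer(tab$position)

  parse_cell <- function(cell) {
    parts <- strsplit(cell, "/", fixed = TRUE)[[1L]]
    code <- sub("[0-9]+$", "", parts)
    n <- suppressWarnings(as.integer(sub("^[A-Z]", "", parts)))
    data.frame(code = code, count = n, stringsAsFactors = FALSE)
  }
  cells <- lapply(species, function(sp) lapply(tab[[sp]], parse_cell))
  names(cells) <- species
  # sample coverage differs between the two amplicons, so the realized
  # per-species sample count is computed per region: max over that region's
  # positions of the implied minimum (explicit counts + 1 per unnumbered
  # code), floored at the declared header count
  implied <- function(d) sum(d$count, na.rm = TRUE) + sum(is.na(d$count))
  region_of <- tab$region
  n_sp_region <- lapply(unique(region_of), function(rg) {
    v <- vapply(seq_along(species), function(k)
      max(declared_n[[k]],
          vapply(cells[[species[[k]]]][region_of == rg], implied,
                 integer(1L))), integer(1L))
    stats::setNames(v, species)
  })
  names(n_sp_region) <- unique(region_of)
  n_sp <- vapply(species, function(sp)
    max(vapply(n_sp_region, `[[`, integer(1L), sp)), integer(1L))

  columns <- lapply(species, function(sp) {
    n_total <- n_sp[[sp]]
    vapply(seq_len(nrow(tab)), function(r) {
      d <- cells[[sp]][[r]]
      n <- n_sp_region[[region_of[[r]]]][[sp]]
      free <- which(is.na(d$count))
      rem <- n - sum(d$count, na.rm = TRUE)
      if (length(free)) {
        share <- rem %/% length(free)
        d$count[free] <- share
        d$count[free[seq_len(rem - share * length(free))]] <- share + 1L
      }
      paste(c(rep(d$code, d$count), rep("-", n_total - sum(d$count))),
            collapse = "")
    }, "")
  })
  names(columns) <- species

  samples <- do.call(rbind, lapply(species, function(sp) {
    n <- n_sp[[sp]]
    m <- do.call(cbind, strsplit(columns[[sp]], "", fixed = TRUE))
    data.frame(sample_id = sprintf("%s_%02d", gsub("[ .]+", "_", sp),
                                   seq_len(n)),
               species = sp, origin = "",
               sequence = apply(m, 1L, paste, collapse = ""),
               stringsAsFactors = FALSE)
  }))
  aln <- als_alignment(samples$sample_id, samples$species, samples$origin,
                       samples$sequence, region_name = region)
  aln$coord_map <- data.frame(alignment_column = seq_along(positions),
                              reference_position = positions)
  aln
}
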