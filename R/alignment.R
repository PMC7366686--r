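# Alignment container and I/O. One `als_alignment` bundles the sample table
# (id, species, origin, sequence -- every sequence in one shared coordinate
# frame) with an optional reference coordinate map, so that positions printed
# in the literature (e.g. ALS 349..2016) address alignment columns directly.

#' Construct an alignment of IUPAC-coded samples
#'
#' @param sample_id,species,origin,sequence Parallel character vectors; one
#'   entry per sample. Sequences may contain IUPAC ambiguity codes and `-`,
#'   are case-normalised to upper case, and must share one length.
#' @param region_name Label for the sequenced region (e.g. `"ITS"`,
#'   `"ALS-BE"`).
#' @param coord_map Optional coordinate map from [build_coord_map()].
#' @return An object of class `als_alignment`: a list with elements
#'   `samples` (data.frame), `region_name`, `coord_map`.
#' @export
als_alignment <- function(sample_id, species = "", origin = "",
                          sequence, region_name = "region",
                          coord_map = NULL) {
  n <- length(sample_id)
  samples <- data.frame(
    sample_id = as.character(sample_id),
    species   = rep_len(as.character(species), n),
    origin    = rep_len(as.character(origin), n),
    sequence  = toupper(as.character(sequence)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in alignment: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  widths <- nchar(samples$sequence)
  if (n > 0L && length(unique(widths)) != 1L)
    stop(sprintf("ragged alignment: sequence lengths %s",
                 paste(sort(unique(widths)), collapse = ", ")), call. = FALSE)
  .check_alphabet(samples$sequence, samples$sample_id)
  structure(list(samples = samples, region_name = region_name,
                 coord_map = coord_map),
            class = "als_alignment")
}

.check_alphabet <- function(seqs, ids) {
  ok <- paste(iupac_alphabet(), collapse = "")
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", ok), seqs[[i]])
    if (bad > 0L)
      stop(sprintf("illegal character '%s' in sample '%s' at column %d",
                   substr(seqs[[i]], bad, bad), ids[[i]], bad), call. = FALSE)
  }
}

#' @export
print.als_alignment <- function(x, ...) {
  cat(sprintf("<als_alignment> region '%s': %d samples x %d columns",
              x$region_name, nrow(x$samples), alignment_width(x)),
      if (!is.null(x$coord_map)) sprintf(", %d mapped reference positions",
                                         nrow(x$coord_map)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Alignment width (number of columns)
#' @param alignment An `als_alignment`.
#' @export
alignment_width <- function(alignment) {
  if (nrow(alignment$samples) == 0L) return(0L)
  nchar(alignment$samples$sequence[[1L]])
}

# samples x columns character matrix; rownames are sample ids
seq_matrix <- function(alignment) {
  s <- alignment$samples
  m <- do.call(rbind, strsplit(s$sequence, "", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(0), 0, 0)
  rownames(m) <- s$sample_id
  m
}

#' Read an aligned FASTA file
#'
#' Headers of the form `sample_id|species|origin` carry metadata; missing
#' fields are tolerated. A metadata TSV (columns `sample_id`, `species`,
#' `origin`), when supplied, is the single source of truth and overrides
#' header-derived fields.
#'
#' @param path FASTA file of equal-length IUPAC sequences.
#' @param metadata Optional path to a metadata TSV, or a data.frame.
#' @param region_name Region label stored on the alignment.
#' @return An `als_alignment` (without a coordinate map).
#' @export
read_fasta <- function(path, metadata = NULL, region_name = "region") {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  field <- function(k) vapply(parts, function(p) {
    v <- if (length(p) >= k) trimws(p[[k]]) else ""
    if (is.na(v)) "" else v
  }, "")
  aln <- als_alignment(sample_id = field(1L), species = field(2L),
                       origin = field(3L),
                       sequence = as.character(set),
                       region_name = region_name)
  if (!is.null(metadata)) aln <- apply_metadata(aln, metadata)
  message(sprintf("read %d aligned records (%d columns) from %s",
                  nrow(aln$samples), alignment_width(aln), path))
  aln
}

#' Write an alignment to FASTA
#'
#' Metadata are serialised back into `sample_id|species|origin` headers, so
#' `read_fasta(write_fasta(aln, f))` round-trips records exactly.
#'
#' @param alignment An `als_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  s <- alignment$samples
  set <- Biostrings::BStringSet(s$sequence)
  names(set) <- paste(s$sample_id, s$species, s$origin, sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' @param path TSV with header columns `sample_id`, `species`, `origin`
#'   (`origin` optional).
#' @return data.frame with those three columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("sample_id", "species")
  if (!all(need %in% names(md)))
    stop("metadata must have columns sample_id and species", call. = FALSE)
  if (is.null(md$origin)) md$origin <- ""
  message(sprintf("read metadata for %d samples from %s", nrow(md), path))
  md[, c("sample_id", "species", "origin")]
}

#' Override alignment metadata from a table
#' @param alignment An `als_alignment`.
#' @param metadata data.frame or TSV path as in [read_metadata()].
#' @return The alignment with `species`/`origin` replaced for listed samples.
#' @export
apply_metadata <- function(alignment, metadata) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.null(metadata$origin)) metadata$origin <- ""
  idx <- match(alignment$samples$sample_id, metadata$sample_id)
  hit <- !is.na(idx)
  alignment$samples$species[hit] <- metadata$species[idx[hit]]
  alignment$samples$origin[hit] <- metadata$origin[idx[hit]]
  alignment
}

#' Build a reference coordinate map from a gap-bearing reference sample
#'
#' Non-gap columns of the reference are numbered consecutively from
#' `first_reference_position`; gap columns stay unmapped. Coordinates are
#' 1-based and closed on both axes, matching how target-site positions are
#' reported in the ALS literature.
#'
#' @param alignment An `als_alignment`.
#' @param reference_sample `sample_id` of the reference row.
#' @param first_reference_position Reference position of the reference's
#'   first non-gap column.
#' @return data.frame with columns `alignment_column`, `reference_position`,
#'   strictly increasing in both.
#' @export
build_coord_map <- function(alignment, reference_sample,
                            first_reference_position = 1L) {
  s <- alignment$samples
  i <- match(reference_sample, s$sample_id)
  if (is.na(i))
    stop(sprintf("reference sample '%s' not in alignment", reference_sample),
         call. = FALSE)
  chars <- strsplit(s$sequence[[i]], "", fixed = TRUE)[[1L]]
  cols <- which(chars != "-")
  data.frame(alignment_column = cols,
             reference_position = seq_along(cols) - 1L +
               as.integer(first_reference_position))
}

#' Attach a coordinate map to an alignment
#' @inheritParams build_coord_map
#' @param coord_map A map from [build_coord_map()], or `NULL` to build one
#'   from `reference_sample`.
#' @return The alignment with `coord_map` set.
#' @export
set_coord_map <- function(alignment, coord_map = NULL, reference_sample = NULL,
                          first_reference_position = 1L) {
  if (is.null(coord_map))
    coord_map <- build_coord_map(alignment, reference_sample,
                                 first_reference_position)
  stopifnot(all(diff(coord_map$alignment_column) > 0),
            all(diff(coord_map$reference_position) > 0))
  alignment$coord_map <- coord_map
  alignment
}

# reference positions -> alignment columns (error on unmapped)
ref_to_col <- function(alignment, positions) {
  cm <- alignment$coord_map
  if (is.null(cm)) stop("alignment has no coordinate map", call. = FALSE)
  idx <- match(positions, cm$reference_position)
  if (anyNA(idx))
    stop("reference position(s) not mapped: ",
         paste(positions[is.na(idx)], collapse = ", "), call. = FALSE)
  cm$alignment_column[idx]
}
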