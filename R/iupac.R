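# IUPAC nucleotide algebra. In diploid Sanger data a two-base ambiguity code
# at one position is read as a heterozygote, so expansion/collapse is the
# primitive every downstream module leans on.

.IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_ALPHABET <- c(names(.IUPAC_MAP), "-")

# reverse lookup keyed by sorted base set, e.g. "G|T" -> "K"
.IUPAC_REV <- local({
  keys <- vapply(.IUPAC_MAP, function(b) paste(sort(b), collapse = "|"), "")
  stats::setNames(names(.IUPAC_MAP), keys)
})

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code Single character in the IUPAC nucleotide alphabet
#'   (`A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N`). Gaps are not expandable.
#' @return Character vector of the unambiguous bases the code denotes
#'   (`N` expands to all four).
#' @examples
#' expand_iupac("K") # G, T
#' expand_iupac("A") # A
#' @seealso [collapse_to_iupac()] for the inverse.
#' @export
expand_iupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("`code` must be a single character", call. = FALSE)
  code <- toupper(code)
  if (code == "-")
    stop("gap character '-' has no base expansion", call. = FALSE)
  bases <- .IUPAC_MAP[[code]]
  if (is.null(bases))
    stop(sprintf("unknown nucleotide code '%s'", code), call. = FALSE)
  bases
}

#' Collapse a set of bases to the unique IUPAC code
#'
#' Inverse of [expand_iupac()]: `expand_iupac(collapse_to_iupac(S))`
#' equals `S` for every non-empty subset of `{A,C,G,T}`.
#'
#' @param bases Character vector, a non-empty subset of `A,C,G,T`
#'   (duplicates tolerated).
#' @return Single IUPAC character.
#' @examples
#' collapse_to_iupac(c("A", "T")) # "W"
#' collapse_to_iupac("C")         # "C"
#' @export
collapse_to_iupac <- function(bases) {
  bases <- unique(toupper(bases))
  if (length(bases) == 0L)
    stop("cannot collapse an empty base set", call. = FALSE)
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("base set may only contain A, C, G, T", call. = FALSE)
  unname(.IUPAC_REV[[paste(sort(bases), collapse = "|")]])
}

#' @rdname expand_iupac
#' @details `iupac_alphabet()` returns the full stored alphabet, gap included.
#' @export
iupac_alphabet <- function() .IUPAC_ALPHABET

# Vectorised resolved-base sets for one alignment column. Gaps and (by the
# package-wide missing-data rule) N contribute nothing.
.resolve_column <- function(chars, drop_n = TRUE) {
  chars <- chars[chars != "-"]
  if (drop_n) chars <- chars[chars != "N"]
  if (length(chars) == 0L) return(character(0))
  unique(unlist(.IUPAC_MAP[chars], use.names = FALSE))
}
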