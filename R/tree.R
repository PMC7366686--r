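# Tree input and patristic distances. Trees are supplied, never inferred:
# the package only walks branch lengths.

#' Read a newick tree
#'
#' Wraps [ape::read.tree()] with the validation this package relies on:
#' unique leaf labels, non-negative branch lengths. Edges without a branch
#' length default to 0 with a warning.
#'
#' @param path Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("unparseable newick in ", path, call. = FALSE)
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object (e.g. parsed from a string).
#' @export
validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0", call. = FALSE)
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning(sum(is.na(tree$edge.length)),
            " missing branch length(s) defaulted to 0", call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  tree
}

#' Mean patristic distance within and between species
#'
#' The patristic distance between two leaves is the sum of branch lengths on
#' the path joining them. Every unordered leaf pair is classified as
#' intraspecific (same species label) or interspecific; species represented by
#' a single leaf contribute no intraspecific pairs.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param metadata data.frame mapping `sample_id` to `species`. Leaves whose
#'   label already *is* a species in `metadata$species` are accepted too.
#' @return List with `mean_intraspecific`, `mean_interspecific`,
#'   `n_intra_pairs`, `n_inter_pairs` (means are `NaN` when a class has no
#'   pairs).
#' @export
patristic_summary <- function(tree, metadata) {
  tree <- validate_tree(tree)
  lab <- tree$tip.label
  sp <- metadata$species[match(lab, metadata$sample_id)]
  sp[is.na(sp) & lab %in% metadata$species] <- lab[is.na(sp) & lab %in% metadata$species]
  if (anyNA(sp))
    stop("leaf without species metadata: ",
         paste(lab[is.na(sp)], collapse = ", "), call. = FALSE)
  d <- ape::dist.nodes(tree)[seq_along(lab), seq_along(lab), drop = FALSE]
  same <- outer(sp, sp, "==")
  ut <- upper.tri(d)
  intra <- d[ut & same]
  inter <- d[ut & !same]
  list(mean_intraspecific = mean(intra),
       mean_interspecific = mean(inter),
       n_intra_pairs = length(intra),
       n_inter_pairs = length(inter))
}
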