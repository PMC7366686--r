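# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (own IUPAC table, own path enumeration) so the
# dual-route checks stay dual.

# oracle-local IUPAC expansion (never calls the package)
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# all-pairs patristic distances by explicit path enumeration over the edge
# list: DFS from each tip along an adjacency list, summing branch lengths
oracle_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  nodes <- max(tree$edge)
  adj <- vector("list", nodes)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1L]; b <- tree$edge[k, 2L]; w <- tree$edge.length[[k]]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  dist_from <- function(start) {
    d <- rep(NA_real_, nodes); d[[start]] <- 0
    stack <- start
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1L]
        if (is.na(d[[u]])) { d[[u]] <- d[[v]] + adj[[v]][k, 2L]; stack <- c(stack, u) }
      }
    }
    d[seq_len(n_tip)]
  }
  m <- vapply(seq_len(n_tip), dist_from, numeric(n_tip))
  dimnames(m) <- list(tree$tip.label, tree$tip.label)
  m
}

# intra/inter means by explicit double loop over leaf pairs
oracle_distance_summary <- function(tree, species) {
  m <- oracle_patristic(tree)
  sp <- species[tree$tip.label]
  intra <- c(); inter <- c()
  n <- length(tree$tip.label)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sp[[i]] == sp[[j]]) intra <- c(intra, m[i, j]) else
      inter <- c(inter, m[i, j])
  }
  list(mean_intraspecific = mean(intra), mean_interspecific = mean(inter),
       n_intra_pairs = length(intra), n_inter_pairs = length(inter))
}

# diagnostic verdicts by explicit per-column set intersection on the raw
# character matrix (rows = samples)
oracle_diagnostic <- function(mat, species, target) {
  vapply(seq_len(ncol(mat)), function(j) {
    sets <- function(rows) {
      ch <- mat[rows, j]
      ch <- ch[!ch %in% c("-", "N")]
      unique(unlist(ORACLE_IUPAC[ch]))
    }
    tgt <- sets(species == target)
    oth <- sets(species != target)
    length(tgt) > 0 && length(oth) > 0 && length(intersect(tgt, oth)) == 0
  }, logical(1L))
}

# variable / PIS verdicts for one column of IUPAC characters
oracle_variable <- function(column) {
  ch <- column[!column %in% c("-", "N")]
  length(unique(unlist(ORACLE_IUPAC[ch]))) >= 2L
}
oracle_pis <- function(column) {
  ch <- column[!column %in% c("-", "N")]
  occ <- table(unlist(ORACLE_IUPAC[ch]))
  sum(occ >= 2L) >= 2L
}

# every unordered codon pair consistent with a 3-character IUPAC genotype,
# by scanning all 64 x 64 codon pairs
oracle_allele_pairs <- function(genotype) {
  g <- strsplit(genotype, "")[[1L]]
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T"),
                              stringsAsFactors = FALSE)[, 3:1],
                  1L, paste, collapse = "")
  ok <- list()
  for (c1 in codons) for (c2 in codons) {
    if (c1 > c2) next
    match_all <- TRUE
    for (i in 1:3) {
      pair <- unique(c(substr(c1, i, i), substr(c2, i, i)))
      if (!setequal(pair, ORACLE_IUPAC[[g[[i]]]])) { match_all <- FALSE; break }
    }
    if (match_all) ok[[length(ok) + 1L]] <- c(c1, c2)
  }
  ok
}

# seeded random alignment with species labels; IUPAC-rich columns
random_alignment <- function(n_samples, n_cols, n_species = 2L,
                             codes = c("A","C","G","T","R","Y","W","K","M","-")) {
  m <- matrix(sample(codes, n_samples * n_cols, replace = TRUE,
                     prob = c(rep(6, 4), rep(1, 5), 0.5)),
              nrow = n_samples)
  species <- paste0("sp", rep_len(seq_len(n_species), n_samples))
  als_alignment(sample_id = sprintf("s%03d", seq_len(n_samples)),
                species = species,
                sequence = apply(m, 1L, paste, collapse = ""))
}

with_coord_identity <- function(aln, first = 1L) {
  aln$coord_map <- data.frame(
    alignment_column = seq_len(alignment_width(aln)),
    reference_position = seq_len(alignment_width(aln)) + first - 1L)
  aln
}

random_tree <- function(n_leaves) {
  tree <- ape::rtree(n_leaves, br = function(k) stats::runif(k, 0, 0.1))
  tree$tip.label <- sprintf("L%02d", seq_len(n_leaves))
  tree
}
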