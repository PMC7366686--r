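# Deterministic synthetic-data generator. Emulates what the analysis assumes
# about multi-species Sanger amplicon data: fixed interspecific SNPs,
# intraspecific polymorphism with heterozygotes written as IUPAC codes,
# resistance mutations injected at catalog codons as wild+mutant diplotypes,
# multi-locus haplotype groups, and a species-clustered tree. Every draw is
# seeded; per-stage substreams are derived from the one config seed so adding
# a stage never perturbs earlier draws.

#' Build a simulation configuration
#'
#' Defaults state a sampling design of the kind the package targets: six
#' similar amaranth species with border-interception sample sizes, a shared
#' ALS reference frame 349..2016, a handful of fixed species-diagnostic SNPs,
#' intraspecific polymorphism inside the most-sampled species, resistance
#' injections at catalog codons at moderate frequencies, and three haplotype
#' groups over the 1770-1794 interval.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param species data.frame `species`, `population`, `n` (samples per
#'   species x population cell).
#' @param first_position,length Reference frame: first reference position and
#'   number of columns (no gaps are simulated).
#' @param diagnostic_sites data.frame `position`, `target_species`,
#'   `target_base`, `other_base`: the target species is fixed for
#'   `target_base`, every other species for `other_base`.
#' @param poly_sites data.frame `position`, `species` (`NA` = all),
#'   `major`, `minor`, `het_freq`, `minor_freq`: per sample the site is
#'   heterozygous (IUPAC collapse of major+minor) with probability
#'   `het_freq`, otherwise homozygous minor with probability `minor_freq`,
#'   else homozygous major.
#' @param injections data.frame `species`, `population` (`NA` = all
#'   populations), `aa_number`, `to_aa`, `zygosity`, `frequency`: each scoped
#'   sample receives the substitution with the given probability;
#'   heterozygotes are written as the IUPAC collapse of one wild and one
#'   mutant codon.
#' @param haplotypes `NULL`, or list `positions`, `species`, `freqs` (named
#'   numeric, names are haplotype strings over the loci; two haplotypes are
#'   drawn per sample). Loci of non-scoped species carry the first haplotype.
#' @param catalog Resistance catalog supplying codon coordinates/wild codons.
#' @param tree_between,tree_within Patristic depth parameters: species crown
#'   groups hang on branches ~`tree_between`, leaves on branches
#'   ~`tree_within`, so intraspecific distances sit well below interspecific
#'   ones by construction.
#' @return List of class `als_sim_config`.
#' @export
sim_config <- function(seed = 20200716L,
                       species = NULL, first_position = 349L, length = 1668L,
                       diagnostic_sites = NULL, poly_sites = NULL,
                       injections = NULL, haplotypes = NULL,
                       catalog = default_catalog(),
                       tree_between = 0.013, tree_within = 0.0008) {
  if (is.null(species))
    species <- data.frame(
      species = c(rep("A. tuberculatus", 3L), rep("A. palmeri", 2L),
                  "A. arenicola", "A. spinosus", "A. dubius", "A. hybridus"),
      population = c("Fujian", "Jiangsu", "Shandong", "Beijing", "Jiangsu",
                     "Hebei", "Guangdong", "Yunnan", "Hebei"),
      n = c(10L, 10L, 9L, 20L, 9L, 1L, 8L, 1L, 2L),
      stringsAsFactors = FALSE)
  if (is.null(diagnostic_sites))
    diagnostic_sites <- data.frame(
      position = c(351L, 465L, 516L, 636L, 1435L),
      target_species = c(rep("A. tuberculatus", 4L), "A. hybridus"),
      target_base = c("T", "T", "C", "A", "T"),
      other_base = c("A", "C", "T", "C", "G"),
      stringsAsFactors = FALSE)
  if (is.null(poly_sites))
    poly_sites <- data.frame(
      position = c(1482L, 1611L, 1974L),
      species = "A. tuberculatus",
      major = c("C", "T", "C"), minor = c("T", "C", "T"),
      het_freq = c(0.5, 0.45, 0.2), minor_freq = c(0.35, 0.5, 0.1),
      stringsAsFactors = FALSE)
  if (is.null(injections))
    injections <- data.frame(
      species = c("A. tuberculatus", "A. tuberculatus", "A. tuberculatus",
                  "A. palmeri", "A. palmeri"),
      population = c("Fujian", NA, "Jiangsu", NA, NA),
      aa_number = c(122L, 574L, 653L, 197L, 574L),
      to_aa = c("N", "L", "T", "S", "L"),
      zygosity = c("homozygous", "heterozygous", "heterozygous",
                   "heterozygous", "heterozygous"),
      frequency = c(0.4, 0.3, 0.2, 0.2, 0.15),
      stringsAsFactors = FALSE)
  if (is.null(haplotypes))
    haplotypes <- list(positions = c(1770L, 1776L, 1782L, 1794L),
                       species = "A. tuberculatus",
                       freqs = c(ATCA = 0.4, ATCG = 0.3, TAAG = 0.3))
  cfg <- structure(list(seed = as.integer(seed), species = species,
                        first_position = as.integer(first_position),
                        length = as.integer(length),
                        diagnostic_sites = diagnostic_sites,
                        poly_sites = poly_sites, injections = injections,
                        haplotypes = haplotypes, catalog = catalog,
                        tree_between = tree_between,
                        tree_within = tree_within),
                   class = "als_sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config An `als_sim_config`.
#' @export
validate_sim_config <- function(config) {
  problems <- character(0)
  last <- config$first_position + config$length - 1L
  chk_pos <- function(p, what)
    if (length(p) && (any(p < config$first_position) || any(p > last)))
      problems <<- c(problems, sprintf("%s position(s) outside frame", what))
  chk_pos(config$diagnostic_sites$position, "diagnostic")
  chk_pos(config$poly_sites$position, "polymorphic")
  if (!is.null(config$haplotypes)) {
    chk_pos(config$haplotypes$positions, "haplotype")
    f <- config$haplotypes$freqs
    if (abs(sum(f) - 1) > 1e-8 || any(f < 0))
      problems <- c(problems, "haplotype freqs must be >= 0 and sum to 1")
    if (any(nchar(names(f)) != length(config$haplotypes$positions)))
      problems <- c(problems, "haplotype strings must match locus count")
  }
  fr <- c(config$poly_sites$het_freq, config$poly_sites$minor_freq,
          config$injections$frequency)
  if (any(fr < 0 | fr > 1)) problems <- c(problems, "frequencies outside [0,1]")
  if (nrow(config$injections)) {
    hit <- match(config$injections$aa_number, config$catalog$aa_number)
    if (anyNA(hit) || anyNA(config$catalog$codon_start[hit]))
      problems <- c(problems,
                    "injection references a codon without catalog coordinates")
  }
  if (any(config$species$n < 1L)) problems <- c(problems, "species n must be >= 1")
  if (length(problems))
    stop("invalid simulation config:\n- ", paste(problems, collapse = "\n- "),
         call. = FALSE)
  config
}

# stage substreams: independent-looking seeds derived from the master seed
.stage_seed <- function(seed, stage)
  (as.double(seed) * 7919 + stage * 104729) %% 2147483647

#' Simulate an aligned dataset with ground truth
#'
#' Deterministic given `config$seed`: identical configs give byte-identical
#' outputs. Heterozygous sites are written as the [collapse_to_iupac()] of
#' the two alleles; resistant heterozygotes are wild-codon + mutant-codon
#' diplotypes (the mutant codon is the wild codon with the minimal base
#' changes reaching the target amino acid).
#'
#' @param config From [sim_config()].
#' @param dir Optional directory; when given, writes `alignment.fasta`,
#'   `metadata.tsv`, `tree.nwk` and `truth.json` (documented layout: `samples`
#'   with species/population/haplogroup, `injections` keyed by
#'   sample_id/aa_number, `diagnostic_sites`).
#' @return List of class `als_sim`: `alignment` (with coordinate map),
#'   `metadata`, `tree` ([ape::phylo]), `truth` (list of data.frames), and
#'   `paths` when `dir` was given.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  config <- validate_sim_config(config)
  first <- config$first_position
  width <- config$length
  sp_tab <- config$species

  meta <- do.call(rbind, lapply(seq_len(nrow(sp_tab)), function(i) {
    data.frame(species = sp_tab$species[[i]],
               population = sp_tab$population[[i]],
               sample_id = sprintf("%s_%s_%02d",
                                   gsub("[ .]+", "", sp_tab$species[[i]]),
                                   sp_tab$population[[i]],
                                   seq_len(sp_tab$n[[i]])),
               stringsAsFactors = FALSE)
  }))
  n <- nrow(meta)

  # stage 1: shared background, catalog codons forced to wild
  set.seed(.stage_seed(config$seed, 1))
  background <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
  at <- function(pos) pos - first + 1L
  for (i in seq_len(nrow(config$catalog))) {
    st <- config$catalog$codon_start[[i]]
    if (!is.na(st) && st >= first && st + 2L <= first + width - 1L)
      background[at(st) + 0:2] <-
        strsplit(config$catalog$wild_codons[[i]][[1L]], "")[[1L]]
  }
  if (!is.null(config$haplotypes)) {
    h1 <- strsplit(names(config$haplotypes$freqs)[[1L]], "")[[1L]]
    background[at(config$haplotypes$positions)] <- h1
  }
  seqs <- matrix(rep(background, each = n), nrow = n)

  # stage 2: fixed interspecific (diagnostic) sites -- no randomness
  ds <- config$diagnostic_sites
  for (i in seq_len(nrow(ds))) {
    tgt <- meta$species == ds$target_species[[i]]
    seqs[tgt, at(ds$position[[i]])] <- ds$target_base[[i]]
    seqs[!tgt, at(ds$position[[i]])] <- ds$other_base[[i]]
  }

  # stage 3: intraspecific polymorphism
  set.seed(.stage_seed(config$seed, 3))
  ps <- config$poly_sites
  for (i in seq_len(nrow(ps))) {
    scope <- if (is.na(ps$species[[i]])) rep(TRUE, n) else
      meta$species == ps$species[[i]]
    het <- collapse_to_iupac(c(ps$major[[i]], ps$minor[[i]]))
    for (r in which(scope)) {
      u <- stats::runif(2L)
      seqs[r, at(ps$position[[i]])] <-
        if (u[[1L]] < ps$het_freq[[i]]) het
        else if (u[[2L]] < ps$minor_freq[[i]]) ps$minor[[i]]
        else ps$major[[i]]
    }
  }

  # stage 4: haplotype groups (two haplotypes drawn per scoped sample)
  meta$haplogroup <- NA_character_
  if (!is.null(config$haplotypes)) {
    set.seed(.stage_seed(config$seed, 4))
    hp <- config$haplotypes
    haps <- strsplit(names(hp$freqs), "")
    scope <- which(meta$species == hp$species)
    for (r in scope) {
      pick <- sample(seq_along(haps), 2L, replace = TRUE, prob = hp$freqs)
      g <- mapply(function(a, b) collapse_to_iupac(c(a, b)),
                  haps[[pick[[1L]]]], haps[[pick[[2L]]]])
      seqs[r, at(hp$positions)] <- g
      meta$haplogroup[[r]] <- if (pick[[1L]] == pick[[2L]])
        names(hp$freqs)[[pick[[1L]]]] else "heterozygous"
    }
  }

  # stage 5: resistance injections as wild+mutant diplotypes
  set.seed(.stage_seed(config$seed, 5))
  inj_truth <- list()
  inj <- config$injections
  for (i in seq_len(nrow(inj))) {
    spec <- config$catalog[config$catalog$aa_number == inj$aa_number[[i]], ]
    wild <- spec$wild_codons[[1L]][[1L]]
    mut <- mutant_codon(wild, inj$to_aa[[i]])
    scope <- meta$species == inj$species[[i]] &
      (is.na(inj$population[[i]]) | meta$population == inj$population[[i]])
    for (r in which(scope)) {
      if (stats::runif(1L) >= inj$frequency[[i]]) next
      wchars <- strsplit(wild, "")[[1L]]
      mchars <- strsplit(mut, "")[[1L]]
      g <- if (inj$zygosity[[i]] == "homozygous") mchars else
        mapply(function(a, b) collapse_to_iupac(c(a, b)), wchars, mchars)
      seqs[r, at(spec$codon_start[[1L]]) + 0:2] <- g
      inj_truth[[length(inj_truth) + 1L]] <- data.frame(
        sample_id = meta$sample_id[[r]], aa_number = inj$aa_number[[i]],
        from_aa = spec$wild_aa[[1L]], to_aa = inj$to_aa[[i]],
        zygosity = inj$zygosity[[i]], stringsAsFactors = FALSE)
    }
  }
  inj_truth <- if (length(inj_truth)) do.call(rbind, inj_truth) else
    data.frame(sample_id = character(0), aa_number = integer(0),
               from_aa = character(0), to_aa = character(0),
               zygosity = character(0), stringsAsFactors = FALSE)

  aln <- als_alignment(meta$sample_id, meta$species, meta$population,
                       apply(seqs, 1L, paste, collapse = ""),
                       region_name = "simulated-ALS")
  aln$coord_map <- data.frame(alignment_column = seq_len(width),
                              reference_position = seq_len(width) + first - 1L)

  # stage 6: species-clustered tree
  set.seed(.stage_seed(config$seed, 6))
  tree <- .sim_tree(meta, config$tree_between, config$tree_within)

  truth <- list(samples = meta[, c("sample_id", "species", "population",
                                   "haplogroup")],
                injections = inj_truth,
                diagnostic_sites = ds)
  out <- structure(list(alignment = aln,
                        metadata = data.frame(sample_id = meta$sample_id,
                                              species = meta$species,
                                              origin = meta$population,
                                              stringsAsFactors = FALSE),
                        tree = tree, truth = truth, config = config),
                   class = "als_sim")
  if (!is.null(dir)) out$paths <- write_sim(out, dir)
  out
}

# smallest-edit codon for a target amino acid (ties broken alphabetically)
mutant_codon <- function(wild, to_aa) {
  all_codons <- names(Biostrings::GENETIC_CODE)
  cand <- all_codons[Biostrings::GENETIC_CODE == to_aa]
  if (!length(cand)) stop("no codon encodes '", to_aa, "'", call. = FALSE)
  w <- strsplit(wild, "")[[1L]]
  dist <- vapply(strsplit(cand, ""), function(m) sum(m != w), integer(1L))
  sort(cand[dist == min(dist)])[[1L]]
}

.sim_tree <- function(meta, between, within) {
  jitter <- function(k) stats::runif(k, 0.8, 1.2)
  species <- unique(meta$species)
  clades <- vapply(species, function(sp) {
    ids <- meta$sample_id[meta$species == sp]
    b <- between * jitter(1L)
    if (length(ids) == 1L)
      return(sprintf("%s:%.8f", ids, b + within / 2))
    leaves <- sprintf("%s:%.8f", ids, within / 2 * jitter(length(ids)))
    sprintf("(%s):%.8f", paste(leaves, collapse = ","), b)
  }, "")
  ape::read.tree(text = sprintf("(%s);", paste(clades, collapse = ",")))
}

#' Write a simulated dataset to disk
#' @param sim From [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(dir, "alignment.fasta"),
                metadata = file.path(dir, "metadata.tsv"),
                tree = file.path(dir, "tree.nwk"),
                truth = file.path(dir, "truth.json"))
  write_fasta(sim$alignment, paths$fasta)
  utils::write.table(sim$metadata, paths$metadata, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, paths$tree)
  jsonlite::write_json(sim$truth, paths$truth, dataframe = "rows",
                       auto_unbox = TRUE, na = "null", pretty = TRUE)
  paths
}

#' Score pipeline output against simulator truth
#'
#' Exact-match comparison keyed by `(sample_id, aa_number)` for resistance
#' calls, by position for diagnostic sites, and by `sample_id` for haplotype
#' groups.
#'
#' @param truth `truth` element of an `als_sim` (or the parsed `truth.json`).
#' @param observed For `type = "calls"`: the `calls` data.frame of
#'   [call_dataset()]; `"diagnostics"`: result of [find_diagnostic_sites()]
#'   for one target species (plus `target_species` argument);
#'   `"haplogroups"`: the `assignments` data.frame of [haplogroup_table()].
#' @param type One of `"calls"`, `"diagnostics"`, `"haplogroups"`.
#' @param target_species Required for `type = "diagnostics"`.
#' @return List: `precision`, `recall`, `n_truth`, `n_observed`, and for
#'   calls `zygosity_accuracy` (share of key-matched calls with the injected
#'   zygosity); for haplogroups `accuracy` instead of precision/recall.
#' @export
truth_compare <- function(truth, observed,
                          type = c("calls", "diagnostics", "haplogroups"),
                          target_species = NULL) {
  type <- match.arg(type)
  known_ids <- truth$samples$sample_id
  if (type == "calls") {
    if (nrow(observed) && !all(observed$sample_id %in% known_ids))
      stop("observed calls contain sample ids absent from truth: ",
           paste(setdiff(observed$sample_id, known_ids), collapse = ", "),
           call. = FALSE)
    tkey <- paste(truth$injections$sample_id, truth$injections$aa_number,
                  truth$injections$to_aa)
    okey <- paste(observed$sample_id, observed$aa_number, observed$to_aa)
    matched <- intersect(tkey, okey)
    tz <- truth$injections$zygosity[match(matched, tkey)]
    oz <- observed$zygosity[match(matched, okey)]
    list(precision = if (length(okey)) length(matched) / length(okey) else NaN,
         recall = if (length(tkey)) length(matched) / length(tkey) else NaN,
         zygosity_accuracy = if (length(matched)) mean(tz == oz) else NaN,
         n_truth = length(tkey), n_observed = length(okey))
  } else if (type == "diagnostics") {
    if (is.null(target_species))
      stop("target_species is required for diagnostics", call. = FALSE)
    tpos <- truth$diagnostic_sites$position[
      truth$diagnostic_sites$target_species == target_species]
    opos <- observed$reference_position[observed$verdict == "diagnostic"]
    list(precision = if (length(opos)) mean(opos %in% tpos) else NaN,
         recall = if (length(tpos)) mean(tpos %in% opos) else NaN,
         n_truth = length(tpos), n_observed = length(opos))
  } else {
    if (nrow(observed) && !all(observed$sample_id %in% known_ids))
      stop("observed assignments contain unknown sample ids", call. = FALSE)
    t_grp <- truth$samples$haplogroup
    names(t_grp) <- truth$samples$sample_id
    t_grp <- t_grp[!is.na(t_grp)]
    o_grp <- observed$group[match(names(t_grp), observed$sample_id)]
    list(accuracy = if (length(t_grp)) mean(o_grp == t_grp, na.rm = FALSE)
         else NaN,
         n_truth = length(t_grp), n_observed = nrow(observed))
  }
}
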