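# Synthetic ortholog-family generator.
#
# Emulates the statistical structure of the study inputs: each protein pair
# shares one species tree; the two proteins' branch lengths are the species
# branches scaled by per-protein base rates and per-branch lognormal
# multipliers whose log-scale correlation (rho) encodes shared evolutionary
# rates; topology sharing is a separate axis controlled by NNI perturbation
# of the second protein's tree.  Sequences evolve under the analysis model
# (LG + discrete gamma), so simulated alignments are gap-free.

#' Simulation configuration
#'
#' Defaults describe the study conditions the simulator emulates: ortholog
#' families of 15 species (the typical alignment in the yeast datasets has
#' 12-25 sequences), 300 usable columns (post-filter alignment lengths are a
#' few hundred), gamma shape 0.8 (moderately strong among-site variation,
#' typical for protein families), mean branch length 0.25
#' substitutions/site (giving mean pairwise distances near 1.5, matching
#' divergent eukaryote-wide ortholog sets; lower `divergence_scale` values
#' emulate closely related clades), branch-rate multiplier log-sd 0.5
#' (order-of-magnitude rate variation across lineages), rate correlation
#' 0.9 for interacting pairs, 0 for non-interacting, and shared topologies
#' for both (`n_nni = 0`: non-interacting proteins still share species
#' history).
#'
#' @param n_taxa species per family (>= 3).
#' @param sites_per_protein alignment columns simulated per protein.
#' @param alpha gamma shape used for simulation.
#' @param base_rate_a,base_rate_b per-protein rate scalars.
#' @param rho correlation of per-branch log rate multipliers for
#'   interacting (POS) pairs, in \[0, 1\]; NEG pairs use 0.
#' @param sigma sd of log multipliers (>= 0).
#' @param n_nni NNI moves applied to protein B's tree for NEG pairs
#'   (POS pairs always share the topology).
#' @param divergence_scale mean branch length of the species tree
#'   (exponential branch lengths).
#' @param n_pos_pairs,n_neg_pairs number of interacting / non-interacting
#'   pairs.
#' @param seed master seed; every pair derives its own stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 15L, sites_per_protein = 300L, alpha = 0.8,
                       base_rate_a = 1, base_rate_b = 1,
                       rho = 0.9, sigma = 0.5, n_nni = 0L,
                       divergence_scale = 0.25,
                       n_pos_pairs = 20L, n_neg_pairs = 20L, seed = 1L) {
  stopifnot(n_taxa >= 3L, sites_per_protein >= 1L, alpha > 0,
            rho >= 0, rho <= 1, sigma >= 0, n_nni >= 0L,
            divergence_scale > 0, n_pos_pairs >= 1L, n_neg_pairs >= 1L)
  structure(list(n_taxa = as.integer(n_taxa),
                 sites_per_protein = as.integer(sites_per_protein),
                 alpha = alpha, base_rate_a = base_rate_a,
                 base_rate_b = base_rate_b, rho = rho, sigma = sigma,
                 n_nni = as.integer(n_nni),
                 divergence_scale = divergence_scale,
                 n_pos_pairs = as.integer(n_pos_pairs),
                 n_neg_pairs = as.integer(n_neg_pairs),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a random species tree
#'
#' Random unrooted bifurcating topology, uniform over labelled topologies,
#' with independent exponential branch lengths of mean `divergence_scale`.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param divergence_scale mean branch length (substitutions/site).
#' @param seed RNG seed.
#' @return An unrooted `phylo` with tip labels `sp01`, `sp02`, ...
#' @export
sample_species_tree <- function(n_taxa, divergence_scale = 0.25,
                                seed = NULL) {
  if (n_taxa < 3L) stop("need at least 3 taxa")
  with_seed(seed, {
    tr <- ape::rtopology(n_taxa, rooted = FALSE,
                         br = function(m) stats::rexp(m, rate = 1 / divergence_scale))
    tr$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
    tr
  })
}

#' Derive a pair of protein trees from a species tree
#'
#' Per-branch rate multipliers for the two proteins are drawn from a
#' bivariate lognormal: `log m = sigma * z - sigma^2 / 2` with standard
#' normal `z` of correlation `rho` between the proteins (the mean
#' correction keeps E\[m\] = 1, so expected branch lengths are preserved).
#' Protein trees get branch lengths `species branch * base_rate * m`;
#' protein B's topology is then perturbed by `n_nni` random NNI moves
#' (0 = shared topology).
#'
#' @param species_tree a `phylo`.
#' @param rho log-scale multiplier correlation in \[0, 1\].
#' @param sigma log-scale multiplier sd (>= 0).
#' @param base_rate_a,base_rate_b per-protein rate scalars.
#' @param n_nni topology perturbation moves for protein B.
#' @param seed RNG seed.
#' @return List `(tree_a, tree_b, log_mult_a, log_mult_b)`.
#' @export
derive_pair_trees <- function(species_tree, rho = 0.9, sigma = 0.5,
                              base_rate_a = 1, base_rate_b = 1,
                              n_nni = 0L, seed = NULL) {
  stopifnot(inherits(species_tree, "phylo"), rho >= 0, rho <= 1, sigma >= 0)
  ne <- nrow(species_tree$edge)
  with_seed(seed, {
    za <- stats::rnorm(ne)
    zb <- rho * za + sqrt(1 - rho^2) * stats::rnorm(ne)
    la <- sigma * za - sigma^2 / 2
    lb <- sigma * zb - sigma^2 / 2
    tree_a <- species_tree
    tree_a$edge.length <- species_tree$edge.length * base_rate_a * exp(la)
    tree_b <- species_tree
    tree_b$edge.length <- species_tree$edge.length * base_rate_b * exp(lb)
    if (n_nni > 0L) tree_b <- phangorn::rNNI(tree_b, moves = n_nni)
    list(tree_a = tree_a, tree_b = tree_b,
         log_mult_a = la, log_mult_b = lb)
  })
}

#' Evolve a gap-free alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies; states
#' are propagated along each branch by sampling from the transition
#' probabilities `P(t * rate_c)`, with each site's gamma category fixed
#' across the tree.
#'
#' @param tree a `phylo` with branch lengths.
#' @param model an [aa_model()].
#' @param gamma a [discrete_gamma()].
#' @param n_sites number of columns to simulate.
#' @param seed RNG seed.
#' @param id alignment identifier.
#' @return An [msa()] whose species are the tree's tip labels.
#' @export
evolve_alignment <- function(tree, model, gamma, n_sites, seed = NULL,
                             id = NULL) {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1L)
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  nnode <- max(edge)
  root <- setdiff(unique(edge[, 1L]), edge[, 2L])
  with_seed(seed, {
    cat_of_site <- sample.int(gamma$n_categories, n_sites, replace = TRUE)
    states <- matrix(NA_integer_, nnode, n_sites)
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                                 prob = model$frequencies)
    # preorder = reversed postorder edge list
    for (e in rev(seq_len(nrow(edge)))) {
      p <- edge[e, 1L]; ch <- edge[e, 2L]
      for (c in seq_len(gamma$n_categories)) {
        sites_c <- which(cat_of_site == c)
        if (!length(sites_c)) next
        P <- transition_prob(model, tree$edge.length[e], gamma$rates[c])
        P <- P / rowSums(P)
        parent_states <- states[p, sites_c]
        for (s in unique(parent_states)) {
          idx <- sites_c[parent_states == s]
          states[ch, idx] <- sample.int(20L, length(idx), replace = TRUE,
                                        prob = P[s, ])
        }
      }
    }
    m <- matrix(AA_STATES[states[seq_len(ntip), , drop = FALSE]],
                nrow = ntip)
    rownames(m) <- tree$tip.label
    msa(m, id = id)
  })
}

#' Simulate one protein pair
#'
#' Draws a fresh species tree, derives the pair's protein trees (shared
#' topology unless `n_nni > 0`), and evolves one alignment per protein.
#'
#' @param config a [sim_config()].
#' @param pair_id identifier; also used to derive the pair's RNG stream
#'   from `config$seed`.
#' @param interacting logical: interacting pairs use `config$rho` and a
#'   shared topology; non-interacting pairs use rho = 0 and `config$n_nni`
#'   perturbation moves.
#' @return List with `pair_id`, `label`, `aln_a`, `aln_b`, `species_tree`,
#'   `tree_a`, `tree_b`, `rho`, `n_nni`.
#' @export
simulate_pair <- function(config, pair_id, interacting = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  rho <- if (interacting) config$rho else 0
  n_nni <- if (interacting) 0L else config$n_nni
  sp_seed <- derive_seed(config$seed, pair_id, 11L)
  tr_seed <- derive_seed(config$seed, pair_id, 12L)
  sa_seed <- derive_seed(config$seed, pair_id, 13L)
  sb_seed <- derive_seed(config$seed, pair_id, 14L)
  stree <- sample_species_tree(config$n_taxa, config$divergence_scale,
                               seed = sp_seed)
  pt <- derive_pair_trees(stree, rho = rho, sigma = config$sigma,
                          base_rate_a = config$base_rate_a,
                          base_rate_b = config$base_rate_b,
                          n_nni = n_nni, seed = tr_seed)
  model <- lg_model()
  gamma <- discrete_gamma(config$alpha, 8L)
  aln_a <- evolve_alignment(pt$tree_a, model, gamma,
                            config$sites_per_protein, seed = sa_seed,
                            id = paste0(pair_id, "_A"))
  aln_b <- evolve_alignment(pt$tree_b, model, gamma,
                            config$sites_per_protein, seed = sb_seed,
                            id = paste0(pair_id, "_B"))
  list(pair_id = pair_id,
       label = if (interacting) "interacting" else "non-interacting",
       aln_a = aln_a, aln_b = aln_b, species_tree = stree,
       tree_a = pt$tree_a, tree_b = pt$tree_b, rho = rho, n_nni = n_nni)
}

#' Generate a synthetic POS/NEG dataset
#'
#' Simulates `n_pos_pairs` interacting and `n_neg_pairs` non-interacting
#' pairs.  With a directory argument, writes one aligned FASTA per protein,
#' a manifest TSV (`pair_id`, `path_a`, `path_b`, `label`) consumable by
#' [analyze_dataset()], and a ground-truth JSON (per-pair generating trees
#' and parameters); otherwise the dataset is returned in memory only.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory (created if missing).
#' @return Invisibly, a list of class `sim_dataset` with `pairs` (list of
#'   [simulate_pair()] results), `manifest` (data frame) and `config`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ids <- c(sprintf("pos%03d", seq_len(config$n_pos_pairs)),
           sprintf("neg%03d", seq_len(config$n_neg_pairs)))
  inter <- c(rep(TRUE, config$n_pos_pairs), rep(FALSE, config$n_neg_pairs))
  pairs <- Map(function(id, pos) simulate_pair(config, id, pos), ids, inter)
  manifest <- data.frame(
    pair_id = ids,
    path_a = paste0(ids, "_A.fasta"),
    path_b = paste0(ids, "_B.fasta"),
    label = ifelse(inter, "interacting", "non-interacting"),
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (p in pairs) {
      write_msa_fasta(p$aln_a, file.path(dir, paste0(p$pair_id, "_A.fasta")))
      write_msa_fasta(p$aln_b, file.path(dir, paste0(p$pair_id, "_B.fasta")))
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- lapply(pairs, function(p) {
      list(pair_id = p$pair_id, label = p$label, rho = p$rho,
           n_nni = p$n_nni,
           species_tree = write_newick(p$species_tree),
           tree_a = write_newick(p$tree_a),
           tree_b = write_newick(p$tree_b))
    })
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(structure(list(pairs = pairs, manifest = manifest,
                           config = config),
                      class = "sim_dataset"))
}

#' Inject gap columns into an alignment (filter fixture)
#'
#' Deterministically overwrites the leading rows of selected columns with
#' gap characters; used to exercise the gap-column filter, since the
#' simulator itself has no indel process.
#'
#' @param aln an [msa()].
#' @param columns column indices to receive gaps.
#' @param gap_fraction fraction of rows gapped in each selected column
#'   (rounded up, so the outcome is deterministic).
#' @return The modified [msa()].
#' @export
inject_gap_columns <- function(aln, columns, gap_fraction = 0.5) {
  stopifnot(inherits(aln, "msa"))
  m <- unclass(aln)
  n_gap <- ceiling(nrow(m) * gap_fraction)
  for (j in columns) m[seq_len(n_gap), j] <- "-"
  msa(m, id = attr(aln, "id"))
}
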