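# Per-pair orchestration and dataset-level statistics.

#' Pipeline configuration
#'
#' Collects the analysis settings applied to every pair.  Defaults follow
#' the reference protocol: LG model, 8 gamma categories with per-alignment
#' shape estimation, 20% gap-column threshold, at least 10 common species,
#' rejection level 0.05 with the conjunction rule over the three topology
#' tests, 1000 RELL resamples and 1000 permutations.
#'
#' @param model substitution model name; only "LG" is provided.
#' @param n_categories discrete-gamma categories (default 8).
#' @param alpha fixed gamma shape, or NULL to estimate per alignment.
#' @param alpha_method "profile" (default: 1-D profile likelihood on the NJ
#'   tree with its branch lengths held fixed -- fast, then distances and
#'   branch lengths are re-estimated at the chosen shape) or "joint"
#'   (full [estimate_alpha()] with branch lengths re-optimized per
#'   candidate).
#' @param max_gap_fraction per-column gap threshold (1 keeps the complete
#'   alignment; 0.20 is the filtered variant).
#' @param min_sequences minimum common species per pair (default 10).
#' @param max_sequences optional cap; larger common sets are subsampled
#'   reproducibly (e.g. 25 or 35).
#' @param alpha_level rejection level for the topology tests.
#' @param min_criteria topology criteria (of KH, SH, ELW) that must be
#'   non-rejecting for a direction to pass (default 3).
#' @param n_resamples RELL bootstrap replicates.
#' @param n_permutations permutation-null draws for the correlation.
#' @param nni refine each protein tree by NNI hill climbing (default
#'   FALSE: NJ topology on ML distances with ML branch lengths).
#' @param reoptimize_partner re-optimize the partner topology's branch
#'   lengths on the tested alignment (default TRUE; FALSE keeps its
#'   original lengths).
#' @param seed master seed; per-pair streams are derived by stable hashing
#'   of the pair id.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(model = "LG", n_categories = 8L, alpha = NULL,
                            alpha_method = c("profile", "joint"),
                            max_gap_fraction = 0.20,
                            min_sequences = 10L, max_sequences = NULL,
                            alpha_level = 0.05, min_criteria = 3L,
                            n_resamples = 1000L, n_permutations = 1000L,
                            nni = FALSE, reoptimize_partner = TRUE,
                            seed = 1L) {
  if (!identical(model, "LG")) stop("unknown model: ", model)
  structure(list(model = model, n_categories = as.integer(n_categories),
                 alpha = alpha, alpha_method = match.arg(alpha_method),
                 max_gap_fraction = max_gap_fraction,
                 min_sequences = as.integer(min_sequences),
                 max_sequences = if (is.null(max_sequences)) NULL
                                 else as.integer(max_sequences),
                 alpha_level = alpha_level,
                 min_criteria = as.integer(min_criteria),
                 n_resamples = as.integer(n_resamples),
                 n_permutations = as.integer(n_permutations),
                 nni = isTRUE(nni),
                 reoptimize_partner = isTRUE(reoptimize_partner),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Entry filters: common species and size limits
#'
#' Intersects the two alignments' species sets, rejects the pair (a typed
#' outcome, not an error) when fewer than `min_sequences` species are
#' shared, and reproducibly subsamples to `max_sequences` when the common
#' set is larger.
#'
#' @param aln_a,aln_b [msa()] objects.
#' @param min_sequences minimum common species (default 10).
#' @param max_sequences optional cap on common species.
#' @param seed seed for the subsampling draw.
#' @return List with `accepted` (logical); when accepted, `aln_a`, `aln_b`
#'   restricted to the (sorted) common species set and `species`; when
#'   rejected, `reason`.
#' @export
entry_filters <- function(aln_a, aln_b, min_sequences = 10L,
                          max_sequences = NULL, seed = NULL) {
  common <- sort(intersect(msa_species(aln_a), msa_species(aln_b)))
  if (length(common) < min_sequences) {
    return(list(accepted = FALSE,
                reason = sprintf("only %d common species (minimum %d)",
                                 length(common), min_sequences)))
  }
  if (!is.null(max_sequences) && length(common) > max_sequences) {
    common <- sort(with_seed(seed, sample(common, max_sequences)))
  }
  list(accepted = TRUE,
       aln_a = msa_subset(aln_a, common),
       aln_b = msa_subset(aln_b, common),
       species = common)
}

# Per-alignment tree inference: ML distances -> NJ -> shape -> distances
# re-estimated at the chosen shape -> NJ -> ML branch lengths [-> NNI].
infer_protein_tree <- function(aln, model, config) {
  k <- config$n_categories
  if (!is.null(config$alpha)) {
    alpha <- config$alpha
    gamma <- discrete_gamma(alpha, k)
    dm <- distance_matrix(aln, model, gamma)
    tr <- neighbor_joining(dm)
  } else {
    gamma0 <- discrete_gamma(1, k)
    dm0 <- distance_matrix(aln, model, gamma0)
    tr0 <- neighbor_joining(dm0)
    alpha <- if (config$alpha_method == "joint") {
      as.numeric(estimate_alpha(tr0, aln, model, n_categories = k))
    } else {
      profile_alpha_fixed_tree(tr0, aln, model, k)
    }
    gamma <- discrete_gamma(alpha, k)
    dm <- distance_matrix(aln, model, gamma)
    tr <- neighbor_joining(dm)
  }
  tr <- optimize_branch_lengths(tr, aln, model, gamma,
                                warn_nonconvergence = FALSE)
  if (config$nni) {
    tr <- nni_search(tr, aln, model, gamma)
  }
  list(tree = tr, gamma = gamma, alpha = alpha, dm = dm)
}

# 1-D profile likelihood for the gamma shape on a fixed tree (topology and
# branch lengths held at the NJ estimate).
profile_alpha_fixed_tree <- function(tree, aln, model, n_categories,
                                     interval = c(0.05, 100)) {
  prof <- function(log_a) {
    tree_log_likelihood(tree, aln, model,
                        discrete_gamma(exp(log_a), n_categories))$total
  }
  opt <- stats::optimize(prof, interval = log(interval), maximum = TRUE,
                         tol = 0.01)
  exp(opt$maximum)
}

#' Analyze one protein pair
#'
#' Runs the full per-pair protocol: gap-column filter, entry filters, ML
#' distance matrices, NJ trees with ML branch lengths (optional NNI), the
#' cross-fitted topology tests in both directions, and the
#' distance-matrix correlation with its permutation null.  Fully
#' deterministic given `config$seed` and `pair_id`.
#'
#' @param aln_a,aln_b the two proteins' alignments ([msa()]).
#' @param config a [pipeline_config()].
#' @param pair_id identifier used in outputs and seed derivation.
#' @param label "interacting" or "non-interacting" (carried through to the
#'   dataset summary).
#' @return An object of class `pair_result`, or a rejection record
#'   (`accepted = FALSE`) if the pair fails the entry filters.
#' @export
analyze_pair <- function(aln_a, aln_b, config = pipeline_config(),
                         pair_id = "pair", label = NA_character_) {
  stopifnot(inherits(config, "pipeline_config"))
  aln_a <- filter_gap_columns(aln_a, config$max_gap_fraction)
  aln_b <- filter_gap_columns(aln_b, config$max_gap_fraction)
  ef <- entry_filters(aln_a, aln_b, config$min_sequences,
                      config$max_sequences,
                      seed = derive_seed(config$seed, pair_id, 1L))
  if (!ef$accepted) {
    return(structure(list(pair_id = pair_id, accepted = FALSE,
                          reason = ef$reason, label = label),
                     class = "pair_result"))
  }
  model <- lg_model()
  fa <- infer_protein_tree(ef$aln_a, model, config)
  fb <- infer_protein_tree(ef$aln_b, model, config)
  topo <- compare_topologies(
    ef$aln_a, ef$aln_b, fa$tree, fb$tree, model, fa$gamma, fb$gamma,
    n_resamples = config$n_resamples,
    seed = derive_seed(config$seed, pair_id, 2L),
    alpha_level = config$alpha_level, min_criteria = config$min_criteria,
    reoptimize_other = config$reoptimize_partner
  )
  corr <- correlation_result(fa$dm, fb$dm,
                             n_permutations = config$n_permutations,
                             seed = derive_seed(config$seed, pair_id, 3L),
                             pair_id = pair_id)
  structure(
    list(pair_id = pair_id, accepted = TRUE, label = label,
         n_common_species = length(ef$species),
         alpha_a = fa$alpha, alpha_b = fb$alpha,
         mean_distance_a = mean(upper_tri_values(fa$dm$values)),
         mean_distance_b = mean(upper_tri_values(fb$dm$values)),
         dm_a = fa$dm, dm_b = fb$dm,
         tree_a = fa$tree, tree_b = fb$tree,
         correlation = corr, topology = topo,
         category = topo$category),
    class = "pair_result"
  )
}

#' @export
print.pair_result <- function(x, ...) {
  if (!isTRUE(x$accepted)) {
    cat(sprintf("<pair_result %s: rejected (%s)>\n", x$pair_id, x$reason))
  } else {
    cat(sprintf("<pair_result %s [%s]: r = %.3f (p_perm = %.3g), category %s>\n",
                x$pair_id, x$label, x$correlation$r_pearson,
                x$correlation$p_perm, x$category))
  }
  invisible(x)
}

#' Analyze a manifest of protein pairs
#'
#' @param manifest data frame (or TSV path) with columns `pair_id`,
#'   `path_a`, `path_b`, `label`, or a `sim_dataset` from
#'   [generate_dataset()] (analyzed in memory).
#' @param config a [pipeline_config()].
#' @param dir base directory for relative FASTA paths.
#' @param progress print one line per pair.
#' @return Object of class `dataset_result`: list of `pair_result`s and
#'   the [summarize_dataset()] summary.
#' @export
analyze_dataset <- function(manifest, config = pipeline_config(),
                            dir = ".", progress = interactive()) {
  if (inherits(manifest, "sim_dataset")) {
    results <- lapply(manifest$pairs, function(p) {
      if (progress) message("pair ", p$pair_id)
      analyze_pair(p$aln_a, p$aln_b, config, pair_id = p$pair_id,
                   label = p$label)
    })
  } else {
    if (is.character(manifest)) {
      dir <- dirname(manifest)
      manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    }
    needed <- c("pair_id", "path_a", "path_b", "label")
    if (!all(needed %in% names(manifest))) {
      stop("manifest must have columns: ", paste(needed, collapse = ", "))
    }
    results <- lapply(seq_len(nrow(manifest)), function(i) {
      row <- manifest[i, ]
      if (progress) message("pair ", row$pair_id)
      aln_a <- read_msa_fasta(file.path(dir, row$path_a))
      aln_b <- read_msa_fasta(file.path(dir, row$path_b))
      analyze_pair(aln_a, aln_b, config, pair_id = row$pair_id,
                   label = row$label)
    })
  }
  structure(list(results = results,
                 summary = summarize_dataset(results),
                 config = config),
            class = "dataset_result")
}

#' Chi-square comparison of topology-category distributions
#'
#' Pearson chi-square (no continuity correction) on the 2 x 3 table of
#' `(+,+)`, `(+,-)`, `(-,-)` counts for interacting (POS) versus
#' non-interacting (NEG) pairs; df = 2 when all three categories occur.
#' Categories empty in both groups are dropped with a structural-zero
#' warning (proportional tables then return statistic 0, p = 1).
#'
#' @param counts_pos,counts_neg nonnegative integer triples, ordered
#'   `(+,+)`, `(+,-)`, `(-,-)`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_categories <- function(counts_pos, counts_neg) {
  if (length(counts_pos) != length(counts_neg)) {
    stop("count vectors must have equal length")
  }
  if (any(counts_pos < 0) || any(counts_neg < 0)) stop("counts must be >= 0")
  tab <- rbind(POS = as.numeric(counts_pos), NEG = as.numeric(counts_neg))
  if (any(rowSums(tab) == 0)) stop("a dataset (row) has zero total count")
  zero_col <- colSums(tab) == 0
  if (any(zero_col)) {
    warning("structural zero: category absent in both datasets")
    tab <- tab[, !zero_col, drop = FALSE]
  }
  if (ncol(tab) < 2L) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Area under the ROC curve by the rank statistic
#'
#' `AUC = P(score_pos > score_neg) + 0.5 P(tie)`, computed from the
#' Mann-Whitney rank sum.
#'
#' @param scores_pos,scores_neg numeric score vectors (e.g. per-pair
#'   Pearson correlations) for interacting and non-interacting pairs.
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg)) {
    stop("both score vectors must be nonempty")
  }
  np <- length(scores_pos)
  nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Summarize a dataset of analyzed pairs
#'
#' Tallies topology categories by label, compares the POS and NEG
#' distributions by chi-square, and collects rate-correlation summaries
#' (mean per-alignment genetic distance both per-pair-averaged and pooled,
#' Mann-Whitney comparison of the Pearson correlations, ROC AUC of the
#' correlation as an interaction predictor).
#'
#' @param results list of `pair_result` objects (rejected pairs are
#'   excluded from tallies).
#' @return A list of class `dataset_summary` with `counts_pos`,
#'   `counts_neg` (named category triples), `chi2`, `n_pos`, `n_neg`,
#'   `r_pos`, `r_neg`, `mw_p_value`, `auc`, and mean-distance summaries.
#' @export
summarize_dataset <- function(results) {
  results <- Filter(function(r) isTRUE(r$accepted), results)
  labels <- vapply(results, function(r) r$label, character(1))
  if (!any(labels == "interacting") || !any(labels == "non-interacting")) {
    stop("need at least one accepted pair in each label class")
  }
  cats <- c("(+,+)", "(+,-)", "(-,-)")
  tally <- function(rs) {
    out <- table(factor(vapply(rs, function(r) r$category, character(1)),
                        levels = cats))
    stats::setNames(as.integer(out), cats)
  }
  pos <- results[labels == "interacting"]
  neg <- results[labels == "non-interacting"]
  counts_pos <- tally(pos)
  counts_neg <- tally(neg)
  chi2 <- chi_square_categories(counts_pos, counts_neg)
  r_of <- function(rs) {
    stats::setNames(vapply(rs, function(r) r$correlation$r_pearson,
                           numeric(1)),
                    vapply(rs, function(r) r$pair_id, character(1)))
  }
  r_pos <- r_of(pos)
  r_neg <- r_of(neg)
  mw <- stats::wilcox.test(r_pos, r_neg, alternative = "greater",
                           exact = FALSE)
  mean_dists <- function(rs) {
    per_aln <- unlist(lapply(rs, function(r)
      c(r$mean_distance_a, r$mean_distance_b)))
    pooled <- unlist(lapply(rs, function(r)
      c(upper_tri_values(r$dm_a$values), upper_tri_values(r$dm_b$values))))
    c(per_pair_mean = mean(per_aln), pooled_mean = mean(pooled))
  }
  structure(
    list(counts_pos = counts_pos, counts_neg = counts_neg,
         chi2 = chi2, n_pos = length(pos), n_neg = length(neg),
         r_pos = r_pos, r_neg = r_neg,
         mw_p_value = unname(mw$p.value),
         auc = roc_auc(r_pos, r_neg),
         mean_distance_pos = mean_dists(pos),
         mean_distance_neg = mean_dists(neg)),
    class = "dataset_summary"
  )
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("<dataset_summary: %d POS / %d NEG pairs>\n", x$n_pos, x$n_neg))
  cat("  categories POS:", paste(names(x$counts_pos), x$counts_pos,
                                 sep = "=", collapse = " "), "\n")
  cat("  categories NEG:", paste(names(x$counts_neg), x$counts_neg,
                                 sep = "=", collapse = " "), "\n")
  cat(sprintf("  chi-square: X2 = %.3f, df = %d, p = %.4g\n",
              x$chi2$statistic, x$chi2$df, x$chi2$p_value))
  cat(sprintf("  correlations: mean r POS = %.3f, NEG = %.3f; Mann-Whitney p = %.3g; AUC = %.3f\n",
              mean(x$r_pos), mean(x$r_neg), x$mw_p_value, x$auc))
  invisible(x)
}

#' Published category counts for the yeast benchmark datasets
#'
#' Loads the packaged table of topology-category counts (POS and NEG) and
#' printed chi-square p-values for the eight published yeast
#' interacting/non-interacting dataset variants, used to validate
#' [chi_square_categories()] against the printed values.
#'
#' @return Data frame with columns `dataset`, `pos_pp`, `pos_pm`, `pos_mm`,
#'   `neg_pp`, `neg_pm`, `neg_mm`, `p_printed`.
#' @export
yeast_category_counts <- function() {
  path <- system.file("extdata", "yeast_category_counts.tsv",
                      package = "mirrortopo", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
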