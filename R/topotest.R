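# Likelihood-based topology similarity testing.
#
# The question asked of every protein pair is whether the partner protein's
# tree topology explains an alignment as well as the alignment's own tree.
# Per-site log-likelihoods are compared by RELL resampling (resampling
# estimated log-likelihoods: bootstrap over site log-likelihood vectors
# without re-optimizing trees), via the Kishino-Hasegawa test (two-sided),
# the Shimodaira-Hasegawa test (one-sided, with per-tree recentering), and
# expected likelihood weights.

#' Cross-fit a partner topology to an alignment
#'
#' Fits both the alignment's own tree and the partner protein's tree
#' (topology only: its branch lengths are re-optimized on this alignment,
#' so everything except topology is controlled) and records total and
#' per-site log-likelihoods.  The difference `d_ll = ll_own - ll_other` is
#' the "difference log-likelihood" (dLL) summarizing how much worse the
#' partner topology explains this alignment.
#'
#' @param aln an [msa()].
#' @param own_tree tree inferred from `aln` (leaf set must equal the
#'   partner's after pruning).
#' @param other_tree the partner protein's tree, pruned to the same leaf
#'   set.
#' @param model an [aa_model()]; `gamma` a [discrete_gamma()].
#' @param gamma rate-heterogeneity object shared by both fits.
#' @param reoptimize_own also re-optimize the own tree's branch lengths on
#'   the alignment (cheap when they are already near-optimal; guarantees
#'   the comparison is between two optimized fits).
#' @param reoptimize_other re-optimize the partner topology's branch
#'   lengths (default TRUE, the topology-only hypothesis); setting FALSE
#'   compares against the partner tree with its original lengths.
#' @return An object of class `cross_fit`: `alignment_id`, `ll_own`,
#'   `ll_other`, `d_ll`, `site_ll_own`, `site_ll_other`, and the two fitted
#'   trees.
#' @export
cross_fit <- function(aln, own_tree, other_tree, model, gamma,
                      reoptimize_own = TRUE, reoptimize_other = TRUE) {
  sp_own <- sort(own_tree$tip.label)
  sp_oth <- sort(other_tree$tip.label)
  if (!identical(sp_own, sp_oth)) {
    stop("leaf-set mismatch between trees: ",
         paste(union(setdiff(sp_own, sp_oth), setdiff(sp_oth, sp_own)),
               collapse = ", "))
  }
  if (!all(sp_own %in% rownames(aln))) {
    stop("tree leaves absent from alignment: ",
         paste(setdiff(sp_own, rownames(aln)), collapse = ", "))
  }
  fit_own <- if (reoptimize_own) {
    optimize_branch_lengths(own_tree, aln, model, gamma,
                            warn_nonconvergence = FALSE)
  } else own_tree
  fit_oth <- if (reoptimize_other) {
    optimize_branch_lengths(other_tree, aln, model, gamma,
                            warn_nonconvergence = FALSE)
  } else other_tree
  sl_own <- tree_log_likelihood(fit_own, aln, model, gamma)
  sl_oth <- tree_log_likelihood(fit_oth, aln, model, gamma)
  structure(
    list(alignment_id = msa_id(aln),
         ll_own = sl_own$total, ll_other = sl_oth$total,
         d_ll = sl_own$total - sl_oth$total,
         site_ll_own = sl_own$per_site, site_ll_other = sl_oth$per_site,
         tree_own = fit_own, tree_other = fit_oth),
    class = "cross_fit"
  )
}

#' @export
print.cross_fit <- function(x, ...) {
  cat(sprintf("<cross_fit %s: LL own %.3f, LL other %.3f, dLL %.3f>\n",
              if (is.null(x$alignment_id)) "" else x$alignment_id,
              x$ll_own, x$ll_other, x$d_ll))
  invisible(x)
}

rell_indices <- function(n_sites, n_resamples, seed) {
  with_seed(seed, matrix(sample.int(n_sites, n_sites * n_resamples,
                                    replace = TRUE),
                         nrow = n_sites))
}

#' Kishino-Hasegawa RELL test (two-sided)
#'
#' Tests the null hypothesis that two topologies have equal expected
#' support: the observed summed site-wise log-likelihood difference is
#' compared against its RELL bootstrap distribution, centered at zero by
#' subtracting the per-site mean difference.  An identically zero
#' difference vector returns p = 1 by convention.
#'
#' @param site_ll_own,site_ll_other equal-length per-site log-likelihood
#'   vectors.
#' @param n_resamples RELL bootstrap replicates (>= 100).
#' @param seed RNG seed; results are bit-reproducible given
#'   (vectors, n_resamples, seed).
#' @return Two-sided p-value, using the add-one convention
#'   `(1 + #extreme) / (n_resamples + 1)`.
#' @export
kh_test <- function(site_ll_own, site_ll_other, n_resamples = 1000L,
                    seed = NULL) {
  if (length(site_ll_own) != length(site_ll_other)) {
    stop("per-site vectors must have equal length")
  }
  if (n_resamples < 100L) stop("n_resamples must be >= 100")
  d <- site_ll_own - site_ll_other
  if (all(abs(d) < 1e-12)) return(1)
  t_obs <- sum(d)
  dc <- d - mean(d)
  idx <- rell_indices(length(d), n_resamples, seed)
  t_null <- colSums(matrix(dc[idx], nrow = nrow(idx)))
  (1 + sum(abs(t_null) >= abs(t_obs) - 1e-9)) / (n_resamples + 1)
}

#' Shimodaira-Hasegawa RELL test
#'
#' Multiple-comparison-safe topology test: all candidate trees' resampled
#' log-likelihood sums are recentered per tree, and the tested tree's
#' observed deficit from the best tree is compared against the resampled
#' distribution of its deficit from the per-replicate best.  One-sided by
#' definition; the maximum-likelihood tree receives p = 1.
#'
#' @param site_ll_candidates list of >= 2 equal-length per-site
#'   log-likelihood vectors, one per candidate tree.
#' @param index_tested index of the candidate whose p-value is returned.
#' @inheritParams kh_test
#' @return p-value for the tested candidate (add-one convention).
#' @export
sh_test <- function(site_ll_candidates, index_tested, n_resamples = 1000L,
                    seed = NULL) {
  M <- length(site_ll_candidates)
  if (M < 2L) stop("need at least 2 candidate trees")
  n <- unique(lengths(site_ll_candidates))
  if (length(n) != 1L) stop("per-site vectors must have equal length")
  if (n_resamples < 100L) stop("n_resamples must be >= 100")
  L <- do.call(cbind, site_ll_candidates)      # n x M
  obs <- colSums(L)
  s_obs <- max(obs) - obs[index_tested]
  idx <- rell_indices(n, n_resamples, seed)
  R <- matrix(0, n_resamples, M)
  for (m in seq_len(M)) {
    R[, m] <- colSums(matrix(L[idx, m], nrow = n))
  }
  Rc <- sweep(R, 2, colMeans(R))               # per-tree centering
  s_null <- apply(Rc, 1, max) - Rc[, index_tested]
  (1 + sum(s_null >= s_obs - 1e-9)) / (n_resamples + 1)
}

#' Expected likelihood weights
#'
#' Each candidate's weight is the fraction of RELL resamples in which it
#' attains the maximal resampled log-likelihood (ties split evenly), so the
#' weights sum to one.  A candidate is "accepted" if it belongs to the
#' smallest set of candidates whose cumulative weight reaches `conf_level`.
#'
#' @inheritParams sh_test
#' @param conf_level confidence level of the acceptance set (default 0.95).
#' @return List with `weights` (numeric, sums to 1) and `accepted`
#'   (logical per candidate).
#' @export
expected_likelihood_weights <- function(site_ll_candidates,
                                        n_resamples = 1000L, seed = NULL,
                                        conf_level = 0.95) {
  M <- length(site_ll_candidates)
  if (M < 2L) stop("need at least 2 candidate trees")
  n <- unique(lengths(site_ll_candidates))
  if (length(n) != 1L) stop("per-site vectors must have equal length")
  if (n_resamples < 100L) stop("n_resamples must be >= 100")
  L <- do.call(cbind, site_ll_candidates)
  idx <- rell_indices(n, n_resamples, seed)
  R <- matrix(0, n_resamples, M)
  for (m in seq_len(M)) {
    R[, m] <- colSums(matrix(L[idx, m], nrow = n))
  }
  w <- numeric(M)
  mx <- apply(R, 1, max)
  is_max <- R >= mx - 1e-9
  share <- 1 / rowSums(is_max)
  for (m in seq_len(M)) w[m] <- sum(share[is_max[, m]])
  w <- w / n_resamples
  ord <- order(w, decreasing = TRUE)
  cum <- cumsum(w[ord])
  n_keep <- which(cum >= conf_level - 1e-12)[1]
  accepted <- logical(M)
  accepted[ord[seq_len(n_keep)]] <- TRUE
  list(weights = w, accepted = accepted)
}

#' Run the three topology tests for one cross-fit direction
#'
#' Applies [kh_test()], [sh_test()] and [expected_likelihood_weights()] to
#' a [cross_fit()] (candidates = own tree, partner tree; the partner tree
#' is the tested candidate), sharing one seed.
#'
#' @param cf a [cross_fit()].
#' @inheritParams kh_test
#' @param conf_level ELW acceptance-set confidence level.
#' @return List with `p_kh`, `p_sh`, `elw_weight` (partner tree's weight),
#'   `elw_accepted`, `d_ll`.
#' @export
topology_tests <- function(cf, n_resamples = 1000L, seed = NULL,
                           conf_level = 0.95) {
  stopifnot(inherits(cf, "cross_fit"))
  cands <- list(cf$site_ll_own, cf$site_ll_other)
  p_kh <- kh_test(cf$site_ll_own, cf$site_ll_other,
                  n_resamples = n_resamples, seed = seed)
  p_sh <- sh_test(cands, index_tested = 2L, n_resamples = n_resamples,
                  seed = seed)
  elw <- expected_likelihood_weights(cands, n_resamples = n_resamples,
                                     seed = seed, conf_level = conf_level)
  list(p_kh = p_kh, p_sh = p_sh,
       elw_weight = elw$weights[2L], elw_accepted = elw$accepted[2L],
       d_ll = cf$d_ll)
}

direction_passes <- function(tests, alpha_level = 0.05, min_criteria = 3L) {
  votes <- c(tests$p_kh >= alpha_level,
             tests$p_sh >= alpha_level,
             isTRUE(tests$elw_accepted))
  sum(votes) >= min_criteria
}

#' Classify a protein pair by topology similarity
#'
#' A direction "passes" when the partner topology is not rejected by the
#' KH and SH tests at `alpha_level` and is inside the ELW confidence set
#' (by default all three criteria must agree -- the conservative
#' conjunction rule; `min_criteria` relaxes this to any k of 3).  Pairs are
#' categorized `(+,+)` when both directions pass, `(+,-)` when exactly one
#' does, `(-,-)` when neither does.
#'
#' @param tests_a,tests_b results of [topology_tests()] for the two
#'   directions (partner tree tested on alignment A, and on alignment B).
#' @param alpha_level rejection level for KH and SH (default 0.05).
#' @param min_criteria number of the three criteria that must be
#'   non-rejecting for a direction to pass (default 3 = conjunction).
#' @return List with `passes_a`, `passes_b`, `category`.
#' @export
classify_pair <- function(tests_a, tests_b, alpha_level = 0.05,
                          min_criteria = 3L) {
  pa <- direction_passes(tests_a, alpha_level, min_criteria)
  pb <- direction_passes(tests_b, alpha_level, min_criteria)
  category <- if (pa && pb) "(+,+)" else if (pa || pb) "(+,-)" else "(-,-)"
  list(passes_a = pa, passes_b = pb, category = category)
}

#' Full topology comparison for a protein pair
#'
#' Cross-fits each protein's tree to the partner's alignment, runs the
#' three RELL tests in both directions, and assigns the pair's similarity
#' category.
#'
#' @param aln_a,aln_b alignments of the two proteins over a common species
#'   set.
#' @param tree_a,tree_b trees inferred from the respective alignments.
#' @inheritParams cross_fit
#' @param gamma_a,gamma_b rate objects for the two alignments (each
#'   alignment keeps its own estimated shape).
#' @param n_resamples RELL replicates; `seed` master seed for the tests.
#' @param seed integer seed (two independent streams are derived from it).
#' @param alpha_level,min_criteria see [classify_pair()].
#' @param conf_level ELW confidence level.
#' @return Object of class `topology_comparison`: both cross-fits, both
#'   test sets, pass flags and `category`.
#' @export
compare_topologies <- function(aln_a, aln_b, tree_a, tree_b, model,
                               gamma_a, gamma_b,
                               n_resamples = 1000L, seed = NULL,
                               alpha_level = 0.05, min_criteria = 3L,
                               conf_level = 0.95,
                               reoptimize_other = TRUE) {
  cf_a <- cross_fit(aln_a, tree_a, tree_b, model, gamma_a,
                    reoptimize_other = reoptimize_other)
  cf_b <- cross_fit(aln_b, tree_b, tree_a, model, gamma_b,
                    reoptimize_other = reoptimize_other)
  seed_a <- if (is.null(seed)) NULL else derive_seed(seed, "kh_a", 1L)
  seed_b <- if (is.null(seed)) NULL else derive_seed(seed, "kh_b", 2L)
  t_a <- topology_tests(cf_a, n_resamples, seed_a, conf_level)
  t_b <- topology_tests(cf_b, n_resamples, seed_b, conf_level)
  cls <- classify_pair(t_a, t_b, alpha_level, min_criteria)
  structure(
    list(crossfit_a = cf_a, crossfit_b = cf_b,
         tests_a = t_a, tests_b = t_b,
         passes_a = cls$passes_a, passes_b = cls$passes_b,
         category = cls$category),
    class = "topology_comparison"
  )
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat(sprintf(
    "<topology_comparison %s: dLL_a %.2f (KH %.3f, SH %.3f), dLL_b %.2f (KH %.3f, SH %.3f)>\n",
    x$category, x$crossfit_a$d_ll, x$tests_a$p_kh, x$tests_a$p_sh,
    x$crossfit_b$d_ll, x$tests_b$p_kh, x$tests_b$p_sh))
  invisible(x)
}
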