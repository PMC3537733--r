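# Mirrortree-style correlation of genetic-distance matrices.
#
# The prediction signal is the correlation between two proteins' pairwise
# distance matrices over their common species; significance is assessed by
# a Mantel-style permutation null that relabels one matrix's species (rows
# and columns jointly), preserving matrix validity.

#' Restrict two distance matrices to their common species
#'
#' @param dm_a,dm_b `genetic_dist` objects (or labelled symmetric
#'   matrices).
#' @return List `(dm_a, dm_b)` of `genetic_dist` objects over the common
#'   species in identical (sorted) order; errors if fewer than 3 species
#'   are shared.
#' @export
align_matrices <- function(dm_a, dm_b) {
  ma <- as_gdist(dm_a)
  mb <- as_gdist(dm_b)
  common <- sort(intersect(ma$species, mb$species))
  if (length(common) < 3L) {
    stop("fewer than 3 common species between the two matrices")
  }
  list(dm_a = gdist_subset(ma, common), dm_b = gdist_subset(mb, common))
}

as_gdist <- function(x) {
  if (inherits(x, "genetic_dist")) return(x)
  m <- as.matrix(x)
  if (is.null(rownames(m))) stop("distance matrix must carry species labels")
  structure(list(species = rownames(m), values = m, alpha_used = NA_real_),
            class = "genetic_dist")
}

gdist_subset <- function(dm, species) {
  structure(list(species = species,
                 values = dm$values[species, species, drop = FALSE],
                 alpha_used = dm$alpha_used),
            class = "genetic_dist")
}

#' Correlation between two aligned distance matrices
#'
#' Pearson (the classical mirrortree statistic) or Spearman correlation
#' over the strictly-upper-triangle entries (n(n-1)/2 values; the zero
#' diagonal is excluded as it would inflate the correlation).
#'
#' @param dm_a,dm_b `genetic_dist` objects over the same ordered species
#'   set (see [align_matrices()]).
#' @param method "pearson" or "spearman".
#' @return The correlation coefficient.
#' @export
matrix_correlation <- function(dm_a, dm_b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_aligned(dm_a, dm_b)
  x <- upper_tri_values(dm_a$values)
  y <- upper_tri_values(dm_b$values)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in a distance matrix")
  }
  stats::cor(x, y, method = method)
}

check_aligned <- function(dm_a, dm_b) {
  if (!identical(dm_a$species, dm_b$species)) {
    stop("matrices are not over the same ordered species set; ",
         "use align_matrices() first")
  }
}

#' Permutation test for distance-matrix correlation
#'
#' Builds the null distribution by jointly permuting the species labels of
#' the second matrix (rows and columns together, the Mantel-style null
#' that preserves symmetry) and recomputing the correlation.  The p-value
#' uses the add-one convention `p = (1 + #\{r_null >= r_obs\}) /
#' (n_permutations + 1)`, so p is never exactly zero; the z-score is
#' `(r_obs - mean(null)) / sd(null)`.
#'
#' A literal column-transposition scheme (`scheme = "swaps"`: each null
#' draw applies `n_swaps` random pairwise label transpositions instead of
#' a full relabeling) is available for comparison.
#'
#' @inheritParams matrix_correlation
#' @param n_permutations number of null draws (default 1000).
#' @param seed RNG seed; results are bit-reproducible given the seed.
#' @param scheme "relabel" (default) or "swaps".
#' @param n_swaps transpositions per draw for `scheme = "swaps"`.
#' @return Object of class `perm_cor`: `r`, `p_perm`, `z_score`, `null`
#'   (the null correlations), `n_permutations`, `method`, `seed`.
#' @export
permutation_test <- function(dm_a, dm_b, n_permutations = 1000L, seed = NULL,
                             method = c("pearson", "spearman"),
                             scheme = c("relabel", "swaps"),
                             n_swaps = 1000L) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  check_aligned(dm_a, dm_b)
  r_obs <- matrix_correlation(dm_a, dm_b, method)
  n <- length(dm_b$species)
  A <- dm_a$values
  B <- dm_b$values
  ut <- upper.tri(A)
  x <- A[ut]
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm <- if (scheme == "relabel") {
        sample.int(n)
      } else {
        p <- seq_len(n)
        for (s in seq_len(n_swaps)) {
          ij <- sample.int(n, 2L)
          p[ij] <- p[rev(ij)]
        }
        p
      }
      stats::cor(x, B[perm, perm][ut], method = method)
    }, numeric(1))
  })
  p <- (1 + sum(null >= r_obs - 1e-12)) / (n_permutations + 1)
  sd_null <- stats::sd(null)
  z <- if (sd_null > 0) (r_obs - mean(null)) / sd_null else {
    warning("degenerate permutation null (sd = 0); z-score undefined")
    NA_real_
  }
  structure(list(r = r_obs, p_perm = p, z_score = z, null = null,
                 n_permutations = n_permutations, method = method,
                 scheme = scheme, seed = seed),
            class = "perm_cor")
}

#' @export
print.perm_cor <- function(x, ...) {
  cat(sprintf("<perm_cor: r = %.4f (%s), p_perm = %.4g, z = %.2f, %d permutations>\n",
              x$r, x$method, x$p_perm, x$z_score, x$n_permutations))
  invisible(x)
}

#' Mirrortree correlation record for a protein pair
#'
#' Convenience wrapper producing the per-pair correlation record: Pearson
#' and Spearman coefficients over the common species plus the permutation
#' p-value and z-score for the Pearson statistic.
#'
#' @inheritParams permutation_test
#' @param pair_id identifier stored in the result.
#' @return Object of class `correlation_result`.
#' @export
correlation_result <- function(dm_a, dm_b, n_permutations = 1000L,
                               seed = NULL, pair_id = NULL) {
  al <- align_matrices(dm_a, dm_b)
  pt <- permutation_test(al$dm_a, al$dm_b, n_permutations = n_permutations,
                         seed = seed, method = "pearson")
  structure(
    list(pair_id = pair_id,
         r_pearson = pt$r,
         r_spearman = matrix_correlation(al$dm_a, al$dm_b, "spearman"),
         p_perm = pt$p_perm, z_score = pt$z_score,
         n_species = length(al$dm_a$species),
         n_permutations = n_permutations, seed = seed),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result %s: r = %.4f (rho = %.4f), p_perm = %.4g, z = %.2f, n = %d>\n",
              if (is.null(x$pair_id)) "" else x$pair_id,
              x$r_pearson, x$r_spearman, x$p_perm, x$z_score, x$n_species))
  invisible(x)
}
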