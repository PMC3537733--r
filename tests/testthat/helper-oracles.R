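# Brute-force oracles used to validate the fast implementations.

# Log-likelihood by explicit enumeration over all internal-node state
# assignments, summing over gamma categories.  Exponential in the number
# of internal nodes: only for toy trees (<= 5 taxa).
brute_force_loglik <- function(tree, aln, model, gamma) {
  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  internal <- sort(unique(edge[, 1]))
  root <- setdiff(edge[, 1], edge[, 2])
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  codes <- matrix(match(m, mirrortopo::AA_STATES), nrow = nrow(m))
  n_sites <- ncol(codes)
  k <- gamma$n_categories
  # transition matrices per edge per category
  P <- lapply(seq_len(k), function(c) {
    lapply(seq_len(nrow(edge)), function(e) {
      mirrortopo::transition_prob(model, tree$edge.length[e], gamma$rates[c])
    })
  })
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  out <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    site_lik <- 0
    for (c in seq_len(k)) {
      lik_assign <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        state_of <- function(v) {
          if (v <= ntip) codes[v, s] else grid[g, match(v, internal)]
        }
        lik <- model$frequencies[grid[g, match(root, internal)]]
        for (e in seq_len(nrow(edge))) {
          sp <- state_of(edge[e, 1])
          sc <- state_of(edge[e, 2])
          if (is.na(sc)) {
            # gap: sum over child states = 1 (row sums of P)
            next
          }
          lik <- lik * P[[c]][[e]][sp, sc]
        }
        lik_assign[g] <- lik
      }
      site_lik <- site_lik + gamma$weights[c] * sum(lik_assign)
    }
    out[s] <- log(site_lik)
  }
  out
}

# Negative support for the ML pairwise distance oracle: log-likelihood of
# a two-sequence alignment at distance t, computed directly.
pair_loglik_direct <- function(seq_a, seq_b, model, gamma, t) {
  a <- match(strsplit(seq_a, "")[[1]], mirrortopo::AA_STATES)
  b <- match(strsplit(seq_b, "")[[1]], mirrortopo::AA_STATES)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  total <- 0
  for (s in seq_along(a)) {
    lik <- 0
    for (c in seq_len(gamma$n_categories)) {
      P <- mirrortopo::transition_prob(model, t, gamma$rates[c])
      lik <- lik + gamma$weights[c] * model$frequencies[a[s]] * P[a[s], b[s]]
    }
    total <- total + log(lik)
  }
  total
}

# Grid-search oracle for the ML pairwise distance: evaluates the exact
# pairwise log-likelihood on every grid point via the spectral identity
# pi_a P_ab(t) = sum_k pi_a V[a,k] Vinv[k,b] exp(lambda_k t), vectorized
# over site patterns x grid points (chunked to bound memory).
grid_loglik_curve <- function(seq_a, seq_b, model, gamma, grid,
                              chunk = 10000L) {
  a <- match(strsplit(seq_a, "")[[1]], mirrortopo::AA_STATES)
  b <- match(strsplit(seq_b, "")[[1]], mirrortopo::AA_STATES)
  keep <- !is.na(a) & !is.na(b)
  pat <- table(paste(a[keep], b[keep]))
  counts <- as.numeric(pat)
  ab <- do.call(rbind, strsplit(names(pat), " "))
  ai <- as.integer(ab[, 1]); bi <- as.integer(ab[, 2])
  # W[p, k] = pi_a V[a,k] Vinv[k,b]
  W <- model$frequencies[ai] * model$V[ai, , drop = FALSE] *
    t(model$Vinv)[bi, , drop = FALSE]
  out <- numeric(length(grid))
  for (start in seq(1, length(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(grid))
    lik <- 0
    for (c in seq_len(gamma$n_categories)) {
      E <- exp(outer(model$lambda, grid[idx] * gamma$rates[c]))  # 20 x T
      lik <- lik + gamma$weights[c] * pmax(W %*% E, 1e-300)
    }
    out[idx] <- as.numeric(counts %*% log(lik))
  }
  out
}

# Exhaustive KH p-value on a tiny site set: enumerate every resample
# (n^n with replacement) of the centered differences.
kh_exhaustive_p <- function(site_ll_a, site_ll_b) {
  d <- site_ll_a - site_ll_b
  n <- length(d)
  t_obs <- sum(d)
  dc <- d - mean(d)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  t_null <- apply(grid, 1, function(idx) sum(dc[idx]))
  mean(abs(t_null) >= abs(t_obs) - 1e-12)
}

# AUC by direct pairwise comparison.
auc_enumeration <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# Small toy fixtures shared across files.
toy_alignment <- function(n_taxa = 4, n_sites = 60, seed = 101,
                          scale = 0.3) {
  cfg_tree <- if (n_taxa >= 3) {
    mirrortopo::sample_species_tree(n_taxa, scale, seed = seed)
  } else {
    ape::read.tree(text = sprintf("(sp01:%g,sp02:%g);", scale, scale))
  }
  mirrortopo::evolve_alignment(cfg_tree, mirrortopo::lg_model(),
                               mirrortopo::discrete_gamma(1, 2),
                               n_sites, seed = seed + 1)
}
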