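# Felsenstein pruning engine with discrete-gamma mixing.
#
# Partial likelihoods are kept per gamma category as npattern x 20 matrices,
# with one scalar log-scale per (node, category) to guard against underflow
# on deep trees.  Transition matrices are evaluated through the model's
# spectral decomposition, and per-branch optimization reuses directional
# partials so that each candidate branch length costs only a matrix-vector
# product per category.

# ---- preparation ----------------------------------------------------------

lik_prep <- function(tree, aln, model, gamma) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "msa"),
            inherits(model, "aa_model"), inherits(gamma, "gamma_rates"))
  tips <- tree$tip.label
  missing <- setdiff(tips, rownames(aln))
  if (length(missing)) {
    stop("tree leaves absent from alignment: ", paste(missing, collapse = ", "))
  }
  tree <- stats::reorder(tree, "postorder")
  enc <- msa_encode(aln)[tips, , drop = FALSE]
  key <- apply(enc, 2, paste, collapse = ".")
  first <- !duplicated(key)
  pat <- enc[, first, drop = FALSE]
  pat_index <- match(key, key[first])
  wts <- as.numeric(table(factor(pat_index, levels = seq_len(sum(first)))))
  npat <- ncol(pat)
  ntip <- length(tips)
  nnode <- max(tree$edge)
  # leaf partials: 0/1 indicator rows; missing data contributes all-ones
  leafpart <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    M <- matrix(0, npat, 20L)
    st <- pat[i, ]
    isna <- is.na(st)
    M[cbind(which(!isna), st[!isna])] <- 1
    if (any(isna)) M[isna, ] <- 1
    leafpart[[i]] <- M
  }
  children <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    children[[p]] <- c(children[[p]], e)
  }
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  list(tree = tree, edge = tree$edge, ntip = ntip, nnode = nnode,
       root = root, children = children, leafpart = leafpart,
       pat = pat, wts = wts, pat_index = pat_index, npat = npat,
       n_sites = ncol(enc), model = model, gamma = gamma)
}

pmat <- function(model, t, rate) {
  model$V %*% (exp(model$lambda * t * rate) * model$Vinv)
}

# ---- downward (postorder) pass -------------------------------------------

# Computes partial likelihoods toward the root for every node.
# Returns list(mats = list[node][cat], sc = matrix node x cat of log-scales).
all_down <- function(prep, el) {
  k <- prep$gamma$n_categories
  rates <- prep$gamma$rates
  mats <- vector("list", prep$nnode)
  sc <- matrix(0, prep$nnode, k)
  for (i in seq_len(prep$ntip)) {
    mats[[i]] <- rep(list(prep$leafpart[[i]]), k)
  }
  edge <- prep$edge
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    if (is.null(mats[[p]])) mats[[p]] <- vector("list", k)
    for (c in seq_len(k)) {
      P <- pmat(prep$model, el[e], rates[c])
      X <- mats[[ch]][[c]] %*% t(P)
      if (is.null(mats[[p]][[c]])) {
        acc <- X
        s <- sc[ch, c]
      } else {
        acc <- mats[[p]][[c]] * X
        s <- sc[p, c] + sc[ch, c]
      }
      m <- max(acc)
      if (m > 0 && m < 1e-150) {
        acc <- acc / m
        s <- s + log(m)
      }
      mats[[p]][[c]] <- acc
      sc[p, c] <- s
    }
  }
  list(mats = mats, sc = sc)
}

root_site_loglik <- function(prep, down) {
  k <- prep$gamma$n_categories
  f <- prep$model$frequencies
  logs <- matrix(0, prep$npat, k)
  for (c in seq_len(k)) {
    v <- as.numeric(down$mats[[prep$root]][[c]] %*% f)
    logs[, c] <- log(pmax(v, 1e-300)) + down$sc[prep$root, c]
  }
  log_sum_exp_rows(logs, prep$gamma$weights)
}

#' Tree log-likelihood with per-site values
#'
#' Computes the log-likelihood of an alignment given a tree under a
#' reversible amino-acid model with discrete-gamma rate mixing, by the
#' pruning algorithm.  Gap and ambiguity characters contribute all-ones
#' partials (missing data), so an all-gap column has per-site
#' log-likelihood zero.
#'
#' @param tree a `phylo` whose leaf labels are all present in the alignment.
#' @param aln an [msa()].
#' @param model an [aa_model()].
#' @param gamma a [discrete_gamma()].
#' @return An object of class `site_loglik`: list with `per_site`
#'   (length = number of alignment columns), `total`, `tree_id`,
#'   `alignment_id`.
#' @export
tree_log_likelihood <- function(tree, aln, model, gamma) {
  prep <- lik_prep(tree, aln, model, gamma)
  down <- all_down(prep, prep$tree$edge.length)
  ll_pat <- root_site_loglik(prep, down)
  per_site <- ll_pat[prep$pat_index]
  structure(list(per_site = per_site, total = sum(per_site),
                 tree_id = attr(tree, "id"), alignment_id = msa_id(aln)),
            class = "site_loglik")
}

#' @export
print.site_loglik <- function(x, ...) {
  cat(sprintf("<site_loglik: %d sites, total LL = %.4f>\n",
              length(x$per_site), x$total))
  invisible(x)
}

# ---- branch-length optimization ------------------------------------------

# Per-edge profile likelihood through the spectral decomposition.
# rest: partial for everything outside the child's subtree, anchored at the
# parent endpoint; downv: child's downward partial.  Returns a function of t.
edge_objective <- function(prep, rest_mats, rest_sc, down_mats, down_sc) {
  model <- prep$model
  k <- prep$gamma$n_categories
  rates <- prep$gamma$rates
  f <- model$frequencies
  C <- vector("list", k)
  sc_tot <- rest_sc + down_sc
  off <- max(sc_tot)
  coef <- prep$gamma$weights * exp(sc_tot - off)
  for (c in seq_len(k)) {
    A <- (rest_mats[[c]] * rep(f, each = prep$npat)) %*% model$V
    B <- down_mats[[c]] %*% t(model$Vinv)
    C[[c]] <- A * B
  }
  lam <- model$lambda
  function(t) {
    lik <- 0
    for (c in seq_len(k)) {
      lik <- lik + coef[c] * as.numeric(C[[c]] %*% exp(lam * t * rates[c]))
    }
    sum(prep$wts * log(pmax(lik, 1e-300)))
  }
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise maximization of the tree likelihood: each branch in turn
#' is optimized by a bounded 1-D search while all others are held fixed,
#' sweeping the tree in depth-first order with directional partials updated
#' in place, so the total log-likelihood never decreases.  Sweeps stop when
#' the improvement falls below `tol` or `max_sweeps` is reached (the latter
#' raises a warning and returns the best tree found).
#'
#' @inheritParams tree_log_likelihood
#' @param max_sweeps maximum number of full sweeps (default 50).
#' @param tol stop when a sweep improves the total log-likelihood by less
#'   than this (default 1e-4).
#' @param min_branch,max_branch bounds for each branch length; the lower
#'   bound (default 1e-8) avoids log(0) pathologies at zero-length branches.
#' @param warn_nonconvergence warn if `max_sweeps` is exhausted.
#' @return The tree with optimized `edge.length`, carrying attributes
#'   `loglik` (total log-likelihood) and `sweeps`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, gamma,
                                    max_sweeps = 50L, tol = 1e-4,
                                    min_branch = 1e-8, max_branch = 10,
                                    warn_nonconvergence = TRUE) {
  prep <- lik_prep(tree, aln, model, gamma)
  k <- gamma$n_categories
  rates <- gamma$rates
  env <- new.env(parent = emptyenv())
  env$el <- prep$tree$edge.length
  down <- all_down(prep, env$el)
  env$mats <- down$mats
  env$sc <- down$sc
  edge <- prep$edge

  recompute_down <- function(v) {
    # rebuild node v's downward partial from its children (current lengths)
    for (c in seq_len(k)) {
      acc <- NULL
      s <- 0
      for (e in prep$children[[v]]) {
        ch <- edge[e, 2L]
        P <- pmat(prep$model, env$el[e], rates[c])
        X <- env$mats[[ch]][[c]] %*% t(P)
        acc <- if (is.null(acc)) X else acc * X
        s <- s + env$sc[ch, c]
      }
      m <- max(acc)
      if (m > 0 && m < 1e-150) {
        acc <- acc / m
        s <- s + log(m)
      }
      env$mats[[v]][[c]] <- acc
      env$sc[v, c] <- s
    }
  }

  dfs <- function(u, up_mats, up_sc) {
    for (e in prep$children[[u]]) {
      v <- edge[e, 2L]
      # rest = up * product over siblings (with current, possibly updated,
      # lengths and partials)
      rest_mats <- vector("list", k)
      rest_sc <- numeric(k)
      for (c in seq_len(k)) {
        acc <- up_mats[[c]]
        s <- up_sc[c]
        for (e2 in prep$children[[u]]) {
          if (e2 == e) next
          ch2 <- edge[e2, 2L]
          P <- pmat(prep$model, env$el[e2], rates[c])
          acc <- acc * (env$mats[[ch2]][[c]] %*% t(P))
          s <- s + env$sc[ch2, c]
        }
        m <- max(acc)
        if (m > 0 && m < 1e-150) {
          acc <- acc / m
          s <- s + log(m)
        }
        rest_mats[[c]] <- acc
        rest_sc[c] <- s
      }
      obj <- edge_objective(prep, rest_mats, rest_sc,
                            env$mats[[v]], env$sc[v, ])
      opt <- stats::optimize(obj, interval = c(min_branch, max_branch),
                             maximum = TRUE, tol = 1e-7)
      if (opt$objective >= obj(env$el[e])) env$el[e] <- opt$maximum
      if (v > prep$ntip) {
        # descend with the outside-partial pushed through the new length
        dn_mats <- vector("list", k)
        dn_sc <- numeric(k)
        for (c in seq_len(k)) {
          # outside-partial pushed from parent to child: by detailed balance
          # P(outside | j at child) = sum_i P_ji(t) rest_i, i.e. rest %*% t(P)
          P <- pmat(prep$model, env$el[e], rates[c])
          acc <- rest_mats[[c]] %*% t(P)
          m <- max(acc)
          s <- rest_sc[c]
          if (m > 0 && m < 1e-150) {
            acc <- acc / m
            s <- s + log(m)
          }
          dn_mats[[c]] <- acc
          dn_sc[c] <- s
        }
        dfs(v, dn_mats, dn_sc)
        recompute_down(v)
      }
    }
  }

  total_ll <- function() {
    f <- prep$model$frequencies
    logs <- matrix(0, prep$npat, k)
    for (c in seq_len(k)) {
      v <- as.numeric(env$mats[[prep$root]][[c]] %*% f)
      logs[, c] <- log(pmax(v, 1e-300)) + env$sc[prep$root, c]
    }
    sum(prep$wts * log_sum_exp_rows(logs, gamma$weights))
  }

  ones <- rep(list(matrix(1, prep$npat, 20L)), k)
  ll_prev <- total_ll()
  sweeps <- 0L
  converged <- FALSE
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    dfs(prep$root, ones, numeric(k))
    recompute_down(prep$root)
    ll_new <- total_ll()
    if (ll_new - ll_prev < tol) {
      ll_prev <- max(ll_prev, ll_new)
      converged <- TRUE
      break
    }
    ll_prev <- ll_new
  }
  if (!converged && warn_nonconvergence) {
    warning("branch-length optimization did not converge in ",
            max_sweeps, " sweeps; returning best tree so far")
  }
  out <- prep$tree
  out$edge.length <- env$el
  attr(out, "loglik") <- ll_prev
  attr(out, "sweeps") <- sweeps
  out
}

#' Estimate the gamma shape parameter by profile maximum likelihood
#'
#' Maximizes the tree likelihood over the gamma shape `alpha`, re-optimizing
#' branch lengths at each candidate value (a fixed number of sweeps from the
#' input tree, keeping the profile deterministic).  The search is performed
#' on the log scale over `interval`.
#'
#' @inheritParams tree_log_likelihood
#' @param n_categories number of discrete-gamma categories.
#' @param interval search bounds for alpha.
#' @param branch_sweeps branch-optimization sweeps per candidate alpha.
#' @param tol optimizer tolerance on log(alpha).
#' @return The ML shape estimate, with attributes `loglik` and `boundary`
#'   (TRUE, with a warning, if the optimum sits at the search boundary).
#' @export
estimate_alpha <- function(tree, aln, model, n_categories = 8L,
                           interval = c(0.05, 100), branch_sweeps = 2L,
                           tol = 0.01) {
  profile <- function(log_a) {
    g <- discrete_gamma(exp(log_a), n_categories)
    tr <- optimize_branch_lengths(tree, aln, model, g,
                                  max_sweeps = branch_sweeps,
                                  warn_nonconvergence = FALSE)
    attr(tr, "loglik")
  }
  opt <- stats::optimize(profile, interval = log(interval),
                         maximum = TRUE, tol = tol)
  alpha <- exp(opt$maximum)
  boundary <- alpha < interval[1] * 1.1 || alpha > interval[2] / 1.1
  if (boundary) {
    warning("alpha estimate at search boundary (", signif(alpha, 4), ")")
  }
  structure(alpha, loglik = opt$objective, boundary = boundary)
}

#' Nearest-neighbor-interchange hill climbing
#'
#' Greedy topology search: starting from the input tree (whose branch
#' lengths are first optimized), all NNI rearrangements are screened with a
#' small number of branch-optimization sweeps; the best candidate is fully
#' optimized and accepted if it strictly improves the log-likelihood.  The
#' search stops when no rearrangement improves, so the returned tree's
#' likelihood is always at least that of the input tree.  Ties are broken
#' by the first candidate in phangorn's deterministic NNI enumeration
#' order.
#'
#' @inheritParams optimize_branch_lengths
#' @param max_rounds maximum accepted rearrangements.
#' @param screen_sweeps branch sweeps used when screening candidates.
#' @return The best tree found, with attribute `loglik`.
#' @export
nni_search <- function(tree, aln, model, gamma, max_rounds = 20L,
                       screen_sweeps = 1L, tol = 1e-4) {
  cur <- optimize_branch_lengths(tree, aln, model, gamma, tol = tol,
                                 warn_nonconvergence = FALSE)
  ll_cur <- attr(cur, "loglik")
  rounds <- 0L
  while (rounds < max_rounds) {
    cands <- phangorn::nni(cur)
    scores <- vapply(cands, function(ct) {
      attr(optimize_branch_lengths(ct, aln, model, gamma,
                                   max_sweeps = screen_sweeps,
                                   warn_nonconvergence = FALSE), "loglik")
    }, numeric(1))
    best <- which.max(scores)
    if (scores[best] <= ll_cur + 1e-6) break
    cand <- optimize_branch_lengths(cands[[best]], aln, model, gamma,
                                    tol = tol, warn_nonconvergence = FALSE)
    if (attr(cand, "loglik") <= ll_cur + 1e-6) break
    cur <- cand
    ll_cur <- attr(cand, "loglik")
    rounds <- rounds + 1L
  }
  attr(cur, "loglik") <- ll_cur
  cur
}
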