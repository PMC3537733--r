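#' Maximum-likelihood pairwise genetic distance
#'
#' Estimates the evolutionary distance (expected substitutions per site)
#' between two aligned amino-acid sequences by maximizing the likelihood
#' \deqn{\ell(t) = \sum_s \log \sum_c w_c \, \pi_{a_s} P_{a_s b_s}(t r_c)}
#' under a reversible substitution model with discrete-gamma rate mixing.
#' Sites where either sequence carries a gap or ambiguity are skipped.
#' Identical site pairs are collapsed to patterns before optimization, and
#' the per-pattern likelihood is evaluated through the model's spectral
#' decomposition, so each candidate `t` costs a single matrix-vector
#' product.
#'
#' @param seq_a,seq_b aligned sequences: character vectors of residues, or
#'   single strings, of equal aligned length.
#' @param model an [aa_model()].
#' @param gamma a [discrete_gamma()] rate object.
#' @param t_max upper bound of the search interval (substitutions/site).
#' @param tol optimizer tolerance on `t`.
#' @return The ML distance estimate.  If the optimizer runs into `t_max`
#'   the value is clamped to `t_max`, a warning is raised and the result
#'   carries attribute `saturated = TRUE`.
#' @export
ml_distance <- function(seq_a, seq_b, model, gamma, t_max = 10, tol = 1e-6) {
  a <- encode_seq(seq_a)
  b <- encode_seq(seq_b)
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no comparable (gap-free in both) sites between the sequences")
  a <- a[ok]; b <- b[ok]
  if (all(a == b)) return(0)
  nll <- pair_negloglik(a, b, model, gamma)
  opt <- stats::optimize(nll, interval = c(0, t_max), tol = tol)
  t_hat <- opt$minimum
  if (t_hat > t_max - 100 * tol - 1e-4) {
    # refuse to report an interior optimum that is really a boundary hit
    if (nll(t_max) <= opt$objective + 1e-9) {
      warning("distance estimate saturated at t_max = ", t_max)
      t_hat <- structure(t_max, saturated = TRUE)
    }
  }
  t_hat
}

# Negative pairwise log-likelihood as a function of t, with site-pattern
# compression.  Returns a closure suitable for 1-D optimization.
pair_negloglik <- function(a, b, model, gamma) {
  key <- (a - 1L) * 20L + b
  tab <- table(key)
  keys <- as.integer(names(tab))
  wts <- as.numeric(tab)
  ai <- (keys - 1L) %/% 20L + 1L
  bi <- (keys - 1L) %% 20L + 1L
  # W[p, k] = pi_a V[a,k] Vinv[k,b]; site likelihood = W %*% exp(lambda t r)
  W <- model$frequencies[ai] * model$V[ai, , drop = FALSE] *
    t(model$Vinv)[bi, , drop = FALSE]
  lam <- model$lambda
  rates <- gamma$rates
  wcat <- gamma$weights
  function(t) {
    lik <- 0
    for (c in seq_along(rates)) {
      lik <- lik + wcat[c] * as.numeric(W %*% exp(lam * t * rates[c]))
    }
    -sum(wts * log(pmax(lik, 1e-300)))
  }
}

encode_seq <- function(s) {
  if (length(s) == 1L && is.character(s) && nchar(s) > 1L) {
    s <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  }
  match(toupper(as.character(s)), AA_STATES)
}

#' ML genetic-distance matrix for an alignment
#'
#' Estimates all pairwise ML distances independently under a shared model
#' and gamma shape (the same per-alignment shape used for tree likelihoods,
#' keeping distance estimation and topology testing internally consistent).
#'
#' @param aln an [msa()] with at least 3 sequences.
#' @inheritParams ml_distance
#' @return An object of class `genetic_dist`: list with `species` (ordered
#'   labels), `values` (symmetric matrix, zero diagonal) and `alpha_used`.
#' @export
distance_matrix <- function(aln, model, gamma, t_max = 10, tol = 1e-6) {
  stopifnot(inherits(aln, "msa"))
  n <- nrow(aln)
  if (n < 3L) stop("distance matrix requires at least 3 sequences")
  sp <- rownames(aln)
  enc <- msa_encode(aln)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- tryCatch(
        ml_distance_encoded(enc[i, ], enc[j, ], model, gamma, t_max, tol),
        error = function(e) {
          stop(sprintf("distance estimation failed for pair (%s, %s): %s",
                       sp[i], sp[j], conditionMessage(e)), call. = FALSE)
        }
      )
      d[i, j] <- d[j, i] <- as.numeric(dij)
    }
  }
  structure(list(species = sp, values = d, alpha_used = gamma$alpha),
            class = "genetic_dist")
}

# Same as ml_distance but for pre-encoded integer sequences.
ml_distance_encoded <- function(a, b, model, gamma, t_max = 10, tol = 1e-6) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  if (all(a == b)) return(0)
  nll <- pair_negloglik(a, b, model, gamma)
  opt <- stats::optimize(nll, interval = c(0, t_max), tol = tol)
  t_hat <- opt$minimum
  if (t_hat > t_max - 100 * tol - 1e-4 && nll(t_max) <= opt$objective + 1e-9) {
    warning("distance estimate saturated at t_max = ", t_max)
    t_hat <- structure(t_max, saturated = TRUE)
  }
  t_hat
}

#' @export
print.genetic_dist <- function(x, ...) {
  cat(sprintf("<genetic_dist: %d species, alpha = %.4g>\n",
              length(x$species), x$alpha_used))
  invisible(x)
}

#' @export
as.matrix.genetic_dist <- function(x, ...) x$values

#' @export
as.dist.genetic_dist <- function(m, ...) stats::as.dist(m$values)

#' Serialize a distance matrix
#'
#' `write_phylip_dist()` writes the square PHYLIP format (taxon count line,
#' then one row per taxon); `write_tsv_dist()` writes a labelled TSV.
#'
#' @param dm a `genetic_dist`.
#' @param path output file.
#' @export
write_phylip_dist <- function(dm, path) {
  stopifnot(inherits(dm, "genetic_dist"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(dm$species)), con)
  for (i in seq_along(dm$species)) {
    writeLines(paste0(formatC(dm$species[i], width = -10),
                      paste(sprintf("%.6f", dm$values[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
write_tsv_dist <- function(dm, path) {
  stopifnot(inherits(dm, "genetic_dist"))
  df <- data.frame(species = dm$species, dm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
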