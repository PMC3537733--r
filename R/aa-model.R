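#' Amino-acid state order used throughout the package (PAML convention)
#'
#' @format Character vector of the 20 one-letter amino-acid codes in the
#'   order of the LG rate matrix (A R N D C Q E G H I L K M F P S T W Y V).
#' @export
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build a reversible amino-acid substitution model
#'
#' Constructs a normalized instantaneous rate matrix \eqn{Q} from a symmetric
#' exchangeability matrix \eqn{S} and stationary frequencies \eqn{\pi}:
#' \eqn{Q_{ij} = S_{ij}\pi_j} for \eqn{i \ne j}, diagonal set so rows sum to
#' zero, and the whole matrix scaled so that \eqn{-\sum_i \pi_i Q_{ii} = 1},
#' i.e. one expected substitution per site per unit branch length at
#' stationarity.  The symmetrized matrix
#' \eqn{\Pi^{1/2} Q \Pi^{-1/2}} is eigendecomposed once so that transition
#' probabilities \eqn{P(t) = e^{Qt}} can be evaluated repeatedly at low cost.
#'
#' @param name model label.
#' @param frequencies numeric length-20 stationary frequencies (will be
#'   renormalized to sum exactly to one).
#' @param exchangeabilities either a symmetric non-negative 20x20 matrix with
#'   zero diagonal, or the 190 lower-triangle entries in column-major order.
#' @return An object of class `aa_model` with elements `name`, `frequencies`,
#'   `exchangeabilities`, `rate_matrix`, and the spectral factors
#'   `lambda`, `V`, `Vinv` such that `Q = V diag(lambda) Vinv`.
#' @seealso [lg_model()], [transition_prob()]
#' @export
aa_model <- function(name, frequencies, exchangeabilities) {
  f <- as.numeric(frequencies)
  if (length(f) != 20L || any(f <= 0)) {
    stop("frequencies must be 20 positive values")
  }
  f <- f / sum(f)
  if (is.matrix(exchangeabilities)) {
    S <- exchangeabilities
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
      stop("exchangeability matrix must be symmetric")
    }
  } else {
    if (length(exchangeabilities) != 190L) {
      stop("expected 190 lower-triangle exchangeabilities")
    }
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- as.numeric(exchangeabilities)
    S <- S + t(S)
  }
  if (any(S < 0)) stop("exchangeabilities must be nonnegative")
  diag(S) <- 0
  Q <- sweep(S, 2, f, "*")
  diag(Q) <- -rowSums(Q)
  mu <- -sum(f * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q / mu
  # symmetric eigendecomposition: B = D^{1/2} Q D^{-1/2} with D = diag(f)
  sq <- sqrt(f)
  B <- Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- eig$vectors / sq          # rows scaled: V = D^{-1/2} U
  Vinv <- t(eig$vectors * sq)    # Vinv = U' D^{1/2}
  structure(
    list(name = name, frequencies = f, exchangeabilities = S,
         rate_matrix = Q, lambda = eig$values, V = V, Vinv = Vinv),
    class = "aa_model"
  )
}

#' The LG amino-acid substitution model
#'
#' Returns the LG general amino-acid replacement model (the empirical
#' exchangeabilities and stationary frequencies estimated by Le and Gascuel
#' from a large alignment database), normalized to one expected substitution
#' per site per unit time.  The published constants are taken from the model
#' registry shipped with \pkg{phangorn} and validated on load (dimensions,
#' frequency sum, and a spot check of the first published exchangeability).
#'
#' @return An [aa_model()] object.
#' @examples
#' m <- lg_model()
#' range(rowSums(m$rate_matrix))       # rows sum to zero
#' -sum(m$frequencies * diag(m$rate_matrix))  # unit normalization
#' @export
lg_model <- function() {
  consts <- lg_constants()
  aa_model("LG", consts$frequencies, consts$exchangeabilities)
}

# Fetch the published LG constants from phangorn's internal model table and
# sanity-check them before use.
lg_constants <- function() {
  got <- tryCatch({
    fetch <- function() {
      Q <- NULL; bf <- NULL
      phangorn_getModelAA("LG", bf = TRUE, Q = TRUE)
      list(Q = Q, bf = bf)
    }
    fetch()
  }, error = function(e) NULL)
  if (is.null(got) || length(got$Q) != 190L || length(got$bf) != 20L ||
      abs(sum(got$bf) - 1) > 1e-6 || abs(got$Q[1] - 0.425093) > 1e-6) {
    stop("LG model constants unavailable or corrupt (configuration error)")
  }
  list(exchangeabilities = as.numeric(got$Q), frequencies = as.numeric(got$bf))
}

# Thin indirection so the unexported phangorn accessor is isolated in one
# place.  getModelAA assigns `Q` and `bf` into the caller's frame.
phangorn_getModelAA <- function(model, bf = TRUE, Q = TRUE) {
  fn <- utils::getFromNamespace("getModelAA", "phangorn")
  # evaluate in the caller's frame so the assignments land there
  eval.parent(as.call(list(fn, model, bf = bf, Q = Q)))
}

#' Discrete-gamma rate heterogeneity
#'
#' Discretizes a mean-one gamma distribution with shape `alpha` into
#' `n_categories` equal-probability categories, each represented by the mean
#' of its quantile slice (the TREE-PUZZLE/PHYML convention).  Category means
#' are computed in closed form via the incomplete-gamma identity
#' \eqn{E[X; a < X < b] = F_{\alpha+1}(b) - F_{\alpha+1}(a)} for a mean-one
#' gamma, so no numerical integration is involved.
#'
#' @param alpha gamma shape parameter, > 0. Large values approach rate
#'   homogeneity; small values give strong among-site variation.
#' @param n_categories number of categories (default 8).
#' @return An object of class `gamma_rates` with `alpha`, `n_categories`,
#'   `rates` (strictly increasing, mean one) and `weights` (each
#'   `1/n_categories`).
#' @examples
#' discrete_gamma(0.5, 8)$rates
#' @export
discrete_gamma <- function(alpha, n_categories = 8L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  k <- as.integer(n_categories)
  if (k < 1L) stop("n_categories must be >= 1")
  if (k == 1L) {
    rates <- 1
  } else {
    q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
    p <- stats::pgamma(q, shape = alpha + 1, rate = alpha)
    rates <- k * diff(p)
  }
  structure(
    list(alpha = alpha, n_categories = k, rates = rates,
         weights = rep(1 / k, k)),
    class = "gamma_rates"
  )
}

#' Transition-probability matrix P(t) = exp(Q t r)
#'
#' @param model an [aa_model()].
#' @param t branch length in expected substitutions per site (>= 0).
#' @param rate relative rate multiplier (>= 0), e.g. a gamma-category rate.
#' @return 20x20 row-stochastic matrix; entry (i, j) is the probability of
#'   state j after time `t * rate` given state i.
#' @export
transition_prob <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "aa_model"))
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  if (!is.finite(rate) || rate < 0) stop("rate must be >= 0")
  P <- model$V %*% (exp(model$lambda * t * rate) * model$Vinv)
  P[P < 0] <- 0
  P
}

#' @export
print.aa_model <- function(x, ...) {
  cat(sprintf("<aa_model %s: 20 states, unit-normalized reversible Q>\n", x$name))
  invisible(x)
}

#' @export
print.gamma_rates <- function(x, ...) {
  cat(sprintf("<gamma_rates alpha=%.4g, %d categories, rates %s>\n",
              x$alpha, x$n_categories,
              paste(sprintf("%.3g", x$rates), collapse = " ")))
  invisible(x)
}
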