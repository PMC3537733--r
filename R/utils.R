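# Internal RNG helpers: every stochastic entry point takes an explicit seed
# and restores the caller's RNG state afterwards, so pipeline runs are
# reproducible end-to-end without clobbering the session RNG.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Stable across platforms and R sessions: the key is hashed by a simple
#' polynomial rolling hash over its UTF-8 bytes and mixed with the master
#' seed modulo a Mersenne-ish prime below 2^31, so derived seeds are always
#' valid 32-bit integers.
#'
#' @param master integer master seed.
#' @param key character scalar (e.g. a pair identifier).
#' @param salt optional integer to derive several independent streams from
#'   the same (master, key).
#' @return A single integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, key, salt = 0L) {
  m <- 2147483629              # prime < 2^31; all arithmetic exact in doubles
  h <- 0
  for (b in utf8ToInt(as.character(key))) h <- (h * 131 + b) %% m
  s <- (abs(as.numeric(master)) %% m)
  out <- (s * 69069 + h * 2654435 + as.numeric(salt) * 97 + 1) %% m
  as.integer(out %% (m - 1) + 1)
}

upper_tri_values <- function(mat) mat[upper.tri(mat)]

log_sum_exp_rows <- function(logs, weights) {
  # logs: matrix (rows = sites, cols = components); returns per-row
  # log(sum_j weights_j * exp(logs_j))
  mx <- do.call(pmax, c(as.data.frame(logs), na.rm = TRUE))
  mx[!is.finite(mx)] <- 0
  log(rowSums(exp(logs - mx) * rep(weights, each = nrow(logs)))) + mx
}
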