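# Internal utilities: seeded evaluation, weighted quantiles, provenance hash.

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a reproducible sub-seed from a master seed and a stage label.
sub_seed <- function(seed, label) {
  h <- fnv1a(paste0(label, ":", format(seed, scientific = FALSE)))
  (as.numeric(seed) + h) %% 2147483647
}

# FNV-1a 32-bit hash of a character string (provenance fingerprints; no
# cryptographic claim).
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, split to stay exact
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

fnv1a_hex <- function(x) {
  h <- fnv1a(x)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Production-weighted empirical quantile
#'
#' Left-continuous inverse of the weighted empirical CDF: the quantile at
#' probability `p` is the smallest data value whose cumulative weight reaches
#' at least `p` of the total. Ties in `x` are merged before the scan, so a
#' quantile that falls on a tied value resolves toward the smaller value.
#' This is the single quantile convention used throughout the package
#' (envelope bounds and percentile class breaks), because classification
#' results depend on it.
#'
#' @param x Numeric values.
#' @param w Non-negative weights (default: equal).
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @examples
#' weighted_quantile(c(10, 15, 20, 25, 30), c(10, 20, 40, 20, 10), c(.025, .975))
#' @export
weighted_quantile <- function(x, w = rep(1, length(x)), probs) {
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]
  w <- w[keep]
  if (length(x) == 0) stop("no non-missing values", call. = FALSE)
  if (any(w < 0)) stop("negative weights", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]", call. = FALSE)
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) {
    if (p <= 0) return(xs[1])
    xs[which(cw >= p - 1e-15)[1]]
  }, numeric(1))
}
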