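# Internal helpers shared across modules.

#' @import methods
#' @importFrom stats rnorm runif setNames aggregate prcomp sd var lm coef
#' @importFrom utils read.delim read.csv write.csv adist head
NULL

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector (may contain -Inf).
#' @return log(sum(exp(x))), computed with a max shift.
#' @keywords internal
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (or an Inf/NaN propagates)
  m + log(sum(exp(x - m)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library functions never clobber the
# user's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic substream seed below 2^31, derived from (seed, index).
# Doubles are exact well past 2^52 so the modular arithmetic is safe.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}

# Content-addressed substream seed: a polynomial rolling hash of the key
# string folded with the master seed, so per-sequence randomness depends
# on the sequence itself, not on its position in a batch.
contentSeed <- function(seed, key) {
  vapply(key, function(k) {
    h <- 0
    for (v in utf8ToInt(k)) h <- (h * 31 + v) %% 2147483647
    as.integer((h + as.numeric(seed) * 48271) %% 2147483629)
  }, integer(1), USE.NAMES = FALSE)
}

softmaxRows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

assertProbVector <- function(p, what, tol = 1e-6) {
  if (any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(what, " must be a probability vector summing to 1", call. = FALSE)
  }
}

isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
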