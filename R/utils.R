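# Internal helpers shared across the package.

#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis
#' @importFrom utils modifyList
#' @importFrom methods as is
#' @importFrom Matrix sparseMatrix crossprod t rowSums nnzero
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards so package functions never
# perturb user-level randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  force(code)
}

# Deterministic content hash of a character vector. Polynomial rolling
# hashes over two coprime moduli, computed exactly in doubles (all
# intermediates < 2^53). Used to tie feature matrices to the vocabulary
# a model was trained on; collision resistance only needs to defeat
# accidental mismatches, not adversaries.
content_hash <- function(x) {
  s <- paste(as.character(x), collapse = "\x1f")
  if (!nzchar(s)) return("00000000-00000000")
  bytes <- utf8ToInt(s)
  h1 <- 5381
  h2 <- 52711
  for (b in bytes) {
    h1 <- (h1 * 33 + b) %% 4294967291
    h2 <- (h2 * 131 + b) %% 2147483647
  }
  sprintf("%010.0f-%010.0f", h1, h2)
}

# log(1 + exp(x)) without overflow for large |x|.
log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= -37
  mid <- !lo & x <= 18
  hi2 <- x > 18 & x <= 33.3
  top <- x > 33.3
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi2] <- x[hi2] + exp(-x[hi2])
  out[top] <- x[top]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
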