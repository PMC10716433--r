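# Internal helpers: seeded evaluation, stable string hashing, rounding.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# FNV-1a 32-bit hash of a string, done in doubles with 16-bit limbs so the
# 32-bit modular multiply stays exact (R has no unsigned 32-bit integers).
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(x)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * p) %% 65536) * 65536 + h0 * p
    h <- h %% 4294967296
  }
  h
}

# Derive a 32-bit-safe positive seed from a master seed and a cell key.
derive_seed <- function(master_seed, key) {
  s <- (as.numeric(master_seed) * 48271 + fnv1a(key)) %% 2147483647
  as.integer(max(1, s))
}

# round-half-away-from-zero for positive x (so 0.5 -> 1), used for
# fraction-of-pool removal counts.
round_half_up <- function(x) floor(x + 0.5)

# All permutations of a vector, lexicographic when v is sorted.
permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- vector("list", factorial(length(v)))
  k <- 0L
  for (i in seq_along(v)) {
    for (p in permutations_of(v[-i])) {
      k <- k + 1L
      out[[k]] <- c(v[i], p)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
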