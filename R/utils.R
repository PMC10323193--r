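# Internal helpers shared across modules.

# Deterministic sub-seed derivation: folds the master seed with any number of
# integer or character components through a Lehmer-style recurrence.  All
# arithmetic stays below 2^53 so doubles are exact; results fit in a 32-bit
# integer as required by set.seed().
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  comps <- list(...)
  s <- abs(as.double(master)) %% 2147483647
  for (k in comps) {
    if (is.character(k)) {
      codes <- utf8ToInt(k)
      k <- sum(codes * seq_along(codes))
    }
    s <- (s * 48271 + abs(as.double(k)) + 1) %% 2147483647
  }
  as.integer(s %% 2147483629 + 1)
}

# Evaluate expr with a locally derived RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical unordered-pair key for edge bookkeeping.
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}
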