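# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Counter-based derivation of per-unit seeds from a master seed, kept inside
# the 32-bit signed integer range so the result is a valid set.seed() input.
derive_seed <- function(master_seed, counter) {
  s <- (as.numeric(master_seed) * 48271 + as.numeric(counter) * 16807) %%
    2147483629
  as.integer(s)
}

# Shannon entropy (natural log) of a non-negative weight vector.
shannon_entropy <- function(w) {
  w <- w[w > 0]
  if (length(w) == 0) return(0)
  p <- w / sum(w)
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
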