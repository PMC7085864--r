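# Internal helpers shared across modules.

# Population (biased, divide-by-n) standard deviation. Used wherever a ratio
# of two spreads is formed, so the n/(n-1) factor cancels by construction.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code does not perturb user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit integer range R requires.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483647)
}

stopifnot_scalar_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
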