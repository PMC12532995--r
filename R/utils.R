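# Internal numerical and RNG helpers.

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Run `expr` under a local RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed from a master seed and a string key. Order-invariant
# across inputs because it depends only on (seed, key). Stays below 2^31.
derive_seed <- function(seed, key) {
  h <- 0
  for (cp in utf8ToInt(as.character(key))) h <- (h * 131 + cp) %% 2147483629
  as.integer((h + (as.numeric(seed) %% 2147483629) * 7919) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

VALID_ALLELES <- c("A", "C", "G", "T")

complement_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite scalar number", name), call. = FALSE)
}
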