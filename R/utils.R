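# Internal helpers shared across modules.

# round-half-away-from-zero; base round() rounds half to even, which would
# make masked-cell counts depend on the parity of p*n.
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Modal value of a vector of labels; ties broken by the lexicographically
# smallest label so that results are reproducible.
modal_value <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("cannot take the mode of an all-missing vector")
  tab <- table(as.character(x))
  names(tab)[order(-tab, names(tab))][1L]
}

# Deterministic 32-bit seed stream derived from a master seed and a string
# context (mechanism/proportion/replicate).  Keeps every derived seed in
# [1, 2^31 - 2] and independent of R's RNG state.
derive_seed <- function(master_seed, ...) {
  key <- paste(c(master_seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
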