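# Internal helpers shared across modules.

# Code-point (byte-wise, locale-independent) sorting and ordering. All node
# identifiers and labels in the package are compared this way so that results
# do not depend on the session locale.
sort_cp <- function(x) sort(x, method = "radix")

order_cp <- function(...) order(..., method = "radix")

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. All generator randomness flows through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Zero-padded node names "v001", ... used by the random generators.
pad_names <- function(n, prefix = "v") {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), seq_len(n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
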