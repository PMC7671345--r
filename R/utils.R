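# Internal helpers shared across modules.

# Derive a stage-specific seed from a base seed so each pipeline stage is
# independently reproducible. Kept strictly below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 1009) %% 2147483629L)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Zero-based column index of the unordered allele pair (a, b), a <= b,
# in the packed pair layout used by the C++ posterior matrix.
pair_col <- function(a, b, n_alleles) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  lo * n_alleles - lo * (lo - 1) / 2 + (hi - lo) + 1
}

# Inverse of pair_col: data.frame of zero-based allele indices for columns
# 1..n_alleles*(n_alleles+1)/2.
pair_index_table <- function(n_alleles) {
  lo <- rep(seq_len(n_alleles) - 1L, times = n_alleles - seq_len(n_alleles) + 1L)
  hi <- unlist(lapply(seq_len(n_alleles) - 1L, function(a) a:(n_alleles - 1L)))
  data.frame(a = lo, b = hi)
}

# Sort the two alleles of each call row lexicographically.
sort_pair <- function(a1, a2) {
  swap <- a1 > a2
  list(a1 = ifelse(swap, a2, a1), a2 = ifelse(swap, a1, a2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
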