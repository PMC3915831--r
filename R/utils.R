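# internal helpers shared across modules

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# derive `k` reproducible sub-seeds from one master seed (kept < 2^31)
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# canonicalize an unordered identifier pair: u <= v lexicographically
canonical_pair <- function(a, b) {
  swap <- a > b
  u <- ifelse(swap, b, a)
  v <- ifelse(swap, a, b)
  list(u = u, v = v)
}

edge_key <- function(u, v) paste(u, v, sep = "\r")

# FNV-1a over a string; used for run-manifest config fingerprints
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # h * p mod 2^32 without exceeding double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- rlang::`%||%`
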