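# Internal helpers shared across modules.

GT_STATES <- c("WT", "HET", "HOM")

# Deterministic 31-bit sub-stream seed derived from a base seed and a label,
# so each timepoint (cells, colonies) draws from its own reproducible stream.
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Size-ranked clone labels: A..Z, then A1, B1, ... (deterministic, readable).
clone_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, length.out = n - 26L),
                    rep(seq_len(ceiling((n - 26L) / 26L)), each = 26L)[seq_len(n - 26L)]))
}

# Shannon entropy (natural log) of a count or proportion vector.
shannon_entropy <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

`%||%` <- rlang::`%||%`
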