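# Internal helpers: stable hashing for per-gene RNG streams and output
# provenance, cutoff normalization, TSV writing with a comment header.

# 32-bit xor on doubles, split into 16-bit halves (bitwXor is 31-bit safe)
xor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

# FNV-1a 32-bit string hash, computed in split 16-bit arithmetic so every
# intermediate stays below 2^53 (doubles are exact there).
str_hash32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(x)) {
    h <- xor32(h, b)
    h <- (((h %/% 65536) * p) %% 65536) * 65536 + (h %% 65536) * p
    h <- h %% 4294967296
  }
  h
}

# deterministic per-gene seed in [0, 2^31-2]: probabilities do not depend on
# which other genes are scored in the same call
gene_seed <- function(seed, gene_id) {
  (as.numeric(seed) + str_hash32(gene_id)) %% 2147483647
}

hash_hex <- function(x) {
  h <- str_hash32(x)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# cutoffs may be fractions (0.8) or percents (80); values > 1 are percents
normalize_cutoff <- function(cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff))
    stop("cutoff must be a single number", call. = FALSE)
  if (cutoff < 0 || cutoff > 100)
    stop("cutoff must lie in [0, 1] (fraction) or (1, 100] (percent)",
         call. = FALSE)
  if (cutoff > 1) cutoff / 100 else cutoff
}

# results TSV with '#'-prefixed provenance header (version, seed, config hash)
write_mdeq_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# mdeq %s",
                     as.character(utils::packageVersion("mdeq"))), con)
  for (key in names(meta))
    writeLines(sprintf("# %s: %s", key, as.character(meta[[key]])), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
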