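# Internal helpers: seed derivation, argument checks.

# One user-facing seed expands into independent per-component streams via a
# fixed counter scheme, so partial re-runs (e.g. re-simulating embryo 7 only)
# reproduce the full-run draws. Values stay below 2^31 - 1.
derive_seed <- function(seed, key, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(seed) * 7919 + h * 104729 + counter * 15485863) %% 2147483629)
}

# Run `expr` under a derived seed without disturbing the caller's RNG state.
with_component_seed <- function(seed, key, counter = 0L, expr) {
  withr::with_seed(derive_seed(seed, key, counter), expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

# Chromosome-name helpers; sex chromosomes and the mitochondrial contig are
# recognised by name in either "chrX" or bare "X" style.
strip_chr <- function(x) sub("^chr", "", x)

is_sex_chrom <- function(x) strip_chr(x) %in% c("X", "Y")

is_x_chrom <- function(x) strip_chr(x) == "X"

is_y_chrom <- function(x) strip_chr(x) == "Y"

`%||%` <- function(a, b) if (is.null(a)) b else a
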