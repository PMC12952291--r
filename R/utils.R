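#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# FNV-1a 32-bit string hash. Constants from the published FNV reference
# (offset basis 2166136261, prime 16777619). Products stay below 2^53, so
# plain double arithmetic is exact and the result is platform-independent.
# XOR with a byte only affects the low 8 bits, so it is done on h %% 256.
fnv1a32 <- function(x) {
  vapply(x, function(s) {
    h <- 2166136261
    for (b in as.integer(charToRaw(s))) {
      lo <- h %% 256
      h <- h - lo + bitwXor(as.integer(lo), b)
      h <- (h * 16777619) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Derive a reproducible 31-bit seed from a master seed plus string labels.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))), collapse = "\r")
  as.integer(fnv1a32(key) %% 2147483646) + 1L
}
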