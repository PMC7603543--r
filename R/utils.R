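# Internal helpers: seeded substreams and a config hash.

# All randomness in the package flows from one user seed through named
# substreams, so e.g. the noise stream is unchanged by recording options.
# Returns an integer seed < 2^31 derived from (seed, stream name, index).
substream_seed <- function(seed, stream, i = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 1000003 + h * 7919 + i * 104729) %% 2147483629)
}

# FNV-1a hash (32-bit) of a string, returned as 8 hex digits. Arithmetic is
# done on 16-bit halves to stay inside exact double/integer range.
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), b)
    hi <- as.integer(h %/% 65536)
    # multiply (hi*2^16 + lo) by the FNV prime mod 2^32
    h <- ((hi * prime) %% 65536) * 65536 + lo * prime
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Recursively sort list keys so the hash is stable under key reordering.
canonicalise <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, canonicalise)
  } else {
    x
  }
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(canonicalise(unclass(config)), digits = NA,
                           auto_unbox = TRUE, force = TRUE)
  fnv1a(as.character(json))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
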