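# Internal helpers: seed streams, hashing, quantile-free ranking.

# Derive a 31-bit child seed from a master seed and a stream tag.
# Tags may be integers or short strings; the scheme is fixed so that a master
# seed fully determines every downstream draw.
derive_seed <- function(seed, tag) {
  if (is.character(tag)) tag <- string_hash31(tag)
  x <- (as.double(seed) %% 2147483647)
  x <- (x * 48271 + 7 * (as.double(tag) %% 2147483647) + 11) %% 2147483647
  x <- (x * 48271 + 3) %% 2147483647
  as.integer(max(1, x))
}

# FNV-1a over a character string, folded to 31 bits. Modular arithmetic is
# kept inside the exact-integer range of doubles.
string_hash31 <- function(s) {
  mulmod31 <- function(h, m) {
    h1 <- h %/% 65536
    h0 <- h %% 65536
    (((h1 * m) %% 2147483648) * 65536 + h0 * m) %% 2147483648
  }
  bytes <- as.integer(charToRaw(paste(s, collapse = "\r")))
  h <- 2166136261 %% 2147483648
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- mulmod31(h, 16777619)
  }
  as.integer(h %% 2147483647)
}

#' Hash of a configuration object
#'
#' Stable 31-bit content hash of a configuration (serialized to JSON first),
#' recorded in run logs so analyses can be traced back to exact settings.
#'
#' @param config any serializable R object.
#' @return integer hash.
#' @export
config_hash <- function(config) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  string_hash31(as.character(jsonlite::toJSON(plain, auto_unbox = TRUE,
                                              digits = 12)))
}

# Equal-size rank groups of x (1 = lowest), deterministic tie-break by id.
ntile_rank <- function(x, ids, n_groups = 4L) {
  ord <- order(x, ids)
  ranks <- integer(length(x))
  ranks[ord] <- ceiling(seq_along(x) * n_groups / length(x))
  as.integer(ranks)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
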