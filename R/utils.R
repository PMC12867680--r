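# Internal helpers shared across modules.

# Derive a reproducible 32-bit substream seed from a master seed and a
# (stream id, index) pair. Two rounds of a Lehmer-style multiplicative mix;
# always in [1, 2^31 - 2] so it is a valid set.seed() argument.
derive_seed <- function(master, stream, index) {
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (abs(as.double(master)) %% m + 1)
  x <- (x * 48271) %% m
  x <- (x + as.double(stream) * 69621 + 1) %% m
  x <- (x * 48271) %% m
  x <- (x + as.double(index) * 16807 + 1) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 1) + 1)
}

# FNV-1a hash of a character scalar, reported as 8 hex digits. Used to
# fingerprint topologies in ensemble records (no cryptographic intent).
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30 # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

topology_hash <- function(web) {
  edges <- which(web$adjacency, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  fnv1a_hash(paste(
    web$n_species,
    paste(edges[, 1], edges[, 2], sep = ">", collapse = ";"),
    sep = "|"
  ))
}

check_square <- function(J, what = "J") {
  if (!is.matrix(J) || !is.numeric(J) || nrow(J) != ncol(J)) {
    abort(sprintf("`%s` must be a square numeric matrix.", what))
  }
  invisible(J)
}

check_finite <- function(J, what = "J") {
  if (!all(is.finite(J))) {
    abort(sprintf("`%s` contains non-finite entries.", what))
  }
  invisible(J)
}
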