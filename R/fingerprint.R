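# Path-based hashed fingerprint with two reserved semantic bits. The
# hashed region holds linear-path features (atoms annotated by element,
# bonds by order class including zero); the two highest bit positions are
# reserved: Z = molecule has at least one zero-order bond, M = molecule
# contains a listed metal. Those bits keep the pre-filter from flooding the
# exact matcher with organic near-misses when the query is an
# organometallic fragment.

.FP_NBITS_HASHED <- 1024L
.FP_HASH_SEED <- 0x9747b28c  # fixed seed mixed into the string hash

# 32-bit FNV-1a over the path string, done in doubles to stay exact
.hash32 <- function(s) {
  h <- .FP_HASH_SEED
  for (b in utf8ToInt(s)) {
    lo <- bitwXor(h %% 65536, b %% 65536)
    h <- (h %/% 65536) * 65536 + lo
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# canonical texts of all simple paths of up to `maxlen` bonds
.path_features <- function(m, maxlen = 7L) {
  n <- n_atoms(m)
  if (n == 0L) return(character())
  adj <- .adjacency(m)
  el <- m$atoms$element
  cls <- .bond_class(m$bonds)
  feats <- new.env(parent = emptyenv())
  walk <- function(path_atoms, fwd, rev_, len) {
    assign(if (fwd <= rev_) fwd else rev_, TRUE, envir = feats)
    if (len == maxlen) return()
    at <- path_atoms[length(path_atoms)]
    nb <- adj$nbr[[at]]
    be <- adj$bond[[at]]
    for (k in seq_along(nb)) {
      w <- nb[k]
      if (w %in% path_atoms) next
      bc <- cls[be[k]]
      walk(c(path_atoms, w),
           paste0(fwd, bc, el[w]),
           paste0(el[w], bc, rev_),
           len + 1L)
    }
  }
  for (a in seq_len(n)) walk(a, el[a], el[a], 0L)
  ls(feats)
}

#' Path fingerprint with reserved zero-bond and metal bits
#'
#' Enumerates all simple paths of up to 7 bonds (atoms annotated by
#' element, bonds by order class including zero and aromatic), hashes each
#' path's canonical text to one position in a 1024-bit region, and sets two
#' reserved bits above it: Z (any zero-order bond present) and M (any
#' listed metal present). Deterministic for a given molecule. Kekule input
#' is normalized by [perceive_aromaticity()] first so that depiction does
#' not change the bits.
#'
#' @param m a `zmol`.
#' @param maxlen maximum path length in bonds (default 7).
#' @return object of class `zfp`: logical `bits` of length `nbits`,
#'   `nbits`, and the reserved-bit values `z_bit`, `m_bit`.
#' @export
fingerprint <- function(m, maxlen = 7L) {
  m <- perceive_aromaticity(m)
  nbits <- .FP_NBITS_HASHED + 2L
  bits <- logical(nbits)
  for (f in .path_features(m, maxlen)) {
    bits[(.hash32(f) %% .FP_NBITS_HASHED) + 1L] <- TRUE
  }
  z <- has_zero_bond(m)
  mt <- any(m$atoms$element %in% zob_option("metals"))
  bits[.FP_NBITS_HASHED + 1L] <- z
  bits[.FP_NBITS_HASHED + 2L] <- mt
  structure(list(bits = bits, nbits = nbits, z_bit = z, m_bit = mt),
            class = "zfp")
}

#' @export
print.zfp <- function(x, ...) {
  cat(sprintf("<fingerprint: %d/%d bits set, Z=%d, M=%d>\n",
              sum(x$bits), x$nbits, x$z_bit, x$m_bit))
  invisible(x)
}

.check_same_nbits <- function(a, b) {
  stopifnot(inherits(a, "zfp"), inherits(b, "zfp"))
  if (a$nbits != b$nbits)
    stop("fingerprints have different lengths", call. = FALSE)
}

#' Fingerprint pre-screen for substructure search
#'
#' TRUE iff every bit of the query fingerprint is also set in the
#' candidate: `(query AND candidate) == query`. If the query is a
#' substructure of the candidate this always holds (path features of a
#' subgraph are a subset of the supergraph's), so the screen produces no
#' false negatives; false positives are removed later by
#' [subgraph_match()].
#'
#' @param query,candidate `zfp` objects of equal length.
#' @return logical.
#' @export
fp_screen <- function(query, candidate) {
  .check_same_nbits(query, candidate)
  all(candidate$bits[query$bits])
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both fingerprints are empty.
#'
#' @param a,b `zfp` objects of equal length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  .check_same_nbits(a, b)
  union_n <- sum(a$bits | b$bits)
  if (union_n == 0L) return(1.0)
  sum(a$bits & b$bits) / union_n
}
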