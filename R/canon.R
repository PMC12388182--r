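# Canonical atom ranking and the structure-identity key. Ranking uses
# Morgan-style iterative refinement over atom invariants; residual ties are
# resolved by exhaustive individualization, taking the lexicographically
# smallest serialized form. The identity key is that minimal serialization;
# it plays the role an external identifier (InChI / TUCAN) plays for a live
# database, and an adapter to such tools can be hung off it.

# dense ranks (1..k) of a character key vector
.dense_rank <- function(keys) match(keys, sort(unique(keys)))

.initial_invariants <- function(m) {
  a <- m$atoms
  b <- m$bonds
  n <- nrow(a)
  deg <- integer(n)
  bclasses <- rep("", n)
  arom <- logical(n)
  if (nrow(b)) {
    cls <- .bond_class(b)
    for (i in seq_len(nrow(b))) {
      deg[b$a1[i]] <- deg[b$a1[i]] + 1L
      deg[b$a2[i]] <- deg[b$a2[i]] + 1L
      bclasses[b$a1[i]] <- paste0(bclasses[b$a1[i]], cls[i])
      bclasses[b$a2[i]] <- paste0(bclasses[b$a2[i]], cls[i])
      if (b$aromatic[i]) arom[c(b$a1[i], b$a2[i])] <- TRUE
    }
    bclasses <- vapply(strsplit(bclasses, ""), function(x) paste(sort(x), collapse = ""),
                       character(1))
  }
  h <- ifelse(is.na(a$hcount), -1L, a$hcount)
  iso <- ifelse(is.na(a$isotope), 0L, a$isotope)
  sprintf("%s|%d|%d|%d|%d|%s|%d", a$element, a$charge, iso, h, deg, bclasses, arom)
}

# refine a rank vector to the stable Morgan partition
.refine <- function(m, ranks) {
  b <- m$bonds
  cls <- .bond_class(b)
  n <- length(ranks)
  repeat {
    env <- rep("", n)
    if (nrow(b)) {
      pieces <- rep(list(character()), n)
      for (i in seq_len(nrow(b))) {
        pieces[[b$a1[i]]] <- c(pieces[[b$a1[i]]], sprintf("%s:%04d", cls[i], ranks[b$a2[i]]))
        pieces[[b$a2[i]]] <- c(pieces[[b$a2[i]]], sprintf("%s:%04d", cls[i], ranks[b$a1[i]]))
      }
      env <- vapply(pieces, function(p) paste(sort(p), collapse = ","), character(1))
    }
    new <- .dense_rank(sprintf("%04d|%s", ranks, env))
    if (identical(new, ranks)) return(ranks)
    ranks <- new
  }
}

# serialize under a discrete ranking (every rank distinct)
.serialize_ranked <- function(m, ranks) {
  a <- m$atoms
  ord <- order(ranks)
  h <- ifelse(is.na(a$hcount), -1L, a$hcount)
  iso <- ifelse(is.na(a$isotope), 0L, a$isotope)
  atom_part <- paste(sprintf("%s%+d.%d.H%d", a$element[ord], a$charge[ord],
                             iso[ord], h[ord]), collapse = ";")
  b <- m$bonds
  if (nrow(b)) {
    cls <- .bond_class(b)
    r1 <- pmin(ranks[b$a1], ranks[b$a2])
    r2 <- pmax(ranks[b$a1], ranks[b$a2])
    edges <- sprintf("%d-%d%s", r1, r2, cls)
    bond_part <- paste(edges[order(r1, r2)], collapse = ";")
  } else bond_part <- ""
  paste(atom_part, bond_part, sep = "|")
}

# exhaustive individualization: returns list(key, ranks) with discrete,
# input-order-independent ranks
.canonical_form <- function(m, ranks) {
  if (max(ranks) == length(ranks)) {
    return(list(key = .serialize_ranked(m, ranks), ranks = ranks))
  }
  tied <- tabulate(ranks)
  cell <- which(tied > 1L)[1]
  members <- which(ranks == cell)
  best <- NULL
  for (at in members) {
    r2 <- ranks * 2L
    r2[at] <- r2[at] - 1L  # individualize below its cell, then re-densify
    r2 <- .refine(m, .dense_rank(sprintf("%06d", r2)))
    cand <- .canonical_form(m, r2)
    if (is.null(best) || cand$key < best$key) best <- cand
  }
  best
}

#' Canonical atom ranking
#'
#' Iterative-refinement (Morgan-style extended-connectivity) ranking over
#' the invariants element, charge, isotope, hydrogen count, degree, the
#' multiset of incident bond classes (orders 0--3 and aromatic) and
#' aromatic-ring membership. The returned `orbit` ranks are the stable
#' refined partition -- atoms sharing a rank are (up to the refinement's
#' resolving power) automorphic; `labels` are discrete 1..n canonical
#' positions obtained by exhaustive individualization with the minimal
#' serialized form as tie-break, and are invariant under input atom
#' permutation.
#'
#' @param m a `zmol`; hydrogen counts are materialized first if missing.
#' @return object of class `zrank`: list with `orbit` (integer vector,
#'   ties = equivalent atoms) and `labels` (integer permutation, canonical
#'   position of each atom).
#' @export
canonical_rank <- function(m) {
  m <- add_implicit_hydrogens(m)
  ranks <- .refine(m, .dense_rank(.initial_invariants(m)))
  form <- .canonical_form(m, ranks)
  structure(list(orbit = ranks, labels = form$ranks, key = form$key),
            class = "zrank")
}

#' @export
print.zrank <- function(x, ...) {
  cat("<canonical ranking:", length(x$labels), "atoms,",
      max(x$orbit), "orbits>\n")
  invisible(x)
}

#' Structure-identity key
#'
#' Canonical serialization of a molecule: atoms in canonical order with
#' element, charge, isotope and hydrogen count, followed by the sorted edge
#' list with bond classes (zero-order bonds included). Two molecules get
#' the same key exactly when they are isomorphic as attributed graphs under
#' this model, so the key is the package's standard for deciding compound
#' identity. For purely organic compounds an external identifier could be
#' substituted at this point; the internal key is computed for all
#' molecules.
#'
#' @param m a `zmol`.
#' @return a single string.
#' @examples
#' k1 <- identity_key(make_metallocene("Fe"))
#' k2 <- identity_key(permute_atoms(make_metallocene("Fe"), sample(11)))
#' identical(k1, k2)  # TRUE
#' @export
identity_key <- function(m) canonical_rank(m)$key

#' Identity table for a batch of molecules
#'
#' One row per molecule: id, identity key, extended SMILES, and whether the
#' organometallic identifier regime applies.
#'
#' @param mols list of `zmol` (names used as ids when present).
#' @return data frame with columns `id`, `organometallic`, `key`, `smiles`.
#' @export
identity_table <- function(mols) {
  ids <- names(mols)
  if (is.null(ids)) ids <- as.character(seq_along(mols))
  data.frame(
    id = ids,
    organometallic = vapply(mols, is_organometallic, logical(1)),
    key = vapply(mols, identity_key, character(1)),
    smiles = vapply(mols, write_smiles, character(1)),
    row.names = NULL
  )
}
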