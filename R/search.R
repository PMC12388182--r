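# Exact zero-bond-aware subgraph matching and the two-stage substructure
# search. Matching contract: an injective atom mapping must preserve
# element and charge on atoms and bond-order class on bonds -- zero-order
# query bonds map only to zero-order target bonds, aromatic query bonds
# only to aromatic target bonds. Hydrogens are counts, not query
# constraints.

#' Exact substructure (subgraph isomorphism) test
#'
#' Backtracking search for an injective mapping of query atoms into target
#' atoms that preserves element and charge and maps every query bond onto
#' a target bond of the same class (orders 0--3 and aromatic as distinct
#' classes). Query atoms are processed rarest-compatible-candidates first,
#' extending along bonds where possible. Kekule inputs are normalized by
#' [perceive_aromaticity()] on both sides before matching so the result
#' does not depend on the drawn Kekule structure.
#'
#' @param q query `zmol`.
#' @param t target `zmol`.
#' @return logical; when TRUE, carries attribute `mapping` -- an integer
#'   vector giving the matched target atom for each query atom (one
#'   witness).
#' @examples
#' benzene <- parse_molfile(write_molfile(make_fixture_corpus(1, 1)[[1]]))
#' subgraph_match(molecule("C"), benzene)
#' @export
subgraph_match <- function(q, t) {
  q <- perceive_aromaticity(q)
  t <- perceive_aromaticity(t)
  nq <- n_atoms(q)
  nt <- n_atoms(t)
  if (nq == 0L) return(structure(TRUE, mapping = integer()))
  if (nq > nt) return(FALSE)

  qa <- q$atoms; ta <- t$atoms
  qcls <- .bond_class(q$bonds); tcls <- .bond_class(t$bonds)
  qadj <- .adjacency(q); tadj <- .adjacency(t)

  # per-atom incident bond-class counts, for degree-style pruning
  class_counts <- function(n, adj, cls) {
    lapply(seq_len(n), function(i) {
      out <- table(cls[adj$bond[[i]]])
      stats::setNames(as.integer(out), names(out))
    })
  }
  qcc <- class_counts(nq, qadj, qcls)
  tcc <- class_counts(nt, tadj, tcls)

  compat <- function(i, j) {
    if (qa$element[i] != ta$element[j] || qa$charge[i] != ta$charge[j]) return(FALSE)
    qc <- qcc[[i]]
    tc <- tcc[[j]]
    for (cl in names(qc)) {
      if (is.na(tc[cl]) || tc[cl] < qc[[cl]]) return(FALSE)
    }
    TRUE
  }
  cand <- lapply(seq_len(nq), function(i) which(vapply(seq_len(nt), function(j)
    compat(i, j), logical(1))))
  if (any(lengths(cand) == 0L)) return(FALSE)

  # order: rarest candidate list first, then prefer atoms bonded to an
  # already-ordered atom so the partial mapping stays connected
  ord <- integer(0)
  remaining <- seq_len(nq)
  while (length(remaining)) {
    attached <- remaining[vapply(remaining, function(i)
      any(qadj$nbr[[i]] %in% ord), logical(1))]
    pool <- if (length(ord) && length(attached)) attached else remaining
    nxt <- pool[which.min(lengths(cand)[pool])]
    ord <- c(ord, nxt)
    remaining <- setdiff(remaining, nxt)
  }

  mapping <- rep(NA_integer_, nq)
  used <- logical(nt)
  bt <- function(k) {
    if (k > nq) return(TRUE)
    i <- ord[k]
    for (j in cand[[i]]) {
      if (used[j]) next
      ok <- TRUE
      nb <- qadj$nbr[[i]]; be <- qadj$bond[[i]]
      for (x in seq_along(nb)) {
        mi <- mapping[nb[x]]
        if (is.na(mi)) next
        e <- .bond_between(t, j, mi)
        if (is.na(e) || tcls[e] != qcls[be[x]]) { ok <- FALSE; break }
      }
      if (!ok) next
      mapping[i] <<- j; used[j] <<- TRUE
      if (bt(k + 1L)) return(TRUE)
      mapping[i] <<- NA_integer_; used[j] <<- FALSE
    }
    FALSE
  }
  if (bt(1L)) structure(TRUE, mapping = mapping) else FALSE
}

#' Two-stage substructure search over a corpus
#'
#' Stage one screens every corpus fingerprint with [fp_screen()] (no false
#' negatives); stage two verifies the survivors with [subgraph_match()].
#' The search stops after `cutoff` verified hits (default 300) since
#' larger hit lists are not realistically inspected.
#'
#' @param q query `zmol`.
#' @param corpus list of `zmol`.
#' @param cutoff maximum number of verified hits to return.
#' @param fps optional precomputed list of corpus fingerprints (from
#'   [fingerprint()]), parallel to `corpus`.
#' @return object of class `substructure_hits`: `hits` (corpus positions,
#'   in corpus order), `n_screened` (candidates passing the fingerprint
#'   screen), `n_verified` (candidates run through the exact matcher) and
#'   `truncated` (TRUE when the cutoff stopped the scan).
#' @export
substructure_search <- function(q, corpus, cutoff = 300L, fps = NULL) {
  if (is.null(fps)) fps <- lapply(corpus, fingerprint)
  qfp <- fingerprint(q)
  hits <- integer()
  n_screened <- 0L
  n_verified <- 0L
  truncated <- FALSE
  for (i in seq_along(corpus)) {
    if (!fp_screen(qfp, fps[[i]])) next
    n_screened <- n_screened + 1L
    n_verified <- n_verified + 1L
    if (isTRUE(subgraph_match(q, corpus[[i]]))) {
      hits <- c(hits, i)
      if (length(hits) >= cutoff) { truncated <- TRUE; break }
    }
  }
  structure(list(hits = hits, n_screened = n_screened,
                 n_verified = n_verified, truncated = truncated),
            class = "substructure_hits")
}

#' @export
print.substructure_hits <- function(x, ...) {
  cat(sprintf("<substructure search: %d hit(s)%s; %d passed screen, %d verified>\n",
              length(x$hits), if (x$truncated) " (cutoff reached)" else "",
              x$n_screened, x$n_verified))
  invisible(x)
}
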