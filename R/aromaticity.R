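# Aromaticity perception over a minimum cycle basis (smallest set of
# smallest rings). Two routes make a ring aromatic:
#  (a) Hueckel 4n+2 counting over in-ring pi electrons, and
#  (b) the eta-ring rule for metal-coordinated all-carbon rings, where
#      every ring atom touches one common metal through a zero-order or
#      single bond (the ferrocene case: pi character is expressed by the
#      metal coordination, not by drawn charges).

# smallest set of smallest rings: for every edge, the shortest cycle
# through it (BFS with the edge removed), kept greedily while linearly
# independent over GF(2) on edge-incidence vectors. With
# exclude_metals = TRUE, bonds incident to a listed metal are ignored, so
# a metallocene yields its carbocycles rather than C-C-metal triangles --
# the ring system that matters for aromaticity and HOSE normalization.
.ring_basis <- function(m, exclude_metals = FALSE) {
  if (exclude_metals) {
    mt <- which(m$atoms$element %in% zob_option("metals"))
    if (length(mt)) {
      drop <- m$bonds$a1 %in% mt | m$bonds$a2 %in% mt
      if (any(drop)) {
        keep <- which(!drop)
        sub <- m
        sub$bonds <- m$bonds[keep, , drop = FALSE]
        rownames(sub$bonds) <- NULL
        rr <- .ring_basis(sub)
        return(lapply(rr, function(r) list(atoms = r$atoms, edges = keep[r$edges])))
      }
    }
  }
  b <- m$bonds
  nb <- nrow(b)
  n <- nrow(m$atoms)
  if (nb == 0L) return(list())
  adj <- .adjacency(m)
  ncomp_edges <- local({
    seen <- logical(n); comp <- 0L
    for (s in seq_len(n)) {
      if (seen[s]) next
      comp <- comp + 1L
      queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj$nbr[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    nb - n + comp
  })
  if (ncomp_edges <= 0L) return(list())

  candidates <- list()
  for (e in seq_len(nb)) {
    u <- b$a1[e]; v <- b$a2[e]
    # BFS from u to v avoiding edge e
    prev <- rep(NA_integer_, n); prevedge <- rep(NA_integer_, n)
    seen <- logical(n); seen[u] <- TRUE; queue <- u
    while (length(queue) && !seen[v]) {
      x <- queue[1]; queue <- queue[-1]
      nb_x <- adj$nbr[[x]]; be_x <- adj$bond[[x]]
      for (k in seq_along(nb_x)) {
        w <- nb_x[k]
        if (be_x[k] == e || seen[w]) next
        seen[w] <- TRUE; prev[w] <- x; prevedge[w] <- be_x[k]
        queue <- c(queue, w)
      }
    }
    if (!seen[v]) next
    edges <- e; atoms <- v
    x <- v
    while (x != u) {
      edges <- c(edges, prevedge[x])
      x <- prev[x]
      atoms <- c(atoms, x)
    }
    candidates[[length(candidates) + 1L]] <- list(atoms = atoms, edges = edges)
  }
  if (length(candidates) == 0L) return(list())
  candidates <- candidates[order(vapply(candidates, function(r) length(r$edges), integer(1)))]

  basis <- list()
  span <- list()  # reduced GF(2) vectors with pivot = lowest set edge
  for (r in candidates) {
    vec <- logical(nb); vec[r$edges] <- TRUE
    for (sv in span) if (vec[sv$pivot]) vec <- xor(vec, sv$vec)
    if (any(vec)) {
      span[[length(span) + 1L]] <- list(pivot = which(vec)[1], vec = vec)
      basis[[length(basis) + 1L]] <- r
      if (length(basis) == ncomp_edges) break
    }
  }
  basis
}

#' Ring atoms and bonds of a molecule
#'
#' Returns the smallest set of smallest rings as a list of
#' `list(atoms =, edges =)` entries (`edges` are bond-table row indices).
#'
#' @param m a `zmol`.
#' @param exclude_metals drop bonds incident to listed metals first, so
#'   metallocene contacts do not shatter the carbocycles into
#'   C-C-metal triangles (used by aromaticity perception).
#' @return list of rings (possibly empty).
#' @export
rings <- function(m, exclude_metals = FALSE) .ring_basis(m, exclude_metals)

# per-ring Hueckel pi-electron count; NA if some ring atom cannot conjugate
.huckel_pi <- function(m, ring) {
  a <- m$atoms
  b <- m$bonds
  ring_edges <- ring$edges
  total <- 0L
  for (at in ring$atoms) {
    inc <- which((b$a1 == at | b$a2 == at))
    in_ring <- intersect(inc, ring_edges)
    out_ring <- setdiff(inc, ring_edges)
    if (any(b$order[in_ring] >= 2L) || any(b$aromatic[in_ring])) {
      total <- total + 1L            # part of an in-ring double bond / aromatic system
    } else if (a$element[at] == "C" && a$charge[at] < 0L) {
      total <- total + 2L            # carbanion lone pair (cyclopentadienyl)
    } else if (a$element[at] %in% c("N", "O", "S", "P") && a$charge[at] <= 0L) {
      total <- total + 2L            # heteroatom lone pair (pyrrole-type)
    } else if (any(b$order[out_ring] >= 2L)) {
      return(NA_integer_)            # exocyclic double bond, no ring pi electron
    } else {
      return(NA_integer_)            # saturated atom breaks conjugation
    }
  }
  total
}

# eta-ring rule: all-carbon ring whose every atom touches one common listed
# metal via a zero-order or single bond
.eta_aromatic <- function(m, ring) {
  a <- m$atoms
  b <- m$bonds
  if (!all(a$element[ring$atoms] == "C")) return(FALSE)
  metals <- which(a$element %in% zob_option("metals"))
  if (length(metals) == 0L) return(FALSE)
  for (mt in metals) {
    ok <- vapply(ring$atoms, function(at) {
      e <- .bond_between(m, at, mt)
      !is.na(e) && b$order[e] %in% c(0L, 1L)
    }, logical(1))
    if (all(ok)) return(TRUE)
  }
  FALSE
}

#' Perceive aromatic rings
#'
#' Sets the aromatic flag on the bonds of every ring that is aromatic by
#' either route: (a) Hueckel 4n+2 counting over in-ring pi electrons
#' contributed by double bonds, anionic carbons and heteroatom lone pairs,
#' or (b) the eta-ring rule -- an all-carbon ring whose every atom is
#' attached to one common listed metal through a zero-order or single bond
#' (the metallocene case, where the drawing carries no charges). Rings
#' entered with all bonds already aromatic-flagged are left aromatic. Bond
#' orders are never changed, so the Kekule drawing survives; idempotent.
#'
#' @param m a `zmol`.
#' @return the molecule with aromatic flags set.
#' @export
perceive_aromaticity <- function(m) {
  validate_molecule(m)
  rr <- .ring_basis(m, exclude_metals = TRUE)
  if (length(rr) == 0L) return(m)
  for (ring in rr) {
    if (all(m$bonds$aromatic[ring$edges])) next
    pi_n <- .huckel_pi(m, ring)
    arom <- (!is.na(pi_n) && pi_n >= 2L && pi_n %% 4L == 2L) || .eta_aromatic(m, ring)
    if (arom) m$bonds$aromatic[ring$edges] <- TRUE
  }
  m
}
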