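# Independent brute-force oracles. These deliberately use exhaustive
# enumeration, not the package's backtracking/refinement algorithms, so
# they can arbitrate correctness on small inputs.

.oracle_bond_class <- function(bonds) ifelse(bonds$aromatic, "a", as.character(bonds$order))

# n_target x n_target matrix of bond classes ("" where no bond)
.oracle_class_matrix <- function(m) {
  n <- n_atoms(m)
  cm <- matrix("", n, n)
  b <- m$bonds
  cls <- .oracle_bond_class(b)
  for (i in seq_len(nrow(b))) {
    cm[b$a1[i], b$a2[i]] <- cls[i]
    cm[b$a2[i], b$a1[i]] <- cls[i]
  }
  cm
}

# exhaustive subgraph-isomorphism oracle: enumerate every injective
# assignment of query atoms to element/charge-compatible target atoms and
# test all query bonds on the complete assignment (vectorized over the
# full assignment grid)
brute_subgraph <- function(q, t) {
  q <- perceive_aromaticity(q)
  t <- perceive_aromaticity(t)
  nq <- n_atoms(q)
  nt <- n_atoms(t)
  if (nq == 0L) return(TRUE)
  if (nq > nt) return(FALSE)
  cand <- lapply(seq_len(nq), function(i) {
    which(t$atoms$element == q$atoms$element[i] &
            t$atoms$charge == q$atoms$charge[i])
  })
  if (any(lengths(cand) == 0L)) return(FALSE)
  if (prod(lengths(cand)) > 5e6) stop("oracle pair too large")
  grid <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
  if (nq > 1L) {
    inj <- apply(grid, 1L, function(r) !anyDuplicated(r))
    grid <- grid[inj, , drop = FALSE]
  }
  if (nrow(grid) == 0L) return(FALSE)
  cm <- .oracle_class_matrix(t)
  qcls <- .oracle_bond_class(q$bonds)
  ok <- rep(TRUE, nrow(grid))
  for (e in seq_len(nrow(q$bonds))) {
    i <- q$bonds$a1[e]; j <- q$bonds$a2[e]
    ok <- ok & (cm[cbind(grid[, i], grid[, j])] == qcls[e])
    if (!any(ok)) return(FALSE)
  }
  any(ok)
}

# automorphism orbits by exhaustive backtracking over attribute-compatible
# bijections; adjacency (bond class, including non-adjacency) must be
# preserved exactly
brute_orbits <- function(m) {
  m <- add_implicit_hydrogens(m)
  n <- n_atoms(m)
  cm <- .oracle_class_matrix(m)
  a <- m$atoms
  lab <- paste(a$element, a$charge, ifelse(is.na(a$hcount), -1L, a$hcount))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  unite <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[rx] <<- ry
  }
  mapping <- integer(n)
  used <- logical(n)
  rec <- function(k) {
    if (k > n) {
      for (i in seq_len(n)) unite(i, mapping[i])
      return(invisible())
    }
    for (j in seq_len(n)) {
      if (used[j] || lab[j] != lab[k]) next
      ok <- TRUE
      for (i in seq_len(k - 1L)) {
        if (cm[k, i] != cm[j, mapping[i]]) { ok <- FALSE; break }
      }
      if (!ok) next
      mapping[k] <<- j; used[j] <<- TRUE
      rec(k + 1L)
      used[j] <<- FALSE
    }
  }
  rec(1L)
  vapply(seq_len(n), find, integer(1))
}

# (subgraph, supergraph) pair: extract a connected vertex subset of a
# perceived molecule, keep its induced bonds, optionally drop a few -- the
# result is a true subgraph with consistent aromatic annotation
random_subgraph_pair <- function(max_target = 12L, max_query = 5L) {
  repeat {
    h <- perceive_aromaticity(random_test_molecule())
    if (n_atoms(h) >= 2L && n_atoms(h) <= max_target) break
  }
  nh <- n_atoms(h)
  nq <- sample(seq_len(min(max_query, nh)), 1)
  adjh <- lapply(seq_len(nh), function(i)
    unique(c(h$bonds$a2[h$bonds$a1 == i], h$bonds$a1[h$bonds$a2 == i])))
  sel <- sample(nh, 1)
  while (length(sel) < nq) {
    frontier <- setdiff(unique(unlist(adjh[sel])), sel)
    if (length(frontier) == 0L) break
    sel <- c(sel, if (length(frontier) == 1L) frontier else sample(frontier, 1))
  }
  keep <- h$bonds$a1 %in% sel & h$bonds$a2 %in% sel
  bonds <- h$bonds[keep, , drop = FALSE]
  if (nrow(bonds) > 1L && stats::runif(1) < 0.3) {
    bonds <- bonds[-sample(nrow(bonds), 1), , drop = FALSE]
  }
  remap <- match(seq_len(nh), sel)
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  atoms <- h$atoms[sel, , drop = FALSE]
  atoms$hcount <- NA_integer_  # hydrogens are not query constraints
  rownames(atoms) <- NULL
  g <- molecule(atoms, bonds)
  list(query = g, target = h)
}
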