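# Extended HOSE codes: sphere-wise encoding of an atom's environment,
# extended with "<" for zero-order bonds. Bond symbols, heaviest first:
#   %  triple    =  double    *  aromatic    (none)  single    <  zero
# The legacy ">" coordinate-bond symbol of classic HOSE codes is a related
# but different concept; it is tolerated in stored reference code text
# (normalized to "<" on comparison) but never emitted.
#
# Code layout (one normative choice, applied everywhere):
#   <focus token>;<sphere 1>/<sphere 2>/.../<sphere depth>
# Within a sphere, the neighbor groups of consecutive parent atoms are
# separated by ",". Each neighbor is rendered as bond symbol + atom token;
# an already-visited neighbor becomes the ring-closure token "&". Hydrogen
# atoms are counts, not vertices, and are ignored. The depth-s code is by
# construction a prefix of the depth-(s+1) code.

.hose_bond_rank <- c("%" = 1L, "=" = 2L, "*" = 3L, " " = 4L, "<" = 5L)

.hose_bond_symbol <- function(order, aromatic) {
  if (aromatic) "*" else switch(as.character(order), "0" = "<", "1" = " ", "2" = "=", "3" = "%")
}

.hose_element_rank <- local({
  pref <- c("C", "O", "N", "S", "P", "Si", "B", "F", "Cl", "Br", "I")
  function(el) {
    r <- match(el, pref)
    ifelse(is.na(r), 100L, r)
  }
})

.hose_atom_token <- function(element, charge) {
  chg <- if (charge > 0L) paste0("+", if (charge > 1L) charge else "")
         else if (charge < 0L) paste0("-", if (charge < -1L) -charge else "") else ""
  paste0(element, chg)
}

# depth-bounded neighborhood string, used only as a permutation-invariant
# sort key when ordering sibling branches
.hose_subtree_key <- function(m, adj, atom, from, depth) {
  tok <- .hose_atom_token(m$atoms$element[atom], m$atoms$charge[atom])
  if (depth == 0L) return(tok)
  nb <- adj$nbr[[atom]]
  be <- adj$bond[[atom]]
  parts <- character()
  for (k in seq_along(nb)) {
    if (nb[k] == from) next
    sym <- .hose_bond_symbol(m$bonds$order[be[k]], m$bonds$aromatic[be[k]])
    parts <- c(parts, paste0(sym, .hose_subtree_key(m, adj, nb[k], atom, depth - 1L)))
  }
  paste0(tok, "(", paste(sort(parts), collapse = ""), ")")
}

#' Normalize a molecule for HOSE-code generation
#'
#' Returns a copy prepared for environment encoding: (a) any single bond
#' between a listed metal and a ring atom whose ring holds at least one
#' other atom zero-bonded to the same metal is reclassified as a zero bond
#' -- this makes the five carbons of an eta5 ring equivalent even when the
#' drawing used one sigma bond plus four zero bonds; (b) in-ring double
#' bonds of aromatic rings are demoted to the aromatic bond class (order 1
#' with the aromatic flag), so the code does not depend on which Kekule
#' structure was drawn. Aromaticity is perceived first if needed. The input
#' molecule is left untouched.
#'
#' @param m a `zmol`.
#' @return the normalized copy.
#' @export
normalize_for_hose <- function(m) {
  m <- perceive_aromaticity(m)
  metals <- which(m$atoms$element %in% zob_option("metals"))
  if (length(metals)) {
    rr <- .ring_basis(m, exclude_metals = TRUE)
    b <- m$bonds
    for (mt in metals) {
      zero_partners <- unique(c(b$a1[b$order == 0L & b$a2 == mt],
                                b$a2[b$order == 0L & b$a1 == mt]))
      if (length(zero_partners) == 0L) next
      for (ring in rr) {
        if (!any(ring$atoms %in% zero_partners)) next
        for (at in setdiff(ring$atoms, zero_partners)) {
          e <- .bond_between(m, at, mt)
          if (!is.na(e) && m$bonds$order[e] == 1L) {
            m$bonds$order[e] <- 0L
            m$bonds$aromatic[e] <- FALSE
          }
        }
      }
    }
  }
  demote <- m$bonds$aromatic & m$bonds$order > 1L
  m$bonds$order[demote] <- 1L
  # a sigma bond turned zero bond may complete an eta ring: re-perceive
  perceive_aromaticity(m)
}

#' Generate an extended HOSE code
#'
#' Breadth-first sphere expansion from the focus atom. Neighbors are
#' rendered as bond symbol plus element token (with charge); bond symbols
#' are `%` (triple), `=` (double), `*` (aromatic), nothing (single) and `<`
#' (zero-order). Zero bonds are traversed like any other bond, so a metal
#' reached through a zero bond contributes its own neighbors (the second
#' ring of a metallocene) to deeper spheres; set
#' `zob_options(hose_through_metals = FALSE)` to stop expansion at metals.
#' Hydrogens are counts and never appear. Within a sphere, a parent's
#' neighbors are ordered by descending priority: bond-symbol rank, element
#' rank, then a depth-bounded extended-connectivity key; residual ties
#' break by canonical rank. Atoms seen before render as the ring-closure
#' token `&`.
#'
#' @param m a `zmol`.
#' @param focus 1-based atom index.
#' @param max_spheres number of spheres to encode (default 4).
#' @param normalize normalize via [normalize_for_hose()] first (default
#'   TRUE; a no-op on already-normalized input).
#' @return object of class `hose`: list with `focus`, `spheres` (character
#'   vector of length `max_spheres`), `text` and `depth`.
#' @examples
#' fc <- make_metallocene("Fe")
#' generate_hose(fc, 2)$text
#' @export
generate_hose <- function(m, focus, max_spheres = 4L, normalize = TRUE) {
  if (length(focus) != 1L || is.na(focus) || focus < 1L || focus > n_atoms(m))
    stop("focus atom out of range", call. = FALSE)
  if (max_spheres < 1L) stop("max_spheres must be >= 1", call. = FALSE)
  if (normalize) m <- normalize_for_hose(m)
  adj <- .adjacency(m)
  orbit <- canonical_rank(m)
  through_metals <- isTRUE(zob_option("hose_through_metals"))
  metals <- zob_option("metals")

  visited <- logical(n_atoms(m))
  visited[focus] <- TRUE
  used_bond <- logical(nrow(m$bonds))
  frontier <- focus
  spheres <- character(max_spheres)

  for (s in seq_len(max_spheres)) {
    groups <- character(length(frontier))
    next_frontier <- integer()
    for (gi in seq_along(frontier)) {
      at <- frontier[gi]
      if (!through_metals && at != focus && m$atoms$element[at] %in% metals) {
        groups[gi] <- ""
        next
      }
      nb <- adj$nbr[[at]]
      be <- adj$bond[[at]]
      keep <- !used_bond[be]
      nb <- nb[keep]; be <- be[keep]
      if (length(nb) == 0L) { groups[gi] <- ""; next }
      syms <- vapply(seq_along(nb), function(k)
        .hose_bond_symbol(m$bonds$order[be[k]], m$bonds$aromatic[be[k]]), character(1))
      keys <- vapply(seq_along(nb), function(k)
        .hose_subtree_key(m, adj, nb[k], at, 3L), character(1))
      # ring closures (already-visited neighbors) sort before new atoms of
      # the same bond class, so traversal history cannot leak numbering
      # noise into the rendering of symmetric environments
      closing <- visited[nb]
      ord <- order(.hose_bond_rank[syms], !closing,
                   .hose_element_rank(m$atoms$element[nb]), keys, orbit$labels[nb])
      toks <- character(length(ord))
      for (j in seq_along(ord)) {
        k <- ord[j]
        used_bond[be[k]] <- TRUE
        if (visited[nb[k]]) {
          toks[j] <- paste0(sub(" $", "", syms[k]), "&")
        } else {
          visited[nb[k]] <- TRUE
          toks[j] <- paste0(sub(" $", "", syms[k]),
                            .hose_atom_token(m$atoms$element[nb[k]], m$atoms$charge[nb[k]]))
          next_frontier <- c(next_frontier, nb[k])
        }
      }
      groups[gi] <- paste(toks, collapse = "")
    }
    spheres[s] <- paste(groups, collapse = ",")
    frontier <- next_frontier
  }

  focus_tok <- .hose_atom_token(m$atoms$element[focus], m$atoms$charge[focus])
  structure(
    list(focus = focus, spheres = spheres,
         text = paste0(focus_tok, ";", paste(spheres, collapse = "/")),
         depth = as.integer(max_spheres)),
    class = "hose"
  )
}

#' @export
print.hose <- function(x, ...) {
  cat("<HOSE code, focus atom", x$focus, "depth", x$depth, ">\n ", x$text, "\n")
  invisible(x)
}

#' Truncate a HOSE code to fewer spheres
#'
#' Returns the depth-`s` code; by the prefix property this equals the code
#' [generate_hose()] would produce with `max_spheres = s`.
#'
#' @param code a `hose` object.
#' @param s target depth, `1 <= s <= code$depth`.
#' @return a `hose` object of depth `s`.
#' @export
hose_truncate <- function(code, s) {
  stopifnot(inherits(code, "hose"))
  if (s < 1L || s > code$depth) stop("truncation depth out of range", call. = FALSE)
  spheres <- code$spheres[seq_len(s)]
  focus_tok <- sub(";.*$", "", code$text)
  structure(
    list(focus = code$focus, spheres = spheres,
         text = paste0(focus_tok, ";", paste(spheres, collapse = "/")),
         depth = as.integer(s)),
    class = "hose"
  )
}

# accept legacy ">" coordinate-bond symbol in stored reference code text
.normalize_code_text <- function(text) gsub(">", "<", text, fixed = TRUE)

#' HOSE codes for all atoms, as a table
#'
#' Convenience export: one row per (atom, depth) with the code text.
#'
#' @param m a `zmol`.
#' @param atoms atom indices (default: all non-hydrogen atoms).
#' @param max_spheres maximum depth.
#' @param id molecule identifier placed in the first column.
#' @return data frame with columns `id`, `atom`, `depth`, `code`.
#' @export
hose_table <- function(m, atoms = NULL, max_spheres = 4L, id = m$title) {
  mn <- normalize_for_hose(m)
  if (is.null(atoms)) atoms <- which(mn$atoms$element != "H")
  rows <- list()
  for (at in atoms) {
    code <- generate_hose(mn, at, max_spheres, normalize = FALSE)
    for (s in seq_len(max_spheres)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, atom = at, depth = s, code = hose_truncate(code, s)$text
      )
    }
  }
  do.call(rbind, rows)
}
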