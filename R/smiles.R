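# Canonical SMILES output, extended with the apostrophe bond symbol for
# zero-order bonds. With the apostrophe the bond alphabet reads .'-=#$ from
# "light" to "heavy": the zero bond sits between "no bond" (.) and a single
# bond. The dialect is write-only; the apostrophe is not part of standard
# SMILES and is not parsed back.

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.smiles_bond_symbol <- function(order, aromatic) {
  if (aromatic) "" else switch(as.character(order), "0" = "'", "1" = "", "2" = "=", "3" = "#")
}

.smiles_atom_token <- function(m, i, aromatic_atom) {
  a <- m$atoms
  el <- a$element[i]
  lower_ok <- aromatic_atom && el %in% c("B", "C", "N", "O", "P", "S")
  sym <- if (lower_ok) tolower(el) else el
  plain <- el %in% .organic_subset && a$charge[i] == 0L && is.na(a$isotope[i]) &&
    (is.na(a$hcount[i]) || a$hcount[i] == .expected_implicit_h(m, i))
  if (plain) return(sym)
  h <- a$hcount[i]
  htxt <- if (!is.na(h) && h > 0L) paste0("H", if (h > 1L) h else "") else ""
  chg <- a$charge[i]
  ctxt <- if (chg > 0L) paste0("+", if (chg > 1L) chg else "")
          else if (chg < 0L) paste0("-", if (chg < -1L) -chg else "") else ""
  iso <- if (!is.na(a$isotope[i])) a$isotope[i] else ""
  paste0("[", iso, sym, htxt, ctxt, "]")
}

# what the hydrogen rules would compute for this atom (used to decide
# whether an explicit count can stay implicit in SMILES)
.expected_implicit_h <- function(m, i) {
  valences <- zob_option("valences")
  el <- m$atoms$element[i]
  if (!el %in% names(valences)) return(0L)
  b <- m$bonds
  inc <- b$order[b$a1 == i | b$a2 == i]
  max(0L, .effective_valence(el, m$atoms$charge[i], valences) - sum(inc))
}

#' Write canonical SMILES with the zero-bond extension
#'
#' Emits standard SMILES for organic molecules; order-0 bonds are written
#' with an apostrophe between the two atom tokens (before the ring-closure
#' digit when the zero bond closes a ring). Atoms of aromatic rings are
#' written lowercase; zero bonds never make an atom lowercase. Output is
#' canonical: atom order follows [canonical_rank()] labels, so isomorphic
#' molecules give identical strings.
#'
#' @param m a `zmol`.
#' @return a single SMILES string.
#' @examples
#' write_smiles(molecule(c("C", "C"), list(c(1, 2, 1))))  # "CC"
#' @export
write_smiles <- function(m) {
  m <- add_implicit_hydrogens(m)
  n <- nrow(m$atoms)
  if (n == 0L) return("")
  labels <- canonical_rank(m)$labels
  adj <- .adjacency(m)
  b <- m$bonds
  arom_atom <- logical(n)
  if (nrow(b)) arom_atom[unique(c(b$a1[b$aromatic], b$a2[b$aromatic]))] <- TRUE

  visited <- logical(n)
  used_bond <- logical(nrow(b))
  children <- rep(list(integer()), n)     # tree-edge bond rows, in visit order
  closures <- rep(list(list()), n)        # list of (digit, symbol) at each atom
  digit <- 0L

  dfs_order <- function(v) {
    visited[v] <<- TRUE
    nb <- adj$nbr[[v]]
    be <- adj$bond[[v]]
    ord <- order(labels[nb])
    for (k in ord) {
      w <- nb[k]; e <- be[k]
      if (used_bond[e]) next
      if (visited[w]) {
        used_bond[e] <<- TRUE
        digit <<- digit + 1L
        sym <- .smiles_bond_symbol(b$order[e], b$aromatic[e])
        dg <- if (digit > 9L) paste0("%", digit) else as.character(digit)
        # bond symbol only at the first-rendered (opening) digit, so each
        # bond contributes its symbol exactly once to the string
        closures[[v]] <<- c(closures[[v]], list(list(dg, "")))
        closures[[w]] <<- c(closures[[w]], list(list(dg, sym)))
      } else {
        used_bond[e] <<- TRUE
        children[[v]] <<- c(children[[v]], e)
        dfs_order(w)
      }
    }
  }

  render <- function(v) {
    out <- .smiles_atom_token(m, v, arom_atom[v])
    for (cl in closures[[v]]) out <- paste0(out, cl[[2]], cl[[1]])
    ch <- children[[v]]
    for (k in seq_along(ch)) {
      e <- ch[k]
      w <- if (b$a1[e] == v) b$a2[e] else b$a1[e]
      part <- paste0(.smiles_bond_symbol(b$order[e], b$aromatic[e]), render(w))
      out <- if (k < length(ch)) paste0(out, "(", part, ")") else paste0(out, part)
    }
    out
  }

  pieces <- character()
  roots <- order(labels)
  for (v in roots) {
    if (visited[v]) next
    dfs_order(v)
    pieces <- c(pieces, render(v))
  }
  paste(pieces, collapse = ".")
}
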