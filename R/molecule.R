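# The molecule container: an attributed graph shared by organic and
# organometallic species. Atoms and bonds are data frames so that vectorized
# operations (valence sums, bond-class tables) stay cheap.

.bond_stereo_levels <- c("none", "wedge_up", "wedge_down")

#' Construct a molecule
#'
#' A molecule is an attributed graph: an ordered atom table and a bond
#' table. Atom order is significant (it is the 1-based molfile order and the
#' reference frame for shift assignments). Bond orders are 0, 1, 2 or 3; an
#' order-0 "zero bond" records an interaction that is not a well-defined
#' covalent bond and contributes nothing to valence. The graph may be
#' disconnected (salts, counter-ions), and at most one bond may join any
#' atom pair.
#'
#' @param atoms data frame with columns `element` (character; periodic-table
#'   symbol), and optionally `charge` (integer, default 0), `isotope`
#'   (integer or NA), `hcount` (explicit hydrogen count, integer or NA --
#'   NA means "not specified, compute by rule where allowed"), `x`, `y`,
#'   `z` (drawing coordinates, default 0). A character vector of element
#'   symbols is also accepted.
#' @param bonds data frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (0--3) and optionally `aromatic` (logical) and `stereo`
#'   (`"none"`, `"wedge_up"`, `"wedge_down"`). A list of `c(a1, a2, order)`
#'   triples is also accepted. May be empty.
#' @param title molecule title (molfile header line 1).
#' @param properties named list of SDF data items (character values).
#' @return an object of class `zmol`.
#' @examples
#' # hydrogen cyanide
#' m <- molecule(c("C", "N"), list(c(1, 2, 3)))
#' n_atoms(m)
#' @export
molecule <- function(atoms, bonds = NULL, title = "", properties = list()) {
  if (is.character(atoms)) atoms <- data.frame(element = atoms)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$element)) stop("atoms need an 'element' column", call. = FALSE)
  n <- nrow(atoms)
  if (is.null(atoms$charge)) atoms$charge <- rep(0L, n)
  if (is.null(atoms$isotope)) atoms$isotope <- rep(NA_integer_, n)
  if (is.null(atoms$hcount)) atoms$hcount <- rep(NA_integer_, n)
  for (cc in c("x", "y", "z")) if (is.null(atoms[[cc]])) atoms[[cc]] <- rep(0, n)
  atoms$charge <- as.integer(atoms$charge)
  atoms$isotope <- as.integer(atoms$isotope)
  atoms$hcount <- as.integer(atoms$hcount)
  atoms <- atoms[, c("element", "charge", "isotope", "hcount", "x", "y", "z")]

  if (is.null(bonds)) bonds <- list()
  if (is.list(bonds) && !is.data.frame(bonds)) {
    bonds <- if (length(bonds) == 0L) {
      data.frame(a1 = integer(), a2 = integer(), order = integer())
    } else {
      do.call(rbind, lapply(bonds, function(b) {
        data.frame(a1 = b[1], a2 = b[2], order = b[3])
      }))
    }
  }
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (is.null(bonds$aromatic)) bonds$aromatic <- logical(nrow(bonds))
  if (is.null(bonds$stereo)) bonds$stereo <- rep("none", nrow(bonds))
  bonds$a1 <- as.integer(bonds$a1)
  bonds$a2 <- as.integer(bonds$a2)
  bonds$order <- as.integer(bonds$order)
  bonds$aromatic <- as.logical(bonds$aromatic)
  bonds <- bonds[, c("a1", "a2", "order", "aromatic", "stereo")]

  m <- structure(
    list(atoms = atoms, bonds = bonds, title = as.character(title)[1],
         properties = properties),
    class = "zmol"
  )
  validate_molecule(m)
  m
}

#' Validate a molecule's structural invariants
#'
#' Checks that every bond joins two distinct existing atoms, that bond
#' orders lie in 0--3, that no atom pair is bonded twice, that hydrogen
#' counts are non-negative and that zero bonds carry no wedge mark.
#'
#' @param m a `zmol`.
#' @return `m`, invisibly; stops on violation.
#' @export
validate_molecule <- function(m) {
  stopifnot(inherits(m, "zmol"))
  n <- nrow(m$atoms)
  b <- m$bonds
  if (nrow(b)) {
    if (any(b$a1 < 1L | b$a1 > n | b$a2 < 1L | b$a2 > n))
      stop("bond references a nonexistent atom", call. = FALSE)
    if (any(b$a1 == b$a2))
      stop("bond endpoints must be two distinct atoms", call. = FALSE)
    if (!all(b$order %in% 0:3))
      stop("bond order must be 0, 1, 2 or 3", call. = FALSE)
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key))
      stop("at most one bond per atom pair", call. = FALSE)
    if (!all(b$stereo %in% .bond_stereo_levels))
      stop("unknown bond stereo mark", call. = FALSE)
    if (any(b$order == 0L & b$stereo != "none"))
      stop("zero-order bonds cannot carry a wedge mark", call. = FALSE)
  }
  if (any(!is.na(m$atoms$hcount) & m$atoms$hcount < 0L))
    stop("hydrogen counts must be non-negative", call. = FALSE)
  invisible(m)
}

#' @export
print.zmol <- function(x, ...) {
  nz <- sum(x$bonds$order == 0L)
  cat(sprintf(
    "<molecule%s: %d atoms, %d bonds (%d zero-order)%s>\n",
    if (nzchar(x$title)) paste0(" '", x$title, "'") else "",
    nrow(x$atoms), nrow(x$bonds), nz,
    if (is_organometallic(x)) ", organometallic" else ""
  ))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param m a `zmol`.
#' @return integer atom count (heavy atoms; hydrogens are counts, not atoms).
#' @export
n_atoms <- function(m) nrow(m$atoms)

#' Does the molecule contain at least one zero-order bond?
#' @param m a `zmol`.
#' @return logical.
#' @export
has_zero_bond <- function(m) any(m$bonds$order == 0L)

# adjacency list: for each atom, integer matrix-free list of
# (neighbor, bond-row) pairs
.adjacency <- function(m) {
  n <- nrow(m$atoms)
  adj <- rep(list(integer()), n)
  brow <- rep(list(integer()), n)
  b <- m$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], b$a2[i])
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], b$a1[i])
    brow[[b$a1[i]]] <- c(brow[[b$a1[i]]], i)
    brow[[b$a2[i]]] <- c(brow[[b$a2[i]]], i)
  }
  list(nbr = adj, bond = brow)
}

# bond row index for an unordered atom pair, or NA
.bond_between <- function(m, i, j) {
  b <- m$bonds
  hit <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
  if (length(hit)) hit[1] else NA_integer_
}

# bond class used for matching and fingerprints: aromatic bonds form their
# own class, otherwise the numeric order (0,1,2,3)
.bond_class <- function(bonds) ifelse(bonds$aromatic, "a", as.character(bonds$order))

#' Permute the atom numbering of a molecule
#'
#' Renumbers atoms so that new atom `i` is old atom `perm[i]`; bonds are
#' rewritten accordingly. Used heavily in invariance tests.
#'
#' @param m a `zmol`.
#' @param perm a permutation of `seq_len(n_atoms(m))`.
#' @return the renumbered `zmol`.
#' @export
permute_atoms <- function(m, perm) {
  n <- nrow(m$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  atoms <- m$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- m$bonds
  bonds$a1 <- inv[bonds$a1]
  bonds$a2 <- inv[bonds$a2]
  molecule(atoms, bonds, title = m$title, properties = m$properties)
}
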