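# Implicit hydrogen rules. Hydrogens are stored as per-atom counts, never
# as graph vertices. Counts are computed by valence rules for C, N, P, O
# and S only; every other element must be annotated explicitly (metals in
# particular). Zero bonds contribute nothing to valence.

# charge-adjusted valence: N+/P+ gain a bond, O-/S- lose one, carbanions
# and carbocations both drop to three
.effective_valence <- function(element, charge, valences) {
  std <- valences[[element]]
  if (element == "C") std - abs(charge) else std + charge
}

#' Fill in implicit hydrogen counts
#'
#' For every C, N, P, O or S atom without an explicit hydrogen count, sets
#' the count to `max(0, effective_valence - bond_order_sum)`, where the
#' effective valence is the standard valence adjusted for formal charge and
#' the bond-order sum counts each incident bond at its stored order --
#' zero bonds contribute 0, aromatic-flagged bonds contribute their stored
#' order. Atoms of any other element get a count of 0 unless one was given
#' explicitly. Idempotent: a second application changes nothing. Over-valent
#' atoms get count 0 with a warning.
#'
#' @param m a `zmol`.
#' @return a `zmol` in which every atom has a concrete hydrogen count.
#' @examples
#' m <- add_implicit_hydrogens(molecule("C"))
#' m$atoms$hcount  # 4: methane
#' @export
add_implicit_hydrogens <- function(m) {
  validate_molecule(m)
  valences <- zob_option("valences")
  a <- m$atoms
  b <- m$bonds
  ordsum <- integer(nrow(a))
  if (nrow(b)) {
    s <- tapply(c(b$order, b$order), c(b$a1, b$a2), sum)
    ordsum[as.integer(names(s))] <- as.integer(s)
  }
  for (i in seq_len(nrow(a))) {
    if (!is.na(a$hcount[i])) next
    el <- a$element[i]
    if (el %in% names(valences)) {
      eff <- .effective_valence(el, a$charge[i], valences)
      h <- eff - ordsum[i]
      if (h < 0L) {
        warning(sprintf("atom %d (%s) is over-valent (bond-order sum %d > valence %d); hydrogen count set to 0",
                        i, el, ordsum[i], eff), call. = FALSE)
        h <- 0L
      }
      a$hcount[i] <- h
    } else {
      a$hcount[i] <- 0L
    }
  }
  m$atoms <- a
  m
}
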