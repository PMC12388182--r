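# Reference molecules built in code, shared across test files.

benzene_kekule <- function(shift = 0L) {
  # shift = 1L gives the other Kekule drawing (doubles on the other edges)
  orders <- if (shift == 0L) c(2L, 1L, 2L, 1L, 2L, 1L) else c(1L, 2L, 1L, 2L, 1L, 2L)
  molecule(rep("C", 6), Map(c, 1:6, c(2:6, 1), orders))
}

cyclohexane <- function() {
  molecule(rep("C", 6), Map(c, 1:6, c(2:6, 1), rep(1L, 6)))
}

pyrrole <- function() {
  # N1, alpha C2/C5, beta C3/C4
  molecule(c("N", "C", "C", "C", "C"),
           list(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1), c(4, 5, 2), c(5, 1, 1)))
}

pyridine_kekule <- function(shift = 0L) {
  orders <- if (shift == 0L) c(2L, 1L, 2L, 1L, 2L, 1L) else c(1L, 2L, 1L, 2L, 1L, 2L)
  molecule(c("N", rep("C", 5)), Map(c, 1:6, c(2:6, 1), orders))
}

toluene <- function() {
  molecule(rep("C", 7),
           list(c(1, 2, 2), c(2, 3, 1), c(3, 4, 2), c(4, 5, 1), c(5, 6, 2),
                c(6, 1, 1), c(1, 7, 1)))
}

cp_anion <- function() {
  # cyclopentadienyl anion: one anionic carbon, two double bonds
  m <- molecule(rep("C", 5),
                list(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1), c(4, 5, 2), c(5, 1, 1)))
  m$atoms$charge[1] <- -1L
  m
}

# a random molecule for property sweeps: organic, sometimes with a metal
# centre zero-bonded to a few atoms; uses the current RNG state
random_test_molecule <- function(p_metal = 0.3) {
  m <- random_organic(sample(3:8, 1))
  if (stats::runif(1) < p_metal) {
    mt <- sample(zob_option("metals"), 1)
    base <- n_atoms(m)
    m$atoms <- rbind(m$atoms,
                     data.frame(element = mt, charge = 0L, isotope = NA_integer_,
                                hcount = 0L, x = -1, y = -1, z = 0))
    targets <- sample(seq_len(base), min(base, sample(1:3, 1)))
    nb <- data.frame(a1 = targets, a2 = base + 1L, order = 0L,
                     aromatic = FALSE, stereo = "none")
    m <- molecule(m$atoms, rbind(m$bonds, nb), title = m$title)
  }
  m
}
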