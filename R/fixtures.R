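# Synthetic fixtures: metallocene families, one exemplar per coordination
# bond class (metallocene, 3-centre-2-electron, coordinate bridge, agostic,
# coordination complex, hapticity), random organic molecules, and a
# synthetic shift database built from coarse-environment class means plus
# Gaussian noise. Everything is deterministic under a seed.

.substituent_library <- list(
  methyl  = list(el = "C",                 bonds = list()),
  ethyl   = list(el = c("C", "C"),         bonds = list(c(1, 2, 1))),
  vinyl   = list(el = c("C", "C"),         bonds = list(c(1, 2, 2))),
  acetyl  = list(el = c("C", "O", "C"),    bonds = list(c(1, 2, 2), c(1, 3, 1))),
  hydroxy = list(el = "O",                 bonds = list()),
  amino   = list(el = "N",                 bonds = list()),
  chloro  = list(el = "Cl",                bonds = list()),
  silyl   = list(el = c("Si", "C", "C", "C"),
                 bonds = list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1)))
)

# append a substituent group, bonded (order 1) to atom `at`
.attach_group <- function(m, at, group) {
  g <- .substituent_library[[group]]
  if (is.null(g)) stop("unknown substituent group: ", group, call. = FALSE)
  base <- nrow(m$atoms)
  ng <- length(g$el)
  add <- data.frame(element = g$el, charge = 0L, isotope = NA_integer_,
                    hcount = ifelse(g$el %in% names(zob_option("valences")),
                                    NA_integer_, 0L),
                    x = m$atoms$x[at] + seq_len(ng), y = m$atoms$y[at] + 1, z = 0)
  atoms <- rbind(m$atoms, add)
  newbonds <- data.frame(a1 = at, a2 = base + 1L, order = 1L,
                         aromatic = FALSE, stereo = "none")
  for (b in g$bonds) {
    newbonds <- rbind(newbonds, data.frame(a1 = base + b[1], a2 = base + b[2],
                                           order = b[3], aromatic = FALSE,
                                           stereo = "none"))
  }
  molecule(atoms, rbind(m$bonds, newbonds), title = m$title,
           properties = m$properties)
}

#' Build a metallocene
#'
#' Two eta5 cyclopentadienyl rings sandwiching a metal atom, stored in the
#' sigma-plus-zero convention: each ring is a Kekule cyclopentadiene (two
#' double bonds) whose first carbon binds the metal with a single bond
#' while the other four use zero bonds. The metal carries an explicit
#' hydrogen count of 0. Ring atoms are 1--5 and 6--10; the metal is atom
#' 11. Substituents replace ring hydrogens.
#'
#' @param metal element symbol, must be in the configured metal list.
#' @param substituents named character vector mapping ring positions
#'   (1--10) to substituent group names (methyl, ethyl, vinyl, acetyl,
#'   hydroxy, amino, chloro, silyl); an unnamed vector is placed on
#'   successive ring-2 positions 6, 7, ...
#' @return a `zmol`.
#' @examples
#' fc <- make_metallocene("Fe")
#' is_organometallic(fc)
#' @export
make_metallocene <- function(metal = "Fe", substituents = NULL) {
  if (!metal %in% zob_option("metals"))
    stop("metal '", metal, "' is not in the configured metal list", call. = FALSE)
  theta <- 2 * pi * (0:4) / 5
  atoms <- data.frame(
    element = c(rep("C", 10), metal), charge = 0L, isotope = NA_integer_,
    hcount = c(rep(NA_integer_, 10), 0L),
    x = c(cos(theta), cos(theta), 0), y = c(sin(theta), sin(theta) + 3, 1.5), z = 0
  )
  ring <- function(off, mt) {
    rbind(
      data.frame(a1 = off + c(1, 2, 3, 4, 5), a2 = off + c(2, 3, 4, 5, 1),
                 order = c(1L, 2L, 1L, 2L, 1L), aromatic = FALSE, stereo = "none"),
      data.frame(a1 = off + 1L, a2 = mt, order = 1L, aromatic = FALSE, stereo = "none"),
      data.frame(a1 = off + c(2, 3, 4, 5), a2 = mt, order = 0L,
                 aromatic = FALSE, stereo = "none")
    )
  }
  title <- switch(metal, Fe = "ferrocene", Co = "cobaltocene",
                  Ni = "nickelocene", Os = "osmocene",
                  paste0(tolower(metal), "-metallocene"))
  m <- molecule(atoms, rbind(ring(0L, 11L), ring(5L, 11L)), title = title)
  if (!is.null(substituents)) {
    pos <- names(substituents)
    if (is.null(pos)) pos <- as.character(5L + seq_along(substituents))
    for (k in seq_along(substituents)) {
      at <- as.integer(pos[k])
      if (is.na(at) || at < 1L || at > 10L)
        stop("substituent position must be a ring atom 1-10", call. = FALSE)
      m <- .attach_group(m, at, substituents[[k]])
    }
  }
  m
}

# one exemplar per coordination-bond class ------------------------------

# 3-centre-2-electron bond: a methyl bridging two metal centres
.fix_three_center <- function(metal = "W") {
  molecule(
    data.frame(element = c(metal, metal, "C", "C", "C"), charge = 0L,
               isotope = NA_integer_, hcount = c(0L, 0L, 3L, NA, NA),
               x = c(0, 2, 1, -1, 3), y = c(0, 0, 1, 0, 0), z = 0),
    list(c(1, 2, 1), c(3, 1, 0), c(3, 2, 0), c(1, 4, 1), c(2, 5, 1)),
    title = "three-centre bridge (synthetic)"
  )
}

# coordinate bridge: halide sigma-bonded to one metal, zero-bonded to the other
.fix_bridge <- function(metal = "Rh") {
  molecule(
    data.frame(element = c(metal, metal, "Cl", "C", "C"), charge = 0L,
               isotope = NA_integer_, hcount = c(0L, 0L, 0L, NA, NA),
               x = c(0, 2, 1, -1, 3), y = c(0, 0, 1, 0, 0), z = 0),
    list(c(3, 1, 1), c(3, 2, 0), c(1, 4, 1), c(2, 5, 1)),
    title = "coordinate bridge (synthetic)"
  )
}

# agostic interaction: a gamma C-H contact drawn as metal-carbon zero bond
.fix_agostic <- function(metal = "Ti") {
  molecule(
    data.frame(element = c(metal, "C", "C", "C"), charge = 0L,
               isotope = NA_integer_, hcount = c(0L, NA, NA, NA),
               x = c(0, 1, 2, 1.5), y = c(0, 1, 0.5, -0.5), z = 0),
    list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 1, 0)),
    title = "agostic interaction (synthetic)"
  )
}

# coordination complex: square-planar metal with localized charges
.fix_complex <- function(metal = "Pt") {
  molecule(
    data.frame(element = c(metal, "Cl", "Cl", "Cl", "Cl"),
               charge = c(2L, -1L, -1L, -1L, -1L),
               isotope = NA_integer_, hcount = 0L,
               x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1), z = 0),
    list(c(1, 2, 0), c(1, 3, 0), c(1, 4, 0), c(1, 5, 0)),
    title = "coordination complex (synthetic)"
  )
}

# eta2 hapticity: an alkene side-on to a metal
.fix_hapticity <- function(metal = "Ni") {
  molecule(
    data.frame(element = c(metal, "C", "C", "C"), charge = 0L,
               isotope = NA_integer_, hcount = c(0L, NA, NA, NA),
               x = c(0, 1, 2, -1), y = c(0, 1, 1, 0), z = 0),
    list(c(2, 3, 2), c(1, 2, 0), c(1, 3, 0), c(1, 4, 1)),
    title = "eta2 alkene (synthetic)"
  )
}

#' Random organic molecule
#'
#' Valence-safe random generation: a random tree over C/N/O/S/P (plus
#' halogens as leaves), random bond orders within remaining valence,
#' occasional extra ring-closing bonds and occasional pendant benzene
#' rings. Uses the current RNG state; wrap in `set.seed()` for
#' reproducibility.
#'
#' @param n_heavy number of heavy atoms in the acyclic core (a pendant
#'   benzene adds 6 more).
#' @return a `zmol`.
#' @export
random_organic <- function(n_heavy = sample(3:9, 1)) {
  pool <- c("C", "N", "O", "S", "P", "Cl", "F")
  wts <- c(0.62, 0.12, 0.12, 0.05, 0.03, 0.03, 0.03)
  caps <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L, Cl = 1L, F = 1L)
  el <- sample(pool, n_heavy, replace = TRUE, prob = wts)
  el[1] <- "C"
  cap <- unname(caps[el])
  bonds <- list()
  for (i in seq_len(n_heavy)[-1]) {
    open <- which(cap[seq_len(i - 1L)] >= 1L)
    if (length(open) == 0L) next  # fully saturated so far: start a new fragment
    j <- if (length(open) == 1L) open else sample(open, 1)
    maxo <- min(cap[i], cap[j], 3L)
    order <- sample(seq_len(maxo), 1, prob = c(0.8, 0.17, 0.03)[seq_len(maxo)])
    bonds[[length(bonds) + 1L]] <- c(j, i, order)
    cap[i] <- cap[i] - order
    cap[j] <- cap[j] - order
  }
  # occasional ring closure between non-adjacent atoms with spare valence
  if (n_heavy >= 4L && stats::runif(1) < 0.35) {
    adjacent <- vapply(bonds, function(b) paste(sort(b[1:2]), collapse = "-"), character(1))
    open <- which(cap >= 1L)
    if (length(open) >= 2L) {
      pr <- sample(open, 2)
      if (!paste(sort(pr), collapse = "-") %in% adjacent) {
        bonds[[length(bonds) + 1L]] <- c(pr[1], pr[2], 1L)
        cap[pr] <- cap[pr] - 1L
      }
    }
  }
  m <- molecule(data.frame(element = el, x = seq_len(n_heavy), y = 0, z = 0), bonds)
  if (stats::runif(1) < 0.2) {
    att <- which(cap >= 1L)
    if (length(att)) m <- .attach_benzene(m, if (length(att) == 1L) att else sample(att, 1))
  }
  m
}

.attach_benzene <- function(m, at) {
  base <- nrow(m$atoms)
  atoms <- rbind(m$atoms,
                 data.frame(element = "C", charge = 0L, isotope = NA_integer_,
                            hcount = NA_integer_, x = base + 1:6, y = 2, z = 0))
  nb <- data.frame(a1 = base + c(1, 2, 3, 4, 5, 6, 0),
                   a2 = base + c(2, 3, 4, 5, 6, 1, 1),
                   order = c(2L, 1L, 2L, 1L, 2L, 1L, 1L),
                   aromatic = FALSE, stereo = "none")
  nb$a1[7] <- at
  molecule(atoms, rbind(m$bonds, nb), title = m$title, properties = m$properties)
}

#' Generate a mixed fixture corpus
#'
#' The first six molecules are one exemplar per coordination-bond class
#' (metallocene, 3-centre-2-electron bridge, coordinate bridge, agostic,
#' coordination complex, eta2 hapticity); the remainder mixes random
#' organic molecules with randomly substituted metallocenes. Byte-identical
#' output for identical `n` and `seed`.
#'
#' @param n corpus size (>= 1; at least 6 to cover every class).
#' @param seed integer random seed.
#' @return list of `zmol`, named m1..mn.
#' @export
make_fixture_corpus <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  exemplars <- list(
    make_metallocene(sample(c("Fe", "Co", "Ni", "Os"), 1)),
    .fix_three_center(), .fix_bridge(), .fix_agostic(),
    .fix_complex(), .fix_hapticity()
  )
  out <- exemplars[seq_len(min(n, 6L))]
  while (length(out) < n) {
    out[[length(out) + 1L]] <- if (stats::runif(1) < 0.25) {
      grp <- sample(names(.substituent_library), 1)
      pos <- sample(1:10, 1)
      make_metallocene("Fe", stats::setNames(grp, pos))
    } else {
      random_organic()
    }
  }
  names(out) <- paste0("m", seq_len(n))
  out
}

# coarse environment class of a carbon, from its first HOSE sphere
.shift_class <- function(sphere1, heavy_degree) {
  if (grepl("<", sphere1, fixed = TRUE) && grepl("*", sphere1, fixed = TRUE)) return("ring_metal")
  if (grepl("=O", sphere1, fixed = TRUE)) return("carbonyl")
  if (grepl("%", sphere1, fixed = TRUE)) return("alkyne")
  if (grepl("*", sphere1, fixed = TRUE)) return("aromatic")
  if (grepl("=", sphere1, fixed = TRUE)) return("alkene")
  if (grepl("<", sphere1, fixed = TRUE)) return("metal_sigma")
  if (heavy_degree <= 1L) return("methyl")
  "sp3"
}

#' Default coarse-class shift means (ppm)
#'
#' Chemically plausible anchors per coarse carbon environment: metal-ring
#' CH around 69 ppm, carbonyl around 200 ppm, methyl around 27 ppm, and so
#' on; proton means to match.
#'
#' @return list with numeric vectors `c13` and `h1`, named by class.
#' @export
default_shift_classes <- function() {
  list(
    c13 = c(ring_metal = 69.4, carbonyl = 200.0, alkyne = 75.0,
            aromatic = 128.5, alkene = 125.0, metal_sigma = 80.0,
            methyl = 27.3, sp3 = 35.0),
    h1 = c(ring_metal = 4.2, carbonyl = NA, alkyne = 2.0, aromatic = 7.3,
           alkene = 5.8, metal_sigma = 2.5, methyl = 0.9, sp3 = 1.4)
  )
}

#' Synthetic shift assignment table for a corpus
#'
#' Assigns every carbon a 13C shift equal to its coarse-environment class
#' mean plus Gaussian noise, and every proton-bearing carbon a matching 1H
#' shift. With `noise_sd = 0`, symmetry-equivalent atoms get identical
#' shifts. Reproducible under `seed`.
#'
#' @param corpus named list of `zmol`.
#' @param class_means list as returned by [default_shift_classes()].
#' @param noise_sd shift noise standard deviation in ppm (13C; 1H noise is
#'   scaled by 0.1).
#' @param seed integer random seed.
#' @return data frame with columns `mol_id`, `atom`, `nucleus`, `shift`,
#'   `class`.
#' @export
make_shift_db <- function(corpus, class_means = default_shift_classes(),
                          noise_sd = 0.3, seed = 1L) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  ids <- names(corpus)
  if (is.null(ids)) ids <- as.character(seq_along(corpus))
  rows <- list()
  for (i in seq_along(corpus)) {
    m <- add_implicit_hydrogens(corpus[[i]])
    mn <- normalize_for_hose(m)
    adj <- .adjacency(mn)
    for (at in which(mn$atoms$element == "C")) {
      sphere1 <- generate_hose(mn, at, 1L, normalize = FALSE)$spheres[1]
      cls <- .shift_class(sphere1, length(adj$nbr[[at]]))
      shift <- class_means$c13[[cls]] + stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        mol_id = ids[i], atom = at, nucleus = "13C", shift = shift, class = cls
      )
      hmean <- class_means$h1[[cls]]
      if (!is.na(hmean) && m$atoms$hcount[at] > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          mol_id = ids[i], atom = at, nucleus = "1H",
          shift = hmean + stats::rnorm(1, 0, noise_sd * 0.1), class = cls
        )
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(mol_id = character(), atom = integer(),
                      nucleus = character(), shift = numeric(),
                      class = character()))
  do.call(rbind, rows)
}
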