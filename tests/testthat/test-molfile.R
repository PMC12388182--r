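test_that("the metallocene fixture parses to the expected graph", {
  fc <- make_metallocene("Fe")
  txt <- write_molfile(fc)
  m <- parse_molfile(txt)
  expect_equal(n_atoms(m), 11L)
  expect_equal(nrow(m$bonds), 20L)
  expect_equal(sum(m$bonds$order == 0L), 8L)
  expect_equal(sum(m$bonds$order == 2L), 4L)
  fe <- which(m$atoms$element == "Fe")
  sigma <- m$bonds$order == 1L & (m$bonds$a1 == fe | m$bonds$a2 == fe)
  expect_equal(sum(sigma), 2L)
  expect_equal(m$atoms$hcount[fe], 0L)  # explicit count written as property line
  expect_match(txt, "M  ZHC  1  11   0", fixed = TRUE)
})

test_that("zero bonds survive write/parse and output is deterministic", {
  m <- molecule(c("C", "Fe"), list(c(1, 2, 0)))
  txt <- write_molfile(m)
  expect_match(txt, "  1  2  0  0", fixed = TRUE)
  expect_identical(txt, write_molfile(m))
  expect_equal(parse_molfile(txt)$bonds$order, 0L)
})

test_that("bond type 4 reads as aromatic and type 8 as zero bond with a notice", {
  m <- molecule(c("C", "C"), list(c(1, 2, 1)))
  m$bonds$aromatic <- TRUE
  back <- parse_molfile(write_molfile(m))
  expect_true(back$bonds$aromatic)
  expect_equal(back$bonds$order, 1L)

  m8 <- molecule(c("C", "Fe"), list(c(1, 2, 1)))
  txt <- sub("  1  2  1  0", "  1  2  8  0", write_molfile(m8), fixed = TRUE)
  expect_message(parsed <- parse_molfile(txt), "any bond")
  expect_equal(parsed$bonds$order, 0L)
})

test_that("parse errors name the offending line", {
  good <- write_molfile(molecule(c("C", "O"), list(c(1, 2, 1))))
  expect_error(parse_molfile(sub("  2  1  0", "  x  1  0", good, fixed = TRUE)),
               "line 4.*counts")
  expect_error(parse_molfile(sub("  1  2  1", "  1  3  1", good, fixed = TRUE)),
               "line 7.*nonexistent")
  withhc <- write_molfile(molecule(data.frame(element = "C", hcount = 2L)))
  expect_error(parse_molfile(sub("M  ZHC  1   1   2", "M  ZHC  1   1  -2",
                                 withhc, fixed = TRUE)),
               "negative hydrogen count")
})

test_that("charges and isotopes round-trip through property lines", {
  m <- molecule(data.frame(element = c("N", "O"), charge = c(1L, -1L),
                           isotope = c(15L, NA)),
                list(c(1, 2, 1)))
  back <- parse_molfile(write_molfile(m))
  expect_equal(back$atoms$charge, c(1L, -1L))
  expect_equal(back$atoms$isotope, c(15L, NA))
})

test_that("a wedge mark on a zero bond is dropped with a warning", {
  txt <- paste(
    "", "  zobmol  2D", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 Fe  0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  0  1", "M  END", sep = "\n")
  expect_warning(m <- parse_molfile(txt), "wedge")
  expect_equal(m$bonds$stereo, "none")
  # wedges stay on covalent bonds
  m2 <- molecule(c("C", "C"), list(c(1, 2, 1)))
  m2$bonds$stereo <- "wedge_up"
  expect_equal(parse_molfile(write_molfile(m2))$bonds$stereo, "wedge_up")
})

test_that("random molecules round-trip with identical attributes", {
  set.seed(101)
  for (rep in 1:60) {
    m <- random_test_molecule()
    back <- parse_molfile(write_molfile(m))
    expect_identical(back$atoms$element, m$atoms$element)
    expect_identical(back$atoms$charge, m$atoms$charge)
    expect_identical(back$atoms$hcount, m$atoms$hcount)
    expect_identical(back$bonds[c("a1", "a2", "order", "aromatic", "stereo")],
                     m$bonds[c("a1", "a2", "order", "aromatic", "stereo")])
    expect_equal(back$atoms$x, m$atoms$x, tolerance = 1e-4)
  }
})

test_that("SDF records keep their data items and split correctly", {
  m1 <- make_metallocene("Fe")
  m1$properties <- list(Assignments = "1\t13C\t69.58", Source = "synthetic")
  m2 <- benzene_kekule()
  txt <- write_sdf(list(m1, m2))
  mols <- read_sdf(text = txt)
  expect_length(mols, 2L)
  expect_equal(mols[[1]]$properties$Assignments, "1\t13C\t69.58")
  expect_equal(mols[[1]]$properties$Source, "synthetic")
  expect_equal(n_atoms(mols[[2]]), 6L)
})

test_that("the disconnected-graph and duplicate-bond invariants are enforced", {
  # salts may be disconnected
  salt <- molecule(data.frame(element = c("N", "Cl"), charge = c(1L, -1L)))
  expect_equal(nrow(salt$bonds), 0L)
  expect_error(molecule(c("C", "C"), list(c(1, 2, 1), c(2, 1, 2))), "one bond")
  expect_error(molecule(c("C", "C"), list(c(1, 1, 1))), "distinct")
  expect_error(molecule(c("C", "C"), list(c(1, 3, 1))), "nonexistent")
})
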