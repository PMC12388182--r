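test_that("metallocene construction follows the sigma-plus-zero convention", {
  fc <- make_metallocene("Fe")
  expect_equal(n_atoms(fc), 11L)
  expect_true(is_organometallic(fc))
  expect_equal(sum(fc$bonds$order == 0L), 8L)
  expect_identical(identity_key(make_metallocene("Fe")), identity_key(fc))
  expect_error(make_metallocene("Na"), "metal list")
  sub <- make_metallocene("Fe", c(`6` = "acetyl"))
  expect_equal(n_atoms(sub), 14L)
  # the unsubstituted ring stays fully equivalent
  codes <- vapply(1:5, function(a) generate_hose(sub, a, 4)$text, character(1))
  expect_equal(length(unique(codes)), 1L)
})

test_that("the corpus is reproducible, mixed, and covers every bond family", {
  c1 <- make_fixture_corpus(20, seed = 7)
  c2 <- make_fixture_corpus(20, seed = 7)
  expect_identical(write_sdf(c1), write_sdf(c2))
  c3 <- make_fixture_corpus(20, seed = 8)
  expect_false(identical(write_sdf(c1), write_sdf(c3)))
  expect_length(c1, 20L)
  expect_gte(sum(vapply(c1, is_organometallic, logical(1))), 6L)
  titles <- vapply(c1[1:6], function(m) m$title, character(1))
  expect_true(any(grepl("ocene", titles)))
  expect_true(any(grepl("three-centre", titles)))
  expect_true(any(grepl("coordinate bridge", titles)))
  expect_true(any(grepl("agostic", titles)))
  expect_true(any(grepl("coordination complex", titles)))
  expect_true(any(grepl("eta2", titles)))
})

test_that("every generated organometallic is valence-clean and round-trips", {
  corpus <- make_fixture_corpus(20, seed = 7)
  for (m in corpus) {
    if (is_organometallic(m)) expect_gte(sum(m$bonds$order == 0L), 1L)
    expect_warning(add_implicit_hydrogens(m), NA)
    back <- parse_molfile(write_molfile(m))
    expect_identical(identity_key(back), identity_key(m))
  }
})

test_that("shift tables follow class means and the seed", {
  fam <- list(a = make_metallocene("Fe"), b = make_metallocene("Fe", c(`6` = "methyl")))
  db0 <- make_shift_db(fam, noise_sd = 0, seed = 1)
  # without noise, equivalent atoms (same class) get identical shifts
  ring <- db0[db0$mol_id == "a" & db0$nucleus == "13C", ]
  expect_equal(length(unique(ring$shift)), 1L)
  expect_equal(unique(ring$shift), 69.4)
  expect_equal(unique(ring$class), "ring_metal")
  # methyl carbon classified and anchored near methyl range
  met <- db0[db0$mol_id == "b" & db0$nucleus == "13C" & db0$class == "methyl", ]
  expect_equal(nrow(met), 1L)
  expect_equal(met$shift, 27.3)

  dbA <- make_shift_db(fam, noise_sd = 0.3, seed = 5)
  dbB <- make_shift_db(fam, noise_sd = 0.3, seed = 6)
  expect_identical(make_shift_db(fam, noise_sd = 0.3, seed = 5), dbA)
  expect_false(identical(dbA$shift, dbB$shift))
  expect_identical(dbA$class, dbB$class)  # same class structure, new noise
})

test_that("carbonyl and aromatic environments land on their anchors", {
  ac <- make_metallocene("Fe", c(`6` = "acetyl"))
  db <- make_shift_db(list(ac = ac), noise_sd = 0, seed = 1)
  expect_true(200 %in% db$shift[db$class == "carbonyl"])
  bz <- benzene_kekule()
  dbz <- make_shift_db(list(bz = bz), noise_sd = 0, seed = 1)
  expect_true(all(dbz$shift[dbz$nucleus == "13C"] == 128.5))
})

test_that("configuration can be redirected and restored", {
  old <- zob_options(metals = c("Fe"))
  expect_false(is_organometallic(molecule(c("C", "Ti"), list(c(1, 2, 0)))))
  do.call(zob_options, old)
  expect_true(is_organometallic(molecule(c("C", "Ti"), list(c(1, 2, 0)))))

  cfg <- tempfile(fileext = ".conf")
  writeLines(c("# test config", "metals: Fe, Ru", "warn_spheres: 2",
               "valences: C=4, N=3, P=3, O=2, S=2"), cfg)
  old <- load_config(cfg)
  expect_setequal(zob_option("metals"), c("Fe", "Ru"))
  expect_equal(zob_option("warn_spheres"), 2L)
  do.call(zob_options, old)
  expect_equal(zob_option("warn_spheres"), 3L)
})

test_that("the shipped example files load and match their generators", {
  mol <- parse_molfile(readLines(system.file("extdata", "ferrocene.mol",
                                             package = "zobmol")))
  expect_identical(identity_key(mol), identity_key(make_metallocene("Fe")))
  sdf <- read_sdf(system.file("extdata", "metallocenes.sdf", package = "zobmol"))
  expect_length(sdf, 3L)
  shifts <- read_assignments(system.file("extdata", "metallocene_shifts.tsv",
                                         package = "zobmol"))
  idx <- build_shift_index(stats::setNames(sdf, unique(shifts$mol_id)),
                           shifts[shifts$nucleus == "13C", ])
  expect_gt(idx$n_records, 0L)
  old <- load_config(system.file("extdata", "example.conf", package = "zobmol"))
  do.call(zob_options, old)
})
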