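test_that("index construction stores every record at every depth", {
  empty <- build_shift_index(list(), data.frame(mol_id = character(),
                                                atom = integer(),
                                                nucleus = character(),
                                                shift = numeric()))
  expect_equal(empty$n_records, 0L)
  expect_equal(length(ls(empty$map)), 0L)

  fc <- make_metallocene("Fe")
  one <- build_shift_index(list(fc = fc),
                           data.frame(mol_id = "fc", atom = 1L,
                                      nucleus = "13C", shift = 69.58))
  # one distinct key per depth: the five ring atoms share the code anyway
  expect_equal(length(ls(one$map)), 4L)

  dup <- build_shift_index(list(fc = fc),
                           data.frame(mol_id = "fc", atom = c(1L, 1L),
                                      nucleus = "13C", shift = c(69.58, 69.58)))
  expect_equal(length(ls(dup$map)), 4L)  # same keys
  slot <- get(ls(dup$map)[1], envir = dup$map)
  expect_length(slot$shifts, 2L)         # doubled lists
})

test_that("bad assignments fail with the record named", {
  fc <- make_metallocene("Fe")
  expect_error(build_shift_index(list(fc = fc),
                                 data.frame(mol_id = "fc", atom = 99L,
                                            nucleus = "13C", shift = 1)),
               "record 1.*nonexistent atom 99")
  expect_error(build_shift_index(list(fc = fc),
                                 data.frame(mol_id = "nope", atom = 1L,
                                            nucleus = "13C", shift = 1)),
               "unknown molecule")
  expect_error(build_shift_index(list(fc = fc),
                                 data.frame(mol_id = "fc", atom = 1L,
                                            nucleus = "13C", shift = NaN)),
               "finite")
})

test_that("an exact match returns the stored shift at full depth", {
  fc <- make_metallocene("Fe")
  idx <- build_shift_index(list(ref = fc),
                           data.frame(mol_id = "ref", atom = 1L,
                                      nucleus = "13C", shift = 69.58))
  p <- predict_shift(idx, make_metallocene("Fe"), 3, "13C")
  expect_equal(p$value, 69.58)
  expect_equal(p$spheres_used, 4L)
  expect_equal(p$n_examples, 1L)
  expect_true(p$warning)  # a single example is thin evidence
  expect_error(predict_shift(idx, fc, 1, "19F"), "not indexed")
})

test_that("aggregation is the mean (or median on request) of matched shifts", {
  fc <- make_metallocene("Fe")
  idx <- build_shift_index(list(a = fc, b = fc),
                           data.frame(mol_id = c("a", "b"), atom = 1L,
                                      nucleus = "13C", shift = c(10, 20)))
  p <- predict_shift(idx, fc, 2, "13C")
  expect_equal(p$value, 15)
  expect_equal(p$n_examples, 2L)
  expect_false(p$warning)
  old <- zob_options(aggregate = "median")
  on.exit(do.call(zob_options, old))
  idx3 <- build_shift_index(list(a = fc, b = fc, c = fc),
                            data.frame(mol_id = c("a", "b", "c"), atom = 1L,
                                       nucleus = "13C", shift = c(10, 20, 90)))
  expect_equal(predict_shift(idx3, fc, 2, "13C")$value, 20)
})

test_that("prediction matches a linear-scan oracle on a synthetic index", {
  set.seed(701)
  fam <- list(a = make_metallocene("Fe", c(`6` = "methyl")),
              b = make_metallocene("Fe", c(`7` = "acetyl")),
              c = make_metallocene("Fe", c(`6` = "chloro")))
  db <- make_shift_db(fam, noise_sd = 0.5, seed = 11)
  db13 <- db[db$nucleus == "13C", ]
  idx <- build_shift_index(fam, db13)
  query <- make_metallocene("Fe")
  for (atom in c(1L, 5L, 8L)) {
    p <- predict_shift(idx, query, atom, "13C")
    # oracle: deepest depth at which any record's code equals the query's
    qcode <- generate_hose(query, atom, 4)
    ref_codes <- lapply(seq_len(nrow(db13)), function(r)
      generate_hose(fam[[db13$mol_id[r]]], db13$atom[r], 4))
    found <- FALSE
    for (s in 4:1) {
      qt <- hose_truncate(qcode, s)$text
      hit <- vapply(ref_codes, function(cd) hose_truncate(cd, s)$text == qt,
                    logical(1))
      if (any(hit)) {
        expect_equal(p$spheres_used, s)
        expect_equal(p$value, mean(db13$shift[hit]))
        expect_equal(p$n_examples, sum(hit))
        found <- TRUE
        break
      }
    }
    expect_true(found)
  }
})

test_that("sphere fallback never gets shallower when the index grows", {
  fam <- list(a = make_metallocene("Fe", c(`6` = "methyl")))
  db_a <- data.frame(mol_id = "a", atom = 1L, nucleus = "13C", shift = 69)
  small <- build_shift_index(fam, db_a)
  fam2 <- c(fam, list(b = make_metallocene("Fe")))
  big <- build_shift_index(fam2, rbind(db_a, data.frame(mol_id = "b", atom = 1L,
                                                        nucleus = "13C", shift = 70)))
  q <- make_metallocene("Fe")
  for (atom in 1:5) {
    expect_gte(predict_shift(big, q, atom, "13C")$spheres_used,
               predict_shift(small, q, atom, "13C")$spheres_used)
  }
})

test_that("self-exclusion removes the query compound's own records", {
  fc <- make_metallocene("Fe")
  idx <- build_shift_index(list(self = fc, other = make_metallocene("Fe", c(`6` = "methyl"))),
                           data.frame(mol_id = c("self", "other"), atom = 1L,
                                      nucleus = "13C", shift = c(69.58, 70.50)))
  with_self <- predict_shift(idx, fc, 1, "13C")
  expect_equal(with_self$spheres_used, 4L)
  expect_equal(with_self$value, 69.58)
  leave_out <- predict_shift(idx, fc, 1, "13C", exclude = "self")
  expect_lt(leave_out$spheres_used, 4L)
  expect_equal(leave_out$value, 70.50)
})

test_that("no match anywhere yields a warned no-prediction", {
  fc <- make_metallocene("Fe")
  idx <- build_shift_index(list(bz = benzene_kekule()),
                           data.frame(mol_id = "bz", atom = 1L,
                                      nucleus = "13C", shift = 128.5))
  p <- predict_shift(idx, fc, 11, "13C")  # the metal atom matches nothing
  expect_true(is.na(p$value))
  expect_equal(p$spheres_used, 0L)
  expect_true(p$warning)
})

test_that("equivalent atoms are grouped into one report row with the printed error", {
  ref <- make_metallocene("Fe", c(`6` = "acetyl"))
  idx <- build_shift_index(list(ref = ref),
                           data.frame(mol_id = "ref", atom = 1L,
                                      nucleus = "13C", shift = 69.36))
  q <- make_metallocene("Fe", c(`6` = "acetyl"))
  obs <- data.frame(atom = 1:5, nucleus = "13C", shift = 69.58)
  rep <- predict_molecule(idx, q, nuclei = "13C", observed = obs)
  row <- rep[rep$atom_group == "1, 2, 3, 4, 5", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$predicted, 69.36)
  expect_equal(row$observed, 69.58)
  expect_equal(row$error, 0.22)
  expect_equal(row$spheres, 4L)
})

test_that("protons are predicted through their carbon's environment", {
  fam <- list(a = make_metallocene("Fe", c(`6` = "methyl")),
              b = make_metallocene("Fe", c(`7` = "ethyl")))
  db <- make_shift_db(fam, noise_sd = 0, seed = 2)
  idx <- build_shift_index(fam, db)
  rep <- predict_molecule(idx, make_metallocene("Fe"), nuclei = c("13C", "1H"))
  expect_setequal(unique(rep$nucleus), c("13C", "1H"))
  h <- rep[rep$nucleus == "1H", ]
  expect_equal(h$predicted, 4.2, tolerance = 1e-6)
})

test_that("an empty index reports no-prediction rows with warnings", {
  empty <- build_shift_index(list())
  rep <- predict_molecule(empty, benzene_kekule(), nuclei = "13C")
  expect_gt(nrow(rep), 0L)
  expect_true(all(is.na(rep$predicted)))
  expect_true(all(rep$warning))
})

test_that("error arithmetic rounds half away from zero at two decimals", {
  expect_equal(shift_error(69.58, 69.36), 0.22)
  expect_equal(shift_error(0.125, 0), 0.13)
  expect_equal(shift_error(2.39, 2.33), 0.06)
  expect_equal(shift_error(69.36, 69.58), 0.22)  # symmetric
})

test_that("equivalent atoms receive identical predictions", {
  fam <- list(a = make_metallocene("Fe", c(`6` = "methyl")))
  db <- make_shift_db(fam, noise_sd = 0.3, seed = 5)
  idx <- build_shift_index(fam, db[db$nucleus == "13C", ])
  q <- make_metallocene("Fe")
  vals <- vapply(1:10, function(a) predict_shift(idx, q, a, "13C")$value, numeric(1))
  expect_equal(length(unique(vals)), 1L)
})
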