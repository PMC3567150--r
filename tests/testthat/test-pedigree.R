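test_that("pedigree validation catches structural errors", {
  expect_s3_class(
    as_pedigree(data.frame(id = c("a", "b", "c"), sire = NA, dam = NA)),
    "grey_pedigree"
  )
  expect_error(
    as_pedigree(data.frame(id = "X", sire = "X", dam = "")),
    class = "greyherit_error_cycle"
  )
  expect_error(
    as_pedigree(data.frame(id = c("a", "a"), sire = NA, dam = NA)),
    class = "greyherit_error_duplicate"
  )
  # two-animal parentage cycle
  expect_error(
    as_pedigree(data.frame(id = c("a", "b"), sire = c("b", "a"),
                           dam = c(NA, NA))),
    class = "greyherit_error_cycle"
  )
  # undefined parent: added as founder by default, error on request
  expect_warning(
    ped <- as_pedigree(data.frame(id = "k", sire = "s9", dam = ""))
  )
  expect_equal(nrow(ped), 2)
  expect_error(
    as_pedigree(data.frame(id = "k", sire = "s9", dam = ""),
                undefined_parents = "error"),
    class = "greyherit_error_undefined_parent"
  )
  # "0" and "" both mean unknown
  ped <- as_pedigree(data.frame(id = c("a", "b"), sire = c("0", ""),
                                dam = c("", "0")))
  expect_true(all(is.na(ped$sire)) && all(is.na(ped$dam)))
})

test_that("topological order puts parents before offspring", {
  ped <- random_toy_pedigree(300, seed = 21)
  # shuffle and re-validate
  shuffled <- ped[withr::with_seed(1, sample(nrow(ped))), ]
  ped2 <- as_pedigree(shuffled, quiet = TRUE)
  idx <- seq_len(nrow(ped2))
  si <- match(ped2$sire, ped2$id)
  di <- match(ped2$dam, ped2$id)
  expect_true(all(si[!is.na(si)] < idx[!is.na(si)]))
  expect_true(all(di[!is.na(di)] < idx[!is.na(di)]))
})

test_that("classical relationship values are reproduced", {
  ped <- as_pedigree(data.frame(
    id = c("s", "d", "x", "y", "z"),
    sire = c(NA, NA, "s", "s", "x"),
    dam = c(NA, NA, "d", "d", "y")
  ))
  A <- relationship_matrix(ped)
  expect_equal(A["s", "x"], 0.5)   # parent-offspring
  expect_equal(A["x", "y"], 0.5)   # full sibs
  f <- inbreeding(ped)
  expect_equal(f$f[match("z", f$id)], 0.25)  # full-sib mating offspring
  expect_equal(f$f[f$id %in% c("s", "d")], c(0, 0))
})

test_that("founders give identity A and identity A-inverse", {
  ped <- as_pedigree(data.frame(id = letters[1:6], sire = NA, dam = NA))
  expect_equal(unname(relationship_matrix(ped)), diag(6))
  expect_equal(unname(as.matrix(relationship_inverse(ped))), diag(6))
})

test_that("diag(A) = 1 + F: tabular and L-row trace methods agree", {
  ped <- random_toy_pedigree(500, seed = 77)
  A <- relationship_matrix(ped)
  f <- inbreeding(ped)
  expect_lt(max(abs(diag(A) - 1 - f$f)), 1e-12)
  expect_true(any(f$f > 0))  # the pedigree actually contains inbreeding
})

test_that("A is PSD and Henderson's A-inverse inverts it", {
  ped <- random_toy_pedigree(200, seed = 5)
  A <- relationship_matrix(ped)
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  Ai <- as.matrix(relationship_inverse(ped))
  expect_lt(max(abs(A %*% Ai - diag(nrow(A)))), 1e-8)
})

test_that("trio A-inverse matches the textbook closed form", {
  ped <- as_pedigree(data.frame(id = c("s", "d", "x"),
                                sire = c(NA, NA, "s"),
                                dam = c(NA, NA, "d")))
  Ai <- as.matrix(relationship_inverse(ped))
  expected <- matrix(c(1.5, 0.5, -1,
                       0.5, 1.5, -1,
                       -1, -1, 2), 3, 3,
                     dimnames = list(c("s", "d", "x"), c("s", "d", "x")))
  expect_equal(Ai, expected)
})

test_that("an unrelated founder leaves existing A entries unchanged", {
  ped <- random_toy_pedigree(60, seed = 3)
  A1 <- relationship_matrix(ped)
  ped2 <- as_pedigree(dplyr::bind_rows(
    tibble::as_tibble(ped),
    data.frame(id = "new_founder", sire = NA_character_,
               dam = NA_character_)), quiet = TRUE)
  A2 <- relationship_matrix(ped2)
  expect_equal(A2[rownames(A1), colnames(A1)], A1)
  expect_equal(unname(A2["new_founder", rownames(A1)]),
               rep(0, nrow(A1)))
})

test_that("pedigree CSV round-trips through the documented dialect", {
  ped <- random_toy_pedigree(40, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, path)
  ped2 <- read_pedigree(path)
  expect_equal(ped2$id, ped$id)
  expect_equal(ped2$sire, ped$sire)
  expect_equal(ped2$dam, ped$dam)
})
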