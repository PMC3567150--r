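trio_ped <- function() {
  as_pedigree(data.frame(id = c("s", "d", "x"),
                         sire = c(NA, NA, "s"), dam = c(NA, NA, "d")))
}

test_that("colour-based deduction rules work on trios", {
  ped <- trio_ped()
  # grey sire with a coloured foal is heterozygous
  g <- deduce_genotypes(ped, colour = data.frame(
    id = c("s", "d", "x"), colour = c("grey", "grey", "coloured")
  ))
  expect_equal(g$stx17[g$id == "s"], "Gg")
  expect_equal(g$stx17[g$id == "d"], "Gg")
  expect_equal(g$stx17[g$id == "x"], "gg")
  expect_true(all(g$stx17_source == "deduced"))
  # grey foal with one coloured parent is heterozygous
  g <- deduce_genotypes(ped, colour = data.frame(
    id = c("s", "d", "x"), colour = c("coloured", "grey", "grey")
  ))
  expect_equal(g$stx17[g$id == "x"], "Gg")
  expect_true(is.na(g$stx17[g$id == "d"]))  # could be GG or Gg
})

test_that("an isolated grey animal stays unknown", {
  ped <- as_pedigree(data.frame(id = "solo", sire = NA, dam = NA))
  g <- deduce_genotypes(ped, colour = data.frame(id = "solo",
                                                 colour = "grey"))
  expect_true(is.na(g$stx17))
  expect_equal(g$stx17_source, "unknown")
})

test_that("deduction is idempotent and never overwrites measurements", {
  ped <- trio_ped()
  colour <- data.frame(id = c("s", "d", "x"),
                       colour = c("grey", "grey", "coloured"))
  measured <- data.frame(id = "d", stx17 = "Gg", asip = "Aa")
  g1 <- deduce_genotypes(ped, colour = colour, measured = measured)
  expect_equal(g1$stx17_source[g1$id == "d"], "measured")
  expect_equal(g1$asip_source[g1$id == "d"], "measured")
  # feed the full deduced output back in as measurements: fixed point
  g2 <- deduce_genotypes(ped, colour = colour,
                         measured = g1[!is.na(g1$stx17), ])
  expect_equal(g2$stx17, g1$stx17)
  expect_equal(g2$asip, g1$asip)
})

test_that("Mendelian conflicts raise and name the trio", {
  ped <- trio_ped()
  expect_error(
    deduce_genotypes(
      ped,
      colour = data.frame(id = c("s", "d", "x"),
                          colour = c("grey", "grey", "coloured")),
      measured = data.frame(id = "s", stx17 = "GG", asip = NA)
    ),
    regexp = "child x",
    class = "greyherit_error_mendelian"
  )
  # colour contradicting a measured genotype
  expect_error(
    deduce_genotypes(
      ped,
      colour = data.frame(id = "x", colour = "coloured"),
      measured = data.frame(id = "x", stx17 = "GG", asip = NA)
    ),
    class = "greyherit_error_mendelian"
  )
  # measured parent-child impossibility at ASIP
  expect_error(
    deduce_genotypes(
      ped,
      measured = data.frame(id = c("s", "d", "x"),
                            stx17 = NA, asip = c("AA", "AA", "aa"))
    ),
    class = "greyherit_error_mendelian"
  )
})

test_that("deduction matches the exhaustive-enumeration oracle on toys", {
  n_checked <- 0
  for (seed in 1:120) {
    n <- withr::with_seed(seed, sample(4:8, 1))
    ped <- random_toy_pedigree(n, seed = seed * 13)
    truth <- drop_genotypes(ped, p_g = 0.6, p_a = 0.5, seed = seed)
    # reveal a random subset of measured genotypes + full colour
    reveal <- withr::with_seed(seed + 999,
                               runif(nrow(ped)) < 0.4)
    measured <- truth$genotypes[reveal, c("id", "stx17", "asip")]
    g <- deduce_genotypes(ped, colour = truth$colour, measured = measured)

    known_stx <- stats::setNames(
      match(measured$stx17, c("GG", "Gg", "gg")), measured$id)
    grey <- stats::setNames(truth$colour$colour == "grey",
                            truth$colour$id)
    oracle_stx <- enumerate_deduction(ped, known = known_stx, grey = grey)
    got <- match(g$stx17, c("GG", "Gg", "gg"))
    expect_equal(got, unname(oracle_stx[g$id]),
                 info = paste("STX17 seed", seed))

    known_asp <- stats::setNames(
      match(measured$asip, c("AA", "Aa", "aa")), measured$id)
    oracle_asp <- enumerate_deduction(ped, known = known_asp)
    got_a <- match(g$asip, c("AA", "Aa", "aa"))
    expect_equal(got_a, unname(oracle_asp[g$id]),
                 info = paste("ASIP seed", seed))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 120)
})

test_that("allele frequencies are computed by counting", {
  gt <- tibble::tibble(
    id = paste0("a", 1:5),
    stx17 = c("GG", "GG", "GG", "Gg", "Gg"),
    asip = c("AA", "Aa", "aa", NA, NA),
    stx17_source = "measured", asip_source = "measured"
  )
  expect_equal(allele_frequencies(gt, "stx17")$p, 0.8)
  af <- allele_frequencies(gt, "asip")
  expect_equal(af$p, 0.5)
  expect_equal(af$n_counted, 3L)
  expect_error(
    allele_frequencies(gt[4:5, ], "asip"),
    class = "greyherit_error_empty"
  )
  # subset restriction
  expect_equal(
    allele_frequencies(gt, "stx17", subset = c("a4", "a5"))$p, 0.5
  )
})

test_that("counted frequency matches the simulated truth within 3 SE", {
  ped <- as_pedigree(data.frame(id = paste0("f", 1:1000),
                                sire = NA, dam = NA))
  gd <- drop_genotypes(ped, p_g = 0.87, p_a = 0.52, seed = 31)
  p_hat <- allele_frequencies(gd$genotypes, "stx17")$p
  se <- sqrt(0.87 * 0.13 / 2000)
  expect_lt(abs(p_hat - 0.87), 3 * se)
})
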