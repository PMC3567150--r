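test_that("MME likelihood equals the dense REML criterion on tiny data", {
  for (seed in 1:3) {
    td <- tiny_dataset(seed, n_animals = 8, with_loci = (seed == 2))
    for (comp in list(c(0.2, 0.3, 0.4), c(1, 0.01, 0.5))) {
      ll_mme <- reml_loglik(td$design, td$study$pedigree,
                            g0 = comp[1], p0 = comp[2], v_e = comp[3])
      ll_dense <- dense_reml_loglik(td$design, td$study$pedigree,
                                    g0 = comp[1], p0 = comp[2],
                                    v_e = comp[3])
      expect_equal(ll_mme, ll_dense, tolerance = 1e-8)
    }
    # without the permanent-environment term
    ll_mme <- reml_loglik(td$design, td$study$pedigree, g0 = 0.3,
                          v_e = 0.5)
    ll_dense <- dense_reml_loglik(td$design, td$study$pedigree, g0 = 0.3,
                                  v_e = 0.5)
    expect_equal(ll_mme, ll_dense, tolerance = 1e-8)
  }
})

test_that("bivariate MME likelihood equals the dense criterion", {
  cfgs <- default_trait_configs()[c("melanoma", "vitiligo")]
  des <- study_design(n_founders = 4, n_generations = 2,
                      n_per_generation = 5, n_measured = 7,
                      mean_records = 2, years = 2000:2001, n_studs = 2)
  st <- simulate_study(cfgs, des, seed = 11, r_poly = 0.5)
  designs <- lapply(c("melanoma", "vitiligo"), function(tr) {
    build_design(st$phenotypes, st$pedigree, trait = tr)
  })
  g0 <- matrix(c(0.3, 0.1, 0.1, 0.25), 2)
  p0 <- matrix(c(0.2, -0.05, -0.05, 0.15), 2)
  ve <- c(0.4, 0.3)
  expect_equal(
    reml_loglik(designs, st$pedigree, g0, p0, ve),
    dense_reml_loglik(designs, st$pedigree, g0, p0, ve),
    tolerance = 1e-8
  )
})

test_that("a no-polygenic-signal dataset is estimated at the boundary", {
  # pedigreed population whose true polygenic variance is zero: the
  # additive variance is identified against the permanent-environment
  # variance by the lack of covariance among relatives
  cfg <- trait_config("null", v_poly = 0, v_pe = 0.3, v_e = 0.4,
                      v_class = 0)
  des <- study_design(n_founders = 40, n_generations = 3,
                      n_per_generation = 150, n_measured = 250,
                      mean_records = 3)
  ped <- simulate_pedigree(des, seed = 5)
  gd <- drop_genotypes(ped, p_g = 1, p_a = 0.5, seed = 6)
  u <- simulate_breeding_values(ped, g0 = 0, seed = 7, traits = "null")
  ph <- simulate_phenotypes(ped, gd$genotypes, u, cfg, des, seed = 8)
  fit <- fit_animal_model(ph, ped, traits = "null", age = FALSE)
  comp <- fit$components
  v_poly_hat <- comp$estimate[comp$component == "v_poly"]
  v_poly_se <- comp$se[comp$component == "v_poly"]
  expect_lt(v_poly_hat, 2 * v_poly_se + 0.02)
})

test_that("record order does not affect the estimates", {
  td <- tiny_dataset(9, n_animals = 10)
  st <- td$study
  fit1 <- fit_animal_model(st$phenotypes, st$pedigree, traits = "melanoma",
                           class_terms = "stud")
  perm <- withr::with_seed(2, sample(nrow(st$phenotypes)))
  fit2 <- fit_animal_model(st$phenotypes[perm, ], st$pedigree,
                           traits = "melanoma", class_terms = "stud")
  expect_equal(fit1$logL, fit2$logL, tolerance = 1e-10)
  expect_equal(fit1$components$estimate, fit2$components$estimate,
               tolerance = 1e-8)
  expect_equal(
    fit1$ebv$ebv[order(fit1$ebv$animal)],
    fit2$ebv$ebv[order(fit2$ebv$animal)],
    tolerance = 1e-8
  )
})

test_that("EM fallback steps never decrease the likelihood", {
  cfg <- default_trait_configs()$melanoma
  des <- study_design(n_founders = 30, n_generations = 3,
                      n_per_generation = 80, n_measured = 120,
                      mean_records = 3)
  st <- simulate_study(cfg, des, seed = 55)
  fit <- fit_animal_model(st$phenotypes, st$pedigree, traits = "melanoma",
                          genotypes = st$genotypes, stx17 = TRUE,
                          asip = TRUE)
  tr <- fit$trace
  em_rows <- which(tr$step == 2)
  em_rows <- em_rows[em_rows > 1]
  if (length(em_rows)) {
    expect_true(all(tr$logL[em_rows] >= tr$logL[em_rows - 1] - 1e-8))
  }
  expect_true(fit$converged)
  # the trace likelihood is overall non-decreasing at convergence
  expect_gte(tr$logL[nrow(tr)], tr$logL[1])
})

test_that("the heritability estimator tightens on the truth as the
           sample grows", {
  cfg <- default_trait_configs()$melanoma
  sizes <- c(100, 300, 900)
  vs <- locus_variance(cfg$alpha_stx17, cfg$p_g)
  va <- locus_variance(cfg$asip_a, cfg$p_a)
  h2_true <- (cfg$v_poly + vs + va) /
    (cfg$v_poly + cfg$v_pe + cfg$v_e + vs + va)
  rmse <- numeric(3)
  for (k in seq_along(sizes)) {
    n <- sizes[k]
    des <- study_design(n_founders = max(20, n %/% 10),
                        n_generations = 3, n_per_generation = n %/% 2,
                        n_measured = n, mean_records = 3)
    h2_hat <- numeric(4)
    for (r in 1:4) {
      st <- simulate_study(cfg, des, seed = 7000 + 10 * k + r)
      fit <- fit_animal_model(st$phenotypes, st$pedigree,
                              traits = "melanoma",
                              genotypes = st$genotypes,
                              stx17 = TRUE, asip = TRUE)
      h2_hat[r] <- decompose_fit(fit, st$genotypes)$h2
    }
    rmse[k] <- sqrt(mean((h2_hat - h2_true)^2))
  }
  # consistency: the root-mean-square error contracts with n, and at the
  # largest size the estimator is close to the truth
  expect_lt(rmse[3], rmse[1])
  expect_lt(rmse[3], 0.08)
})

test_that("EBV standardization and sanity properties hold", {
  x <- rnorm(50, 3, 2)
  z <- standardize_ebv(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_error(standardize_ebv(rep(1, 10)),
               class = "greyherit_error_standardize")

  cfg <- default_trait_configs()$melanoma
  des <- study_design(n_founders = 40, n_generations = 3,
                      n_per_generation = 120, n_measured = 200,
                      mean_records = 3)
  st <- simulate_study(cfg, des, seed = 77)
  fit <- fit_animal_model(st$phenotypes, st$pedigree, traits = "melanoma",
                          genotypes = st$genotypes, stx17 = TRUE,
                          asip = TRUE)
  ebv <- predict_ebv(fit)
  ped <- st$pedigree
  both <- !is.na(ped$sire) & !is.na(ped$dam)
  mid <- ebv$ebv[match(ped$sire[both], ebv$animal)] +
    ebv$ebv[match(ped$dam[both], ebv$animal)]
  expect_gt(cor(mid, ebv$ebv[match(ped$id[both], ebv$animal)]), 0.3)
  # reliabilities are proportions
  expect_true(all(ebv$reliability >= 0 & ebv$reliability <= 1))
})
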