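#' Trait configuration for the phenotype simulator
#'
#' Bundles the parameters of one trait's generating model: variance
#' components (squared trait units), major-locus effects (trait units),
#' the linear age effect (trait units per year), the mean for a
#' seven-year-old, the age window in which the trait is recorded and the
#' measurement scale. `default_trait_configs()` returns the four shipped
#' configurations corresponding to the published univariate estimates for
#' melanoma grade, grey level (L*), vitiligo grade and speckling grade.
#'
#' @param name Trait name.
#' @param v_poly,v_pe,v_e Polygenic, permanent-environment and residual
#'   variances.
#' @param alpha_stx17 Substitution effect of the Grey mutation (Gg vs GG).
#' @param asip_a,asip_d ASIP additive and dominance values (codes
#'   AA=0, Aa=1, aa=2 and AA=0, Aa=1, aa=0).
#' @param beta_age Linear age effect per year.
#' @param mean7 Expected value for a seven-year-old GG/AA animal in an
#'   average stud-sex-year class.
#' @param age_window `"young"` (records at 12-84 months) or `"old"`
#'   (84-240 months); 84 months (seven years) is included in both windows.
#' @param scale Numeric length-2 measurement bounds, used only when
#'   phenotypes are rounded/clipped to the grading scale.
#' @param scale_step Grading step (e.g. 0.5 for melanoma), or `NULL` for a
#'   continuous scale.
#' @param p_g,p_a Founder allele frequencies of G (STX17) and A (ASIP).
#' @param v_class Variance of the stud-by-sex-by-year class effects;
#'   defaults to 10% of the phenotypic variance implied by the other
#'   parameters.
#' @return A list of class `grey_trait_config`.
#' @export
trait_config <- function(name, v_poly, v_pe, v_e,
                         alpha_stx17 = 0, asip_a = 0, asip_d = 0,
                         beta_age = 0, mean7 = 0,
                         age_window = c("old", "young"),
                         scale = c(-Inf, Inf), scale_step = NULL,
                         p_g = 0.87, p_a = 0.52, v_class = NULL) {
  age_window <- match.arg(age_window)
  for (v in c(v_poly, v_pe, v_e)) {
    if (is.na(v) || v < 0) {
      abort("variances must be non-negative", class = "greyherit_error_config")
    }
  }
  if (p_g < 0 || p_g > 1 || p_a < 0 || p_a > 1) {
    abort("allele frequencies must lie in [0, 1]",
          class = "greyherit_error_config")
  }
  cfg <- list(
    name = name, v_poly = v_poly, v_pe = v_pe, v_e = v_e,
    alpha_stx17 = alpha_stx17, asip_a = asip_a, asip_d = asip_d,
    beta_age = beta_age, mean7 = mean7, age_window = age_window,
    scale = scale, scale_step = scale_step, p_g = p_g, p_a = p_a
  )
  vp <- config_phenotypic_variance(cfg)
  cfg$v_class <- v_class %||% (0.10 * vp)
  structure(cfg, class = "grey_trait_config")
}

# Phenotypic variance implied by a config (Hardy-Weinberg locus variances
# at the founder frequencies plus the three fitted components).
config_phenotypic_variance <- function(cfg) {
  alpha_asip <- cfg$asip_a + (cfg$p_a - (1 - cfg$p_a)) * cfg$asip_d
  cfg$v_poly + cfg$v_pe + cfg$v_e +
    locus_variance(cfg$alpha_stx17, cfg$p_g) +
    locus_variance(alpha_asip, cfg$p_a)
}

#' @rdname trait_config
#' @export
default_trait_configs <- function() {
  list(
    melanoma = trait_config(
      "melanoma", v_poly = 0.19, v_pe = 0.27, v_e = 0.39,
      alpha_stx17 = -0.85, asip_a = 0.19, beta_age = 0.11, mean7 = 0.56,
      age_window = "old", scale = c(0, 5), scale_step = 0.5
    ),
    greying = trait_config(
      "greying", v_poly = 99.19, v_pe = 5.06, v_e = 32.66,
      alpha_stx17 = -13.78, beta_age = 5.88, mean7 = 70.15,
      age_window = "young", scale = c(0, 100)
    ),
    vitiligo = trait_config(
      "vitiligo", v_poly = 0.29, v_pe = 0.00, v_e = 0.26,
      alpha_stx17 = -0.82, beta_age = 0.06, mean7 = 0.85,
      age_window = "old", scale = c(0, 3)
    ),
    speckling = trait_config(
      "speckling", v_poly = 0.09, v_pe = 0.10, v_e = 0.19,
      alpha_stx17 = 1.36, beta_age = 0.02, mean7 = 0.39,
      age_window = "old", scale = c(0, 3)
    )
  )
}

#' Study design for the simulator
#'
#' Describes the population and recording structure the generator emulates:
#' a multi-generation closed studbook with reused sires and dams, a set of
#' studs visited repeatedly over a span of years, and repeated measurements
#' per animal. The defaults mirror the scale of the motivating study
#' (about 5,000 pedigree members, ~1,100 measured grey horses, 6 studs,
#' 9 measurement years, sires with ~6 offspring and dams with ~2.3).
#'
#' @param n_founders Founder animals (generation 0).
#' @param n_generations Total generations including the founders.
#' @param n_per_generation Offspring born into each later generation.
#' @param mean_offspring_per_sire,mean_offspring_per_dam Target family
#'   sizes; they set how many sires/dams of the previous generation are
#'   used as parents.
#' @param n_studs Number of studs.
#' @param years Measurement years.
#' @param n_measured Number of (grey) animals carrying phenotype records.
#' @param mean_records Mean number of records per measured animal and trait
#'   (at least one record each).
#' @return A list of class `grey_study_design`.
#' @export
study_design <- function(n_founders = 500, n_generations = 6,
                         n_per_generation = 743,
                         mean_offspring_per_sire = 5.97,
                         mean_offspring_per_dam = 2.26,
                         n_studs = 6, years = 1999:2007,
                         n_measured = 1119, mean_records = 2.5) {
  if (n_founders < 2 || n_generations < 1 || n_per_generation < 1 ||
      n_studs < 1 || n_measured < 1 || mean_records < 1) {
    abort("study design counts must be positive",
          class = "greyherit_error_config")
  }
  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    n_per_generation = as.integer(n_per_generation),
    mean_offspring_per_sire = mean_offspring_per_sire,
    mean_offspring_per_dam = mean_offspring_per_dam,
    n_studs = as.integer(n_studs), years = as.integer(years),
    n_measured = as.integer(n_measured), mean_records = mean_records
  ), class = "grey_study_design")
}

#' Simulate a multi-generation pedigree
#'
#' Generation 0 consists of unrelated founders with random sex. Each later
#' generation draws, for every offspring, a sire from a reused pool of the
#' previous generation's males and a dam from a pool of its females; pool
#' sizes are set from the design's mean family sizes. Fully reproducible
#' under a seed.
#'
#' @param design A [study_design()].
#' @param seed Integer seed (mandatory; the generator is deterministic).
#' @return A `grey_pedigree` with an extra `generation` column.
#' @export
simulate_pedigree <- function(design = study_design(), seed) {
  stopifnot(inherits(design, "grey_study_design"))
  withr::with_seed(seed, {
    n0 <- design$n_founders
    id_fmt <- function(k) sprintf("H%05d", k)
    ids <- id_fmt(seq_len(n0))
    # balanced founder sexes so every design has available parents
    sex <- sample(rep_len(c("M", "F"), n0))
    ped <- tibble(id = ids, sire = NA_character_, dam = NA_character_,
                  sex = sex, birth_year = min(design$years) -
                    5L * design$n_generations,
                  generation = 0L)
    counter <- n0
    for (g in seq_len(design$n_generations - 1L)) {
      prev <- ped[ped$generation == g - 1L, ]
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      if (!length(males) || !length(females)) {
        abort(paste0("generation ", g - 1L,
                     " has no available sires or dams"),
              class = "greyherit_error_config")
      }
      n_off <- design$n_per_generation
      n_sires <- max(1L, min(length(males),
                             round(n_off / design$mean_offspring_per_sire)))
      n_dams <- max(1L, min(length(females),
                            round(n_off / design$mean_offspring_per_dam)))
      sire_pool <- sample(males, n_sires)
      dam_pool <- sample(females, n_dams)
      off <- tibble(
        id = id_fmt(counter + seq_len(n_off)),
        sire = sample(sire_pool, n_off, replace = TRUE),
        dam = sample(dam_pool, n_off, replace = TRUE),
        sex = ifelse(runif(n_off) < 0.5, "M", "F"),
        birth_year = min(design$years) - 5L * (design$n_generations - g),
        generation = g
      )
      counter <- counter + n_off
      ped <- bind_rows(ped, off)
    }
    as_pedigree(ped, quiet = TRUE)
  })
}

#' Gene-drop genotypes at STX17 and ASIP
#'
#' Founder genotypes are drawn from Hardy-Weinberg proportions at the given
#' allele frequencies; every offspring inherits one allele drawn at random
#' from each parent, independently at the two (unlinked) loci. An unknown
#' parent contributes a population allele. Coat colour follows the dominant
#' Grey mutation: grey iff the animal carries at least one G allele.
#'
#' @param ped A `grey_pedigree`.
#' @param p_g,p_a Founder frequencies of G and A.
#' @param seed Integer seed.
#' @return A list with `genotypes` (tibble
#'   `id, stx17, asip, stx17_source, asip_source`, sources `"measured"`)
#'   and `colour` (tibble `id, colour`).
#' @export
drop_genotypes <- function(ped, p_g = 0.87, p_a = 0.52, seed) {
  stopifnot(inherits(ped, "grey_pedigree"))
  pi <- parent_index(ped)
  withr::with_seed(seed, {
    stx <- gene_drop_locus(pi$sire, pi$dam, p_g)
    asp <- gene_drop_locus(pi$sire, pi$dam, p_a)
  })
  genotypes <- tibble(
    id = ped$id,
    stx17 = c("gg", "Gg", "GG")[stx + 1L],
    asip = c("aa", "Aa", "AA")[asp + 1L],
    stx17_source = "measured", asip_source = "measured"
  )
  colour <- tibble(id = ped$id,
                   colour = ifelse(stx >= 1L, "grey", "coloured"))
  list(genotypes = genotypes, colour = colour)
}

# Reference-allele counts (0/1/2) dropped through the pedigree.
gene_drop_locus <- function(si, di, p) {
  n <- length(si)
  cnt <- integer(n)
  for (i in seq_len(n)) {
    a1 <- if (is.na(si[i])) rbinom(1, 1, p) else rbinom(1, 1, cnt[si[i]] / 2)
    a2 <- if (is.na(di[i])) rbinom(1, 1, p) else rbinom(1, 1, cnt[di[i]] / 2)
    cnt[i] <- a1 + a2
  }
  cnt
}

#' Simulate polygenic breeding values
#'
#' Recursive Mendelian sampling over the pedigree: founders draw
#' `u ~ N(0, G0)`; an offspring draws
#' `u = 0.5 (u_sire + u_dam) + m` with Mendelian-sampling deviation
#' `m ~ N(0, 0.5 (1 - (F_s + F_d)/2) G0)` (with one unknown parent the
#' parent-average term has one parent and the deviation variance is
#' `(0.75 - 0.25 F_p) G0`). The implied joint covariance is the Kronecker
#' product of the relationship matrix A with `G0`.
#'
#' @param ped A `grey_pedigree`.
#' @param g0 Polygenic (co)variance: a scalar, or a symmetric PSD matrix
#'   for several traits.
#' @param seed Integer seed.
#' @param traits Optional trait names for the columns.
#' @return A numeric matrix (animals x traits) with pedigree ids as
#'   rownames.
#' @export
simulate_breeding_values <- function(ped, g0, seed, traits = NULL) {
  stopifnot(inherits(ped, "grey_pedigree"))
  g0 <- as.matrix(g0)
  if (!isSymmetric(unname(g0), tol = 1e-10)) {
    abort("g0 must be symmetric", class = "greyherit_error_config")
  }
  eg <- eigen(g0, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1)) {
    abort("g0 must be positive semi-definite",
          class = "greyherit_error_config")
  }
  sq <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  nt <- ncol(g0)
  pi <- parent_index(ped)
  f <- inbreeding_vector(pi$sire, pi$dam)
  n <- nrow(ped)
  withr::with_seed(seed, {
    u <- matrix(0, n, nt)
    z <- matrix(rnorm(n * nt), n, nt) %*% sq
    for (i in seq_len(n)) {
      s <- pi$sire[i]
      d <- pi$dam[i]
      if (!is.na(s) && !is.na(d)) {
        u[i, ] <- 0.5 * (u[s, ] + u[d, ]) +
          sqrt(0.5 * (1 - (f[s] + f[d]) / 2)) * z[i, ]
      } else if (!is.na(s) || !is.na(d)) {
        p <- if (is.na(s)) d else s
        u[i, ] <- 0.5 * u[p, ] + sqrt(0.75 - 0.25 * f[p]) * z[i, ]
      } else {
        u[i, ] <- z[i, ]
      }
    }
  })
  rownames(u) <- ped$id
  colnames(u) <- traits %||% colnames(g0) %||% paste0("trait", seq_len(nt))
  u
}

#' Simulate repeated phenotype records for one trait
#'
#' Each record is the sum of a stud-by-sex-by-year class effect (drawn once
#' per class from `N(0, v_class)`), the linear age effect, the major-locus
#' effects (STX17 indicator GG=0/Gg=1; ASIP additive AA=0/Aa=1/aa=2 and
#' dominance AA=0/Aa=1/aa=0), the animal's polygenic breeding value, a
#' permanent-environment effect shared across its records, and a record
#' residual. Ages are drawn inside the trait's recording window (young:
#' 12-84 months; old: 84-240 months). Phenotypes are continuous by
#' default; `round_to_scale = TRUE` clips to the measurement scale and
#' rounds to the grading step as a robustness stressor.
#'
#' @param ped A `grey_pedigree` (a `generation` column, if present, is used
#'   to pick measured animals from the latest generations).
#' @param genotypes Genotype tibble covering the measured animals.
#' @param u Breeding values from [simulate_breeding_values()]; the column
#'   matching `cfg$name` (or the only column) is used.
#' @param cfg A [trait_config()].
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @param animals Optional character vector of animals to measure;
#'   defaults to `design$n_measured` grey animals sampled from the last
#'   three generations.
#' @param round_to_scale Clip and round records to the grading scale.
#' @return A tibble `animal, trait, value, age_months, stud, sex, year`
#'   with the simulated truth (class effects, permanent-environment
#'   effects, measured set) in `attr(, "truth")`.
#' @export
simulate_phenotypes <- function(ped, genotypes, u, cfg,
                                design = study_design(), seed,
                                animals = NULL, round_to_scale = FALSE) {
  stopifnot(inherits(ped, "grey_pedigree"),
            inherits(cfg, "grey_trait_config"),
            inherits(design, "grey_study_design"))
  gt <- as_tibble(genotypes)
  withr::with_seed(seed, {
    if (is.null(animals)) {
      animals <- sample_measured_animals(ped, gt, design$n_measured)
    }
    idx <- match(animals, ped$id)
    if (anyNA(idx)) {
      abort("measured animal missing from pedigree",
            class = "greyherit_error_id")
    }
    ucol <- if (cfg$name %in% colnames(u)) u[, cfg$name] else u[, 1]
    gidx <- match(animals, gt$id)
    stx <- gt$stx17[gidx]
    asp <- gt$asip[gidx]
    stx_code <- ifelse(stx == "Gg", 1, 0)       # gg animals are not recorded
    asip_add <- asip_additive_code(asp)
    asip_dom <- asip_dominance_code(asp)
    asip_add[is.na(asip_add)] <- 0
    asip_dom[is.na(asip_dom)] <- 0

    n_an <- length(animals)
    stud <- sample(paste0("stud", seq_len(design$n_studs)), n_an,
                   replace = TRUE)
    sexes <- ped$sex[idx]
    sexes[sexes == "unknown"] <- "F"
    n_rec <- 1L + rpois(n_an, max(design$mean_records - 1, 0))
    pe <- rnorm(n_an, 0, sqrt(cfg$v_pe))

    rec_animal <- rep(seq_len(n_an), n_rec)
    n <- length(rec_animal)
    year <- sample(design$years, n, replace = TRUE)
    age_months <- if (cfg$age_window == "young") {
      runif(n, 12, 84)
    } else {
      runif(n, 84, 240)
    }

    cls <- interaction(stud[rec_animal], sexes[rec_animal], year,
                       drop = TRUE, sep = ":")
    cls_levels <- levels(cls)
    cls_eff <- rnorm(length(cls_levels), 0, sqrt(cfg$v_class))
    names(cls_eff) <- cls_levels

    value <- cfg$mean7 +
      cls_eff[as.character(cls)] +
      cfg$beta_age * (age_months / 12 - 7) +
      cfg$alpha_stx17 * stx_code[rec_animal] +
      cfg$asip_a * asip_add[rec_animal] +
      cfg$asip_d * asip_dom[rec_animal] +
      ucol[ped$id[idx][rec_animal]] +
      pe[rec_animal] +
      rnorm(n, 0, sqrt(cfg$v_e))
    if (round_to_scale) {
      value <- pmin(pmax(value, cfg$scale[1]), cfg$scale[2])
      if (!is.null(cfg$scale_step)) {
        value <- round(value / cfg$scale_step) * cfg$scale_step
      }
    }
    out <- tibble(
      animal = animals[rec_animal], trait = cfg$name,
      value = unname(value), age_months = age_months,
      stud = stud[rec_animal], sex = sexes[rec_animal], year = year
    )
  })
  attr(out, "truth") <- list(
    class_effects = tibble(class = cls_levels, effect = unname(cls_eff)),
    pe = tibble(animal = animals, pe = pe),
    animals = animals
  )
  out
}

sample_measured_animals <- function(ped, gt, n_measured) {
  grey <- gt$id[!is.na(gt$stx17) & gt$stx17 != "gg"]
  pool <- ped$id[ped$id %in% grey]
  if ("generation" %in% names(ped)) {
    gens <- sort(unique(ped$generation), decreasing = TRUE)
    late <- ped$id[ped$generation %in% head(gens, 3)]
    pool_late <- intersect(pool, late)
    if (length(pool_late) >= n_measured) pool <- pool_late
  }
  if (!length(pool)) {
    abort("no grey animals available to measure",
          class = "greyherit_error_empty")
  }
  sample(pool, min(n_measured, length(pool)))
}

#' Simulate a complete study
#'
#' Orchestrates [simulate_pedigree()], [drop_genotypes()],
#' [simulate_breeding_values()] and [simulate_phenotypes()] for one or more
#' traits, with a polygenic correlation structure across traits. One set of
#' measured animals is shared by all traits. All randomness derives from
#' `seed`.
#'
#' @param configs A named list of [trait_config()]s (or a single config).
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @param r_poly Polygenic correlation between traits: a scalar (applied to
#'   every pair) or a full correlation matrix; default 0.
#' @param round_to_scale Passed to [simulate_phenotypes()].
#' @return A list of class `grey_study`: `pedigree`, `genotypes`, `colour`,
#'   `phenotypes` (all traits stacked), `breeding_values`, `configs`,
#'   `design`.
#' @export
simulate_study <- function(configs, design = study_design(), seed,
                           r_poly = 0, round_to_scale = FALSE) {
  if (inherits(configs, "grey_trait_config")) configs <- list(configs)
  names(configs) <- vapply(configs, `[[`, "", "name")
  nt <- length(configs)
  ped <- simulate_pedigree(design, seed = seed)
  gd <- drop_genotypes(ped, p_g = configs[[1]]$p_g, p_a = configs[[1]]$p_a,
                       seed = seed + 1L)
  vp <- vapply(configs, `[[`, 0, "v_poly")
  rho <- if (is.matrix(r_poly)) r_poly else {
    m <- matrix(r_poly, nt, nt)
    diag(m) <- 1
    m
  }
  g0 <- diag(sqrt(vp), nt) %*% rho %*% diag(sqrt(vp), nt)
  dimnames(g0) <- list(names(configs), names(configs))
  u <- simulate_breeding_values(ped, g0, seed = seed + 2L,
                                traits = names(configs))
  measured <- withr::with_seed(seed + 3L, {
    sample_measured_animals(ped, gd$genotypes, design$n_measured)
  })
  phen <- purrr::imap(configs, function(cfg, nm) {
    k <- match(nm, names(configs))
    simulate_phenotypes(ped, gd$genotypes, u, cfg, design,
                        seed = seed + 10L + k, animals = measured,
                        round_to_scale = round_to_scale)
  })
  structure(list(
    pedigree = ped, genotypes = gd$genotypes, colour = gd$colour,
    phenotypes = bind_rows(unname(phen)), breeding_values = u,
    configs = configs, design = design, measured = measured, seed = seed
  ), class = "grey_study")
}

#' @export
print.grey_study <- function(x, ...) {
  cat("<grey_study> ", nrow(x$pedigree), " pedigree animals, ",
      length(x$measured), " measured, ", nrow(x$phenotypes),
      " records across ", length(x$configs), " trait(s)\n", sep = "")
  invisible(x)
}
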