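TRAIT_SCALES <- list(
  melanoma = c(0, 5), greying = c(0, 100),
  vitiligo = c(0, 3), speckling = c(0, 3)
)
# Grey level varies while horses whiten (young window); melanoma, vitiligo
# and speckling only manifest from middle age (old window). Seven years
# (84 months) is deliberately included in BOTH windows, matching the
# inclusive wording of the recording protocol ("seven years old and
# younger" / "seven years old and older").
TRAIT_WINDOWS <- list(
  melanoma = "old", greying = "young", vitiligo = "old", speckling = "old"
)
AGE_BOUNDARY_MONTHS <- 84

#' Filter records to a trait's analysis window and scale
#'
#' Applies the per-trait data-preparation rules: grey-level records are
#' kept only for horses 84 months (seven years) old and younger; melanoma,
#' vitiligo and speckling records only for horses 84 months old and older
#' (the boundary month belongs to both windows); values outside the
#' trait's measurement scale are rejected. The counts removed by each
#' filter are recorded in `attr(, "filter_log")`.
#'
#' @param records Phenotype tibble with `trait`, `value`, `age_months`.
#' @param trait Trait to prepare. The four standard traits carry default
#'   windows and scales; other traits need `window`/`scale`.
#' @param window `"young"`, `"old"` or `NULL` for the trait default.
#' @param scale Length-2 bounds or `NULL` for the trait default.
#' @return The filtered tibble (class `grey_prepared`) with a
#'   `filter_log` attribute (tibble `filter, n_dropped`).
#' @export
prepare_records <- function(records, trait, window = NULL, scale = NULL) {
  rec <- as_tibble(records)
  if ("trait" %in% names(rec)) rec <- rec[rec$trait == trait, ]
  n_in <- nrow(rec)
  if (!n_in) {
    abort(paste0("no records for trait ", trait),
          class = "greyherit_error_empty")
  }
  window <- window %||% TRAIT_WINDOWS[[trait]]
  scale <- scale %||% TRAIT_SCALES[[trait]]
  if (is.null(window) || is.null(scale)) {
    abort(paste0("unknown trait ", trait,
                 ": supply window= and scale= explicitly"),
          class = "greyherit_error_config")
  }
  log_rows <- list()
  keep_age <- if (window == "young") {
    rec$age_months <= AGE_BOUNDARY_MONTHS
  } else {
    rec$age_months >= AGE_BOUNDARY_MONTHS
  }
  log_rows$age <- tibble(
    filter = paste0("age_window_", window), n_dropped = sum(!keep_age)
  )
  rec <- rec[keep_age, ]
  keep_scale <- rec$value >= scale[1] & rec$value <= scale[2]
  log_rows$scale <- tibble(filter = "scale_bounds",
                           n_dropped = sum(!keep_scale))
  rec <- rec[keep_scale, ]
  if (!nrow(rec)) {
    abort(paste0("no records left for ", trait, " after filtering"),
          class = "greyherit_error_empty")
  }
  out <- rec
  attr(out, "filter_log") <- bind_rows(log_rows)
  class(out) <- c("grey_prepared", class(tibble()))
  out
}

#' The three correlation scenarios
#'
#' Fits the bivariate animal model for a pair of traits under the three
#' scenarios used to attribute genetic correlations to major-gene
#' pleiotropy versus polygenic background:
#' scenario 1 - purely polygenic model, all genotyped horses;
#' scenario 2 - polygenic model plus the STX17 covariate for both traits
#' (and the ASIP additive covariate for traits listed in `asip_traits`,
#' by default melanoma), all genotyped horses;
#' scenario 3 - purely polygenic model restricted to homozygous (GG)
#' horses. A drop of the polygenic correlation from scenario 1 to
#' scenarios 2/3 indicates that the correlation was driven by the shared
#' major gene.
#'
#' @param records Prepared phenotype tibble holding both traits.
#' @param ped A `grey_pedigree`.
#' @param genotypes Genotype tibble (measured and/or deduced).
#' @param traits Character vector of the two traits.
#' @param scenarios Which scenarios to run (subset of 1:3).
#' @param asip_traits Traits that get the ASIP covariate in scenario 2.
#' @param strict_gg Restrict scenario 3 to measured (not deduced) GG
#'   genotypes.
#' @param pe_cov Estimate the permanent-environment covariance.
#' @param ... Passed to [fit_animal_model()] (tolerances, `max_iter`, ...).
#' @return A tibble of class `grey_scenarios` with one row per scenario
#'   (`r_poly`, `se`, record and animal counts); the fitted models are in
#'   `attr(, "fits")`.
#' @export
run_scenarios <- function(records, ped, genotypes, traits,
                          scenarios = 1:3, asip_traits = "melanoma",
                          strict_gg = FALSE, pe_cov = TRUE, ...) {
  if (length(traits) != 2) {
    abort("run_scenarios needs exactly two traits",
          class = "greyherit_error_config")
  }
  rec <- as_tibble(records)
  gt <- as_tibble(genotypes)
  fits <- list()
  rows <- list()
  for (sc in scenarios) {
    rec_sc <- rec
    stx_flag <- FALSE
    asip_flag <- c(FALSE, FALSE)
    if (sc == 2) {
      stx_flag <- TRUE
      asip_flag <- traits %in% asip_traits
    }
    if (sc == 3) {
      src_ok <- if (strict_gg) "measured" else c("measured", "deduced")
      gg <- gt$id[!is.na(gt$stx17) & gt$stx17 == "GG" &
                    (!("stx17_source" %in% names(gt)) |
                       gt$stx17_source %in% src_ok)]
      if (!length(gg)) {
        abort("scenario 3 impossible: no homozygous (GG) animals",
              class = "greyherit_error_empty")
      }
      rec_sc <- rec_sc[rec_sc$animal %in% gg, ]
      if (!nrow(rec_sc)) {
        abort("scenario 3 impossible: no records from GG animals",
              class = "greyherit_error_empty")
      }
    }
    fit <- tryCatch(
      fit_animal_model(rec_sc, ped, traits = traits, genotypes = gt,
                       stx17 = stx_flag, asip = asip_flag,
                       pe_cov = pe_cov, ...),
      error = function(e) {
        abort(paste0("scenario ", sc, " failed: ", conditionMessage(e)),
              class = "greyherit_error_scenario", parent = e)
      }
    )
    fits[[as.character(sc)]] <- fit
    rows[[as.character(sc)]] <- tibble(
      scenario = sc,
      description = c("polygenic, all horses",
                      "polygenic + major loci, all horses",
                      "polygenic, GG horses only")[sc],
      trait_1 = traits[1], trait_2 = traits[2],
      r_poly = fit$r_poly$r_poly, se = fit$r_poly$se,
      n_records = sum(fit$n_records), n_animals = fit$n_animals,
      logL = fit$logL
    )
  }
  out <- bind_rows(rows)
  attr(out, "fits") <- fits
  class(out) <- c("grey_scenarios", class(tibble()))
  out
}

#' Report tables
#'
#' Shape fitted results into the three standard report tables:
#' `report_effects()` lists fixed effects and variance components per trait
#' (effects table); `report_partition()` the variance/heritability
#' partition with traits as columns (partition table; values rounded
#' half-up to `digits`); `report_correlations()` the polygenic correlation
#' per trait pair and scenario (correlation table).
#'
#' @param fits Named list of univariate `grey_fit`s (names = traits).
#' @return A tibble.
#' @export
report_effects <- function(fits) {
  if (!length(fits)) {
    return(tibble(trait = character(), parameter = character(),
                  estimate = numeric(), se = numeric()))
  }
  rows <- purrr::imap(fits, function(fit, nm) {
    fx <- fit$fixed[fit$fixed$term %in%
                      c("age_years", "stx17", "asip_add", "asip_dom"), ]
    bind_rows(
      tibble(trait = nm, parameter = fx$term, estimate = fx$estimate,
             se = fx$se),
      tibble(trait = nm,
             parameter = paste0(fit$components$component,
                                ifelse(fit$components$component %in%
                                         c("cov_poly", "cov_pe"), "_cov", "")),
             estimate = fit$components$estimate,
             se = fit$components$se)
    )
  })
  bind_rows(rows)
}

#' @rdname report_effects
#' @param decompositions A list of `grey_decomposition` rows (or a tibble
#'   of them) with the `trait` column filled in.
#' @param digits Rounding (half-up) for the partition table.
#' @export
report_partition <- function(decompositions, digits = 2) {
  dec <- bind_rows(decompositions)
  params <- c("v_p", "repeatability", "c2", "h2",
              "h2_poly", "h2_stx17", "h2_asip")
  if (!nrow(dec)) {
    return(tibble(parameter = params))
  }
  out <- tibble(parameter = params)
  for (k in seq_len(nrow(dec))) {
    vals <- unlist(dec[k, params])
    out[[dec$trait[k]]] <- round_half_up(as.numeric(vals), digits)
  }
  out
}

#' @rdname report_effects
#' @param scenario_results One `grey_scenarios` result or a list of them
#'   (several trait pairs).
#' @export
report_correlations <- function(scenario_results) {
  if (inherits(scenario_results, "grey_scenarios")) {
    scenario_results <- list(scenario_results)
  }
  if (!length(scenario_results)) {
    return(tibble(trait_1 = character(), trait_2 = character(),
                  scenario = integer(), r_poly = numeric(), se = numeric()))
  }
  long <- bind_rows(lapply(scenario_results, as_tibble))
  long[, c("trait_1", "trait_2", "scenario", "r_poly", "se")]
}

#' Export standardized breeding values for plotting
#'
#' Standardizes each trait's breeding values (over animals with records)
#' to mean zero and unit standard deviation, and attaches the STX17
#' genotype label, the plot-ready form of the breeding-value scatter used
#' to visualise major-gene and polygenic contributions to a genetic
#' correlation.
#'
#' @param fit A bivariate (or univariate) `grey_fit`.
#' @param genotypes Genotype tibble supplying `stx17` labels.
#' @return A tibble of class `grey_ebv_export`: `animal`, one standardized
#'   EBV column per trait, `stx17`.
#' @export
export_ebv <- function(fit, genotypes = NULL) {
  stopifnot(inherits(fit, "grey_fit"))
  ebv <- predict_ebv(fit, recorded_only = TRUE)
  wide <- tidyr::pivot_wider(ebv[, c("animal", "trait", "ebv")],
                             names_from = "trait", values_from = "ebv")
  for (tr in fit$traits) {
    wide[[tr]] <- standardize_ebv(wide[[tr]])
  }
  wide$stx17 <- if (!is.null(genotypes)) {
    as_tibble(genotypes)$stx17[match(wide$animal,
                                     as_tibble(genotypes)$id)]
  } else {
    NA_character_
  }
  class(wide) <- c("grey_ebv_export", class(tibble()))
  wide
}

#' Write a report bundle to disk
#'
#' Writes the effects, partition and correlation tables plus the EBV
#' export as CSV files under `dir`.
#'
#' @param bundle Named list with any of `effects`, `partition`,
#'   `correlations`, `ebv` tibbles.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(bundle)) {
    readr::write_csv(as_tibble(bundle[[nm]]),
                     file.path(dir, paste0(nm, ".csv")), progress = FALSE)
  }
  invisible(dir)
}
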