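#' Tidy a fitted animal model
#'
#' Returns one row per estimated quantity: fixed effects, variance
#' components and (for bivariate fits) the polygenic correlation, in the
#' broom convention (`term`, `estimate`, `std.error`).
#'
#' @param x A `grey_fit`.
#' @param effects `"all"`, `"fixed"` or `"ran_pars"`.
#' @param ... Unused.
#' @export
tidy.grey_fit <- function(x, effects = c("all", "fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  fixed <- tibble(
    effect = "fixed", trait = x$fixed$trait, term = x$fixed$term,
    estimate = x$fixed$estimate, std.error = x$fixed$se
  )
  comp <- tibble(
    effect = "ran_pars", trait = x$components$trait_1,
    term = ifelse(x$components$trait_1 == x$components$trait_2,
                  x$components$component,
                  paste0(x$components$component, "(",
                         x$components$trait_1, ",",
                         x$components$trait_2, ")")),
    estimate = x$components$estimate, std.error = x$components$se
  )
  if (!is.null(x$r_poly)) {
    comp <- bind_rows(comp, tibble(
      effect = "ran_pars", trait = NA_character_, term = "r_poly",
      estimate = x$r_poly$r_poly, std.error = x$r_poly$se
    ))
  }
  switch(effects, fixed = fixed, ran_pars = comp,
         all = bind_rows(fixed, comp))
}

#' Glance at a fitted animal model
#'
#' @param x A `grey_fit`.
#' @param ... Unused.
#' @export
glance.grey_fit <- function(x, ...) {
  tibble(
    logLik = x$logL, nobs = sum(x$n_records), n_animals = x$n_animals,
    n_fixed = x$n_fixed, iterations = x$iterations,
    converged = x$converged
  )
}

#' Tidy a variance decomposition
#'
#' @param x A `grey_decomposition`.
#' @param ... Unused.
#' @export
tidy.grey_decomposition <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"trait",
                      names_to = "quantity", values_to = "value")
}

#' Tidy a scenario comparison
#'
#' @param x A `grey_scenarios`.
#' @param ... Unused.
#' @export
tidy.grey_scenarios <- function(x, ...) {
  as_tibble(x)[, c("scenario", "description", "trait_1", "trait_2",
                   "r_poly", "se")]
}

#' Plot standardized breeding values by STX17 genotype
#'
#' Scatter of the two traits' standardized breeding values with 95%
#' normal-contour ellipses per STX17 genotype — the visual check that a
#' genetic correlation persists (elliptical, tilted clouds within
#' genotype) or is driven by the major gene (shifted cloud centres).
#'
#' @param object A `grey_ebv_export` with two trait columns.
#' @param ... Unused.
#' @export
autoplot.grey_ebv_export <- function(object, ...) {
  traits <- setdiff(names(object), c("animal", "stx17"))
  if (length(traits) < 2) {
    abort("autoplot needs a bivariate EBV export",
          class = "greyherit_error_config")
  }
  df <- as_tibble(object)
  ggplot(df, aes(x = .data[[traits[1]]], y = .data[[traits[2]]],
                 colour = .data$stx17)) +
    geom_point(alpha = 0.6, size = 1) +
    stat_ellipse(level = 0.95) +
    labs(x = paste("standardized EBV,", traits[1]),
         y = paste("standardized EBV,", traits[2]),
         colour = "STX17") +
    theme_minimal()
}

#' Plot the variance partition
#'
#' Stacked shares of phenotypic variance per trait.
#'
#' @param object A `grey_decomposition` (possibly several rows).
#' @param ... Unused.
#' @export
autoplot.grey_decomposition <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(
    df[, c("trait", "h2_poly", "h2_stx17", "h2_asip", "c2")],
    -"trait", names_to = "part", values_to = "share"
  )
  long$part <- factor(long$part,
                      levels = c("h2_poly", "h2_stx17", "h2_asip", "c2"))
  ggplot(long, aes(x = .data$trait, y = .data$share, fill = .data$part)) +
    geom_col() +
    labs(x = NULL, y = "share of phenotypic variance", fill = NULL) +
    theme_minimal()
}

#' Plot the REML iteration trace
#'
#' @param object A `grey_fit`.
#' @param ... Unused.
#' @export
autoplot.grey_fit <- function(object, ...) {
  tr <- as_tibble(object$trace)
  tr$step_type <- c("init", "AI", "EM")[tr$step + 1]
  ggplot(tr, aes(x = .data$iter, y = .data$logL)) +
    geom_line(colour = "grey50") +
    geom_point(aes(colour = .data$step_type)) +
    labs(x = "iteration", y = "restricted log-likelihood",
         colour = "step") +
    theme_minimal()
}
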