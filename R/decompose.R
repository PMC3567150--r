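#' Gene-substitution effect at a biallelic locus
#'
#' The average effect of substituting one allele: `alpha = a + (p - q) d`,
#' where `a` is the additive value, `d` the dominance value and `p`, `q`
#' the allele frequencies. For the Grey (STX17) locus only two genotypes
#' segregate among grey horses (GG, Gg), so the fitted regression
#' coefficient is the substitution effect directly (`alpha = a`; `d` does
#' not enter). With `d = 0` the expected phenotype change from one
#' homozygote to the other is `2 alpha`.
#'
#' @param a Additive value (trait units).
#' @param d Dominance value (default 0).
#' @param p Frequency of the reference allele.
#' @param locus `"asip"` (general biallelic form) or `"stx17"`
#'   (two-genotype locus, `alpha = a`).
#' @return The substitution effect `alpha` (trait units).
#' @export
substitution_effect <- function(a, d = 0, p = 0.5,
                                locus = c("asip", "stx17")) {
  locus <- match.arg(locus)
  check_freq(p)
  if (locus == "stx17") a else a + (p - (1 - p)) * d
}

#' Additive variance contributed by a major locus
#'
#' `V_locus = 2 p q alpha^2`: the additive genetic variance of a biallelic
#' locus with substitution effect `alpha` at allele frequency `p`
#' (`q = 1 - p`). Zero when the locus is fixed, maximal at `p = 0.5`, and
#' symmetric in `p` and `q`.
#'
#' @param alpha Substitution effect (trait units).
#' @param p Reference-allele frequency in `[0, 1]`.
#' @return Variance in squared trait units.
#' @export
locus_variance <- function(alpha, p) {
  check_freq(p)
  2 * p * (1 - p) * alpha^2
}

check_freq <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("allele frequency must lie in [0, 1]",
          class = "greyherit_error_config")
  }
  invisible(p)
}

#' Decompose phenotypic variance and heritability
#'
#' Combines REML variance components with major-locus substitution effects
#' into the full partition of phenotypic variance:
#' `V_P = V_POLY + V_STX17 + V_ASIP + V_pe + V_e` with
#' `V_locus = 2 p q alpha^2`, and the derived proportions
#' repeatability `R = (V_POLY + V_STX17 + V_ASIP + V_pe) / V_P`,
#' permanent-environment share `c2 = V_pe / V_P`, narrow-sense heritability
#' `h2 = (V_POLY + V_STX17 + V_ASIP) / V_P` and its parts
#' `h2_poly`, `h2_stx17`, `h2_asip`. A locus that is not fitted (or not
#' significant) contributes zero variance. When `v_p` is supplied (e.g. a
#' published phenotypic variance) the proportions are computed against it
#' instead of the component sum.
#'
#' @param v_poly,v_pe,v_e Estimated variance components.
#' @param alpha_stx17,p_g Substitution effect and G-allele frequency for
#'   STX17; `alpha_stx17 = NULL` omits the locus.
#' @param alpha_asip,p_a Same for ASIP.
#' @param v_p Optional phenotypic-variance override for the proportions.
#' @param trait Optional trait label carried through to reports.
#' @return A one-row tibble of class `grey_decomposition` with the
#'   variances and all derived proportions.
#' @examples
#' # published melanoma-grade inputs
#' decompose_heritability(0.19, 0.27, 0.39,
#'   alpha_stx17 = -0.85, p_g = 0.85,
#'   alpha_asip = 0.19, p_a = 0.51)
#' @export
decompose_heritability <- function(v_poly, v_pe, v_e,
                                   alpha_stx17 = NULL, p_g = NULL,
                                   alpha_asip = NULL, p_a = NULL,
                                   v_p = NULL, trait = NA_character_) {
  for (v in c(v_poly, v_pe, v_e)) {
    if (!is.finite(v) || v < 0) {
      abort("variance components must be non-negative",
            class = "greyherit_error_config")
    }
  }
  v_stx17 <- if (is.null(alpha_stx17)) 0 else {
    locus_variance(alpha_stx17, p_g)
  }
  v_asip <- if (is.null(alpha_asip)) 0 else {
    locus_variance(alpha_asip, p_a)
  }
  v_sum <- v_poly + v_stx17 + v_asip + v_pe + v_e
  v_p_used <- v_p %||% v_sum
  if (!is.finite(v_p_used) || v_p_used <= 0) {
    abort("phenotypic variance must be positive",
          class = "greyherit_error_config")
  }
  out <- tibble(
    trait = trait,
    v_poly = v_poly, v_stx17 = v_stx17, v_asip = v_asip,
    v_pe = v_pe, v_e = v_e, v_p = v_p_used,
    repeatability = (v_poly + v_stx17 + v_asip + v_pe) / v_p_used,
    c2 = v_pe / v_p_used,
    h2 = (v_poly + v_stx17 + v_asip) / v_p_used,
    h2_poly = v_poly / v_p_used,
    h2_stx17 = v_stx17 / v_p_used,
    h2_asip = v_asip / v_p_used
  )
  class(out) <- c("grey_decomposition", class(out))
  out
}

#' Decompose a fitted univariate animal model
#'
#' Convenience wrapper: takes the variance components of a `grey_fit`, the
#' fitted locus regression coefficients (substitution effects) and allele
#' frequencies counted from the analysed animals, and calls
#' [decompose_heritability()].
#'
#' @param fit A univariate `grey_fit`.
#' @param genotypes Genotype tibble used to count allele frequencies over
#'   the fitted animals (those with records).
#' @param p_g,p_a Optional frequency overrides; counted from `genotypes`
#'   when omitted.
#' @return A `grey_decomposition` tibble.
#' @export
decompose_fit <- function(fit, genotypes = NULL, p_g = NULL, p_a = NULL) {
  stopifnot(inherits(fit, "grey_fit"))
  if (length(fit$traits) != 1) {
    abort("decompose_fit expects a univariate fit",
          class = "greyherit_error_config")
  }
  comp <- fit$components
  v_poly <- comp$estimate[comp$component == "v_poly"]
  v_pe_v <- comp$estimate[comp$component == "v_pe"]
  v_pe_v <- if (length(v_pe_v)) v_pe_v else 0
  v_e <- comp$estimate[comp$component == "v_e"]
  recorded <- unique(fit$ebv$animal[fit$ebv$n_records > 0])
  alpha_stx <- fit$fixed$estimate[fit$fixed$term == "stx17"]
  alpha_asip <- fit$fixed$estimate[fit$fixed$term == "asip_add"]
  has_stx <- length(alpha_stx) == 1
  has_asip <- length(alpha_asip) == 1
  if (has_stx && is.null(p_g)) {
    p_g <- allele_frequencies(genotypes, "stx17", subset = recorded)$p
  }
  if (has_asip && is.null(p_a)) {
    p_a <- allele_frequencies(genotypes, "asip", subset = recorded)$p
  }
  decompose_heritability(
    v_poly = v_poly, v_pe = v_pe_v, v_e = v_e,
    alpha_stx17 = if (has_stx) alpha_stx else NULL, p_g = p_g,
    alpha_asip = if (has_asip) alpha_asip else NULL, p_a = p_a,
    trait = fit$traits
  )
}

#' Compose a phenotypic correlation from its parts
#'
#' `r_P = r_POLY sqrt(h2_1 h2_2) + r_e sqrt((1 - h2_1)(1 - h2_2))`:
#' the phenotypic correlation implied by the polygenic correlation, the
#' environmental (residual) correlation and the two heritabilities.
#'
#' @param r_poly,r_e Correlations in `[-1, 1]`.
#' @param h2_1,h2_2 Heritabilities in `[0, 1]`.
#' @return The phenotypic correlation.
#' @export
compose_phenotypic_correlation <- function(r_poly, r_e, h2_1, h2_2) {
  if (any(abs(c(r_poly, r_e)) > 1)) {
    abort("correlations must lie in [-1, 1]",
          class = "greyherit_error_config")
  }
  if (any(c(h2_1, h2_2) < 0) || any(c(h2_1, h2_2) > 1)) {
    abort("heritabilities must lie in [0, 1]",
          class = "greyherit_error_config")
  }
  r_poly * sqrt(h2_1 * h2_2) + r_e * sqrt((1 - h2_1) * (1 - h2_2))
}

# Half-up rounding used for report tables (R's round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
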