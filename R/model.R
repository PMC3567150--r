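#' Build design structures for one trait
#'
#' Assembles the response, fixed-effect design matrix and the
#' record-to-animal incidence for a single trait's repeated-records animal
#' model. Fixed effects are a stud-by-sex-by-year class (built from
#' whichever of the class columns are present), an age covariate in years
#' (months / 12, so coefficients are per year), and optional major-locus
#' covariates: the STX17 indicator (GG = 0, Gg = 1), the ASIP additive code
#' (AA = 0, Aa = 1, aa = 2) and the ASIP dominance code (AA = 0, Aa = 1,
#' aa = 0). Records whose animal lacks a required genotype are dropped and
#' counted. The class part of the design is reduced to full column rank by
#' QR-based reparameterization (covariate estimates are invariant to this);
#' a covariate that is confounded or constant raises an error naming the
#' term.
#'
#' @param records Phenotype tibble with columns `animal`, `value`,
#'   `age_months` and optionally `trait`, `stud`, `sex`, `year`.
#' @param ped A `grey_pedigree`; every recorded animal must appear in it.
#' @param trait If `records` holds several traits, which one to use.
#' @param genotypes Genotype tibble; required when a locus covariate is on.
#' @param age,stx17,asip,asip_dom Switches for the covariates.
#' @param class_terms Columns combined into the fixed class effect.
#' @return A list of class `grey_design`: `y`, `X` (full column rank),
#'   `animal` (ids), `trait`, `n`, `n_dropped`, `covariates`, `records`.
#' @export
build_design <- function(records, ped, trait = NULL, genotypes = NULL,
                         age = TRUE, stx17 = FALSE, asip = FALSE,
                         asip_dom = FALSE,
                         class_terms = c("stud", "sex", "year")) {
  stopifnot(inherits(ped, "grey_pedigree"))
  rec <- as_tibble(records)
  if (!is.null(trait) && "trait" %in% names(rec)) {
    rec <- rec[rec$trait == trait, ]
  }
  trait <- trait %||% (if ("trait" %in% names(rec)) rec$trait[1] else "trait")
  if (!nrow(rec)) {
    abort(paste0("no records for trait ", trait),
          class = "greyherit_error_empty")
  }
  rec$animal <- as.character(rec$animal)
  missing_ped <- setdiff(rec$animal, ped$id)
  if (length(missing_ped)) {
    abort(paste0("recorded animal not in pedigree: ", missing_ped[1]),
          class = "greyherit_error_id")
  }

  n_dropped <- 0L
  covs <- list()
  if (stx17 || asip || asip_dom) {
    if (is.null(genotypes)) {
      abort("genotypes are required for locus covariates",
            class = "greyherit_error_config")
    }
    gt <- as_tibble(genotypes)
    gidx <- match(rec$animal, gt$id)
    if (stx17) covs$stx17 <- stx17_code(gt$stx17[gidx])
    if (asip) covs$asip_add <- asip_additive_code(gt$asip[gidx])
    if (asip_dom) covs$asip_dom <- asip_dominance_code(gt$asip[gidx])
    keep <- rep(TRUE, nrow(rec))
    for (v in covs) keep <- keep & !is.na(v)
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      inform(paste0(n_dropped, " record(s) dropped for missing genotypes (",
                    trait, ")"))
      rec <- rec[keep, ]
      covs <- lapply(covs, function(v) v[keep])
    }
    if (!nrow(rec)) {
      abort("all records dropped for missing genotypes",
            class = "greyherit_error_empty")
    }
  }
  if (age) {
    if (!"age_months" %in% names(rec)) {
      abort("records need an age_months column",
            class = "greyherit_error_columns")
    }
    covs <- c(list(age_years = rec$age_months / 12), covs)
  }

  present <- intersect(class_terms, names(rec))
  if (length(present)) {
    cls <- interaction(rec[present], drop = TRUE, sep = ":")
    Xc <- model.matrix(~cls)
    colnames(Xc) <- c("(Intercept)",
                      paste0("class", levels(cls)[-1]))
  } else {
    Xc <- matrix(1, nrow(rec), 1, dimnames = list(NULL, "(Intercept)"))
  }
  for (nm in names(covs)) {
    v <- covs[[nm]]
    if (length(unique(v)) < 2) {
      abort(paste0("covariate ", nm, " has fewer than 2 distinct values ",
                   "(confounded or constant)"),
            class = "greyherit_error_rank")
    }
  }
  X <- cbind(Xc, do.call(cbind, covs))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep_cols <- sort(qrx$pivot[seq_len(qrx$rank)])
    dropped <- colnames(X)[-keep_cols]
    bad <- intersect(dropped, names(covs))
    if (length(bad)) {
      abort(paste0("covariate confounded with other fixed effects: ",
                   paste(bad, collapse = ", ")),
            class = "greyherit_error_rank")
    }
    X <- X[, keep_cols, drop = FALSE]
  }

  structure(list(
    y = as.numeric(rec$value), X = X, animal = rec$animal, trait = trait,
    n = nrow(rec), n_dropped = n_dropped, covariates = names(covs),
    records = rec
  ), class = "grey_design")
}
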