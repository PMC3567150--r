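STX_LEVELS <- c("GG", "Gg", "gg")
ASIP_LEVELS <- c("AA", "Aa", "aa")
SOURCE_LEVELS <- c("measured", "deduced", "unknown")

# Genotype index convention per biallelic locus: 1 = two reference alleles
# (GG / AA), 2 = heterozygote, 3 = zero reference alleles (gg / aa).

# compat3[c, s, d]: can a child of genotype index c be produced by parents
# of genotype indices s and d (one allele drawn from each)? An unknown
# parent is simply an unconstrained one (any of the 3 genotypes), so no
# separate case is needed.
genotype_compat_tables <- function() {
  contrib <- list(`1` = 1L, `2` = c(1L, 0L), `3` = 0L)  # ref alleles passed
  counts <- c(2L, 1L, 0L)                               # ref alleles carried
  compat3 <- array(FALSE, c(3, 3, 3))
  for (ci in 1:3) {
    for (s in 1:3) {
      for (d in 1:3) {
        pairs <- expand.grid(a = contrib[[s]], b = contrib[[d]])
        compat3[ci, s, d] <- any(pairs$a + pairs$b == counts[ci])
      }
    }
  }
  compat3
}

# Bitmask lookup tables over candidate sets (mask 1..7 encodes a non-empty
# subset of the three genotype indices). For a trio, child_tab[c,s,d] is the
# reduced child mask; par_tab[s,c,o] the reduced mask of one parent given
# the child mask c and the other parent's mask o.
deduction_tables <- function() {
  compat3 <- genotype_compat_tables()
  bits <- function(m) which(bitwAnd(m, c(1L, 2L, 4L)) > 0L)
  child_tab <- array(0L, c(7, 7, 7))
  par_tab <- array(0L, c(7, 7, 7))
  for (cm in 1:7) {
    for (sm in 1:7) {
      for (om in 1:7) {
        keep_c <- 0L
        for (ci in bits(cm)) {
          if (any(compat3[ci, bits(sm), bits(om)])) {
            keep_c <- bitwOr(keep_c, bitwShiftL(1L, ci - 1L))
          }
        }
        child_tab[cm, sm, om] <- keep_c
        keep_p <- 0L
        for (si in bits(sm)) {
          if (any(compat3[bits(cm), si, bits(om)])) {
            keep_p <- bitwOr(keep_p, bitwShiftL(1L, si - 1L))
          }
        }
        par_tab[sm, cm, om] <- keep_p
      }
    }
  }
  list(child = child_tab, parent = par_tab)
}

.greyherit_tables <- new.env(parent = emptyenv())

get_deduction_tables <- function() {
  if (is.null(.greyherit_tables$tabs)) {
    .greyherit_tables$tabs <- deduction_tables()
  }
  .greyherit_tables$tabs
}

mask_of <- function(idx) bitwShiftL(1L, idx - 1L)
is_singleton <- function(m) m %in% c(1L, 2L, 4L)
singleton_idx <- function(m) match(m, c(1L, 2L, 4L))

# Arc-consistency fixed point over parent-offspring trios for one locus.
# Monotone (masks only shrink) hence order-independent and idempotent.
# With `quiet = TRUE` a Mendelian conflict returns NULL instead of
# raising (used for assume-and-propagate candidate testing).
propagate_locus <- function(si, di, mask, ids, locus, quiet = FALSE) {
  tabs <- get_deduction_tables()
  children <- which(!is.na(si) | !is.na(di))
  fail <- function(i, s, d) {
    if (quiet) return(NULL)
    deduction_conflict(ids, i, s, d, locus)
  }
  repeat {
    changed <- FALSE
    for (i in children) {
      s <- si[i]
      d <- di[i]
      sm <- if (is.na(s)) 7L else mask[s]
      dm <- if (is.na(d)) 7L else mask[d]
      cm <- mask[i]
      new_c <- tabs$child[cm, sm, dm]
      if (new_c == 0L) {
        return(fail(i, s, d))
      }
      if (new_c != cm) {
        mask[i] <- new_c
        cm <- new_c
        changed <- TRUE
      }
      if (!is.na(s)) {
        new_s <- tabs$parent[sm, cm, dm]
        if (new_s == 0L) return(fail(i, s, d))
        if (new_s != sm) {
          mask[s] <- new_s
          sm <- new_s
          changed <- TRUE
        }
      }
      if (!is.na(d)) {
        new_d <- tabs$parent[dm, cm, sm]
        if (new_d == 0L) return(fail(i, s, d))
        if (new_d != dm) {
          mask[d] <- new_d
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  mask
}

# Assume-and-propagate refinement on top of arc consistency: every
# remaining candidate genotype is tentatively asserted and discarded if
# propagation then reaches a Mendelian contradiction somewhere in the
# pedigree. This captures eliminations that flow through a mate or around
# pedigree loops, which trio-local propagation alone can miss; candidates
# that survive are left in place, so the step only ever shrinks candidate
# sets (deduction stays conservative: a genotype is called only when a
# single candidate remains).
refine_locus <- function(si, di, mask, ids, locus) {
  mask <- propagate_locus(si, di, mask, ids, locus)
  repeat {
    changed <- FALSE
    for (i in seq_along(mask)) {
      m <- mask[i]
      if (is_singleton(m)) next
      for (b in c(1L, 2L, 4L)) {
        if (bitwAnd(m, b) == 0L) next
        trial <- mask
        trial[i] <- b
        res <- propagate_locus(si, di, trial, ids, locus, quiet = TRUE)
        if (is.null(res)) {
          m <- bitwAnd(m, bitwNot(b))
          mask[i] <- m
          changed <- TRUE
          # a contradiction with every candidate would have surfaced in
          # the initial propagation; re-propagate with the reduced set
          mask <- propagate_locus(si, di, mask, ids, locus)
          m <- mask[i]
        }
      }
    }
    if (!changed) break
  }
  mask
}

deduction_conflict <- function(ids, i, s, d, locus) {
  abort(paste0(
    "Mendelian inconsistency at ", locus, " for trio: child ", ids[i],
    ", sire ", if (is.na(s)) "<unknown>" else ids[s],
    ", dam ", if (is.na(d)) "<unknown>" else ids[d]
  ), class = "greyherit_error_mendelian")
}

#' Deduce genotypes from coat colour and pedigree
#'
#' Extends measured STX17 and ASIP genotypes by constraint propagation over
#' the pedigree, iterated to a fixed point:
#' a coloured (non-grey) animal is `gg`; a grey parent with at least one
#' coloured offspring must be `Gg`; a grey animal with a `gg` parent must be
#' `Gg`; and, generally, any genotype that is Mendelian-incompatible with
#' the remaining candidate genotypes of an animal's parents and offspring is
#' eliminated (this generic elimination is the only rule applied at ASIP,
#' where coat colour is uninformative). Animals whose candidate set is not
#' reduced to a single genotype stay unknown. Deduced entries are flagged
#' `"deduced"` and never overwrite measured ones; an inconsistency between
#' measured genotypes, colour and Mendelian inheritance raises an error
#' naming the trio.
#'
#' The propagation is monotone (candidate sets only shrink), so the result
#' is order-independent and re-running it on its own output changes nothing.
#'
#' @param ped A `grey_pedigree`.
#' @param colour Optional tibble `id`, `colour` with values `"grey"`,
#'   `"coloured"` or `"unknown"`; constrains STX17 only (grey = G carrier,
#'   coloured = `gg`).
#' @param measured Optional genotype tibble with columns `id`, `stx17`,
#'   `asip` (values `"GG"/"Gg"/"gg"`, `"AA"/"Aa"/"aa"`, `NA` = untyped).
#' @return A tibble `id, stx17, asip, stx17_source, asip_source` covering
#'   every pedigree animal, with sources in
#'   `"measured"`, `"deduced"`, `"unknown"`.
#' @export
deduce_genotypes <- function(ped, colour = NULL, measured = NULL) {
  stopifnot(inherits(ped, "grey_pedigree"))
  n <- nrow(ped)
  pi <- parent_index(ped)
  ids <- ped$id

  init_mask <- function(levels, meas_vals) {
    mask <- rep(7L, n)
    src <- rep("unknown", n)
    if (!is.null(meas_vals)) {
      idx <- match(meas_vals$id, ids)
      bad <- is.na(idx)
      if (any(bad)) {
        abort(paste0("genotyped animal not in pedigree: ",
                     meas_vals$id[bad][1]),
              class = "greyherit_error_id")
      }
      g <- match(meas_vals$g, levels)
      keep <- !is.na(g)
      mask[idx[keep]] <- mask_of(g[keep])
      src[idx[keep]] <- "measured"
    }
    list(mask = mask, src = src)
  }

  meas_stx <- NULL
  meas_asip <- NULL
  if (!is.null(measured)) {
    measured <- as_tibble(measured)
    if ("stx17" %in% names(measured)) {
      meas_stx <- tibble(id = as.character(measured$id), g = measured$stx17)
    }
    if ("asip" %in% names(measured)) {
      meas_asip <- tibble(id = as.character(measured$id), g = measured$asip)
    }
  }

  stx <- init_mask(STX_LEVELS, meas_stx)
  asip <- init_mask(ASIP_LEVELS, meas_asip)

  if (!is.null(colour)) {
    colour <- as_tibble(colour)
    idx <- match(as.character(colour$id), ids)
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (is.na(i)) next
      cl <- colour$colour[k]
      constraint <- if (identical(cl, "grey")) {
        3L  # {GG, Gg}
      } else if (identical(cl, "coloured")) {
        4L  # {gg}
      } else {
        7L
      }
      new_mask <- bitwAnd(stx$mask[i], constraint)
      if (new_mask == 0L) {
        abort(paste0("coat colour of ", ids[i],
                     " contradicts its measured STX17 genotype"),
              class = "greyherit_error_mendelian")
      }
      stx$mask[i] <- new_mask
    }
  }

  stx$mask <- refine_locus(pi$sire, pi$dam, stx$mask, ids, "STX17")
  asip$mask <- refine_locus(pi$sire, pi$dam, asip$mask, ids, "ASIP")

  finish <- function(state, levels) {
    g <- rep(NA_character_, n)
    src <- state$src
    single <- is_singleton(state$mask)
    g[single] <- levels[singleton_idx(state$mask[single])]
    newly <- single & src != "measured"
    src[newly] <- "deduced"
    src[!single] <- "unknown"
    list(g = g, src = src)
  }
  s <- finish(stx, STX_LEVELS)
  a <- finish(asip, ASIP_LEVELS)
  tibble(id = ids, stx17 = s$g, asip = a$g,
         stx17_source = s$src, asip_source = a$src)
}

#' Allele frequencies by counting
#'
#' Counts alleles over the animals with a known genotype at the locus,
#' optionally restricted to a subset: `p = (2 n_hom_ref + n_het) /
#' (2 n_known)` where the reference allele is G for STX17 and A for ASIP.
#'
#' @param genotypes Genotype tibble (as from [deduce_genotypes()] or
#'   [drop_genotypes()]).
#' @param locus `"stx17"` or `"asip"`.
#' @param subset Optional character vector of animal ids.
#' @param sources Which provenance classes to count (default measured +
#'   deduced).
#' @return A one-row tibble `locus, p, q, n_counted`.
#' @export
allele_frequencies <- function(genotypes, locus = c("stx17", "asip"),
                               subset = NULL,
                               sources = c("measured", "deduced")) {
  locus <- match.arg(locus)
  gt <- as_tibble(genotypes)
  if (!is.null(subset)) gt <- gt[gt$id %in% subset, ]
  src_col <- paste0(locus, "_source")
  if (src_col %in% names(gt)) gt <- gt[gt[[src_col]] %in% sources, ]
  levels <- if (locus == "stx17") STX_LEVELS else ASIP_LEVELS
  g <- match(gt[[locus]], levels)
  g <- g[!is.na(g)]
  if (!length(g)) {
    abort(paste0("no known ", locus, " genotypes in the requested subset"),
          class = "greyherit_error_empty")
  }
  n_ref <- sum(g == 1) * 2L + sum(g == 2)
  p <- n_ref / (2 * length(g))
  tibble(locus = locus, p = p, q = 1 - p, n_counted = length(g))
}

#' Read / write genotype and colour CSVs
#'
#' Genotype dialect: `id,stx17,asip,stx17_source,asip_source`; colour
#' dialect: `id,colour` with `grey`/`coloured`/`unknown`. Empty genotype
#' fields mean untyped.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_genotypes <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!"id" %in% names(x)) {
    abort("genotype file needs an id column", class = "greyherit_error_columns")
  }
  for (col in c("stx17", "asip")) {
    if (col %in% names(x)) x[[col]][x[[col]] %in% c("", "NA")] <- NA_character_
  }
  x
}

#' @rdname read_genotypes
#' @param genotypes Genotype tibble.
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_csv(as_tibble(genotypes), path, progress = FALSE, na = "")
  invisible(path)
}

# Genotype string -> covariate codes used in the animal model.
stx17_code <- function(g) c(GG = 0, Gg = 1, gg = NA_real_)[g]
asip_additive_code <- function(g) c(AA = 0, Aa = 1, aa = 2)[g]
asip_dominance_code <- function(g) c(AA = 0, Aa = 1, aa = 0)[g]
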