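#' Validate and order a pedigree
#'
#' Checks a pedigree data frame (columns `id`, `sire`, `dam`, optionally
#' `sex` and `birth_year`) and returns it sorted in topological order:
#' every parent's row precedes all of its offspring's rows. Ties are broken
#' by input order, so the result is reproducible. Missing parents may be
#' encoded as `NA`, the empty string or `"0"`; all are treated as unknown,
#' and an animal with both parents unknown is a founder. A parent id that is
#' referenced but has no record of its own is, by default, added as a
#' founder with a warning.
#'
#' @param x A data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`"M"`, `"F"` or unknown) and `birth_year`. Extra columns are
#'   kept.
#' @param undefined_parents Either `"add"` (default; auto-add referenced but
#'   undefined parents as founders, with a warning) or `"error"`.
#' @param quiet Suppress the auto-add warning.
#'
#' @return A tibble of class `grey_pedigree`, in topological order, with
#'   character `id`/`sire`/`dam` (`NA` for unknown parents), a normalised
#'   `sex` column and a `birth_year` column.
#'
#' @examples
#' ped <- as_pedigree(data.frame(
#'   id = c("s", "d", "x"), sire = c(NA, NA, "s"), dam = c(NA, NA, "d")
#' ))
#' inbreeding(ped)
#' @export
as_pedigree <- function(x, undefined_parents = c("add", "error"),
                        quiet = FALSE) {
  undefined_parents <- match.arg(undefined_parents)
  x <- as_tibble(x)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(x))) {
    abort(paste0("pedigree needs columns ", paste(need, collapse = ", ")),
          class = "greyherit_error_columns")
  }
  blank_to_na <- function(v) {
    v <- trimws(as.character(v))
    v[v %in% c("", "0", "NA")] <- NA_character_
    v
  }
  x$id <- trimws(as.character(x$id))
  x$sire <- blank_to_na(x$sire)
  x$dam <- blank_to_na(x$dam)
  if (anyNA(x$id) || any(x$id == "")) {
    abort("pedigree ids must be non-missing", class = "greyherit_error_id")
  }
  if (anyDuplicated(x$id)) {
    dup <- x$id[duplicated(x$id)][1]
    abort(paste0("duplicate pedigree id: ", dup),
          class = "greyherit_error_duplicate")
  }
  self <- which(x$id == x$sire | x$id == x$dam)
  if (length(self)) {
    abort(paste0("animal is its own parent: ", x$id[self[1]]),
          class = "greyherit_error_cycle")
  }
  referenced <- setdiff(stats::na.omit(c(x$sire, x$dam)), x$id)
  if (length(referenced)) {
    if (undefined_parents == "error") {
      abort(paste0("parent referenced but not defined: ",
                   paste(head(referenced, 5), collapse = ", ")),
            class = "greyherit_error_undefined_parent")
    }
    if (!quiet) {
      warn(paste0(length(referenced),
                  " referenced parent(s) added as founders"))
    }
    add <- x[rep(1, length(referenced)), ]
    add[] <- lapply(add, function(col) rep(NA, length(referenced)))
    add$id <- referenced
    x <- bind_rows(add, x)
  }
  if (!"sex" %in% names(x)) x$sex <- NA_character_
  x$sex <- normalise_sex(x$sex)
  if (!"birth_year" %in% names(x)) x$birth_year <- NA_integer_

  ord <- topological_order(x$id, x$sire, x$dam)
  x <- x[ord, ]
  class(x) <- c("grey_pedigree", class(tibble()))
  x
}

normalise_sex <- function(sex) {
  sex <- toupper(trimws(as.character(sex)))
  out <- rep("unknown", length(sex))
  out[sex %in% c("M", "MALE", "1")] <- "M"
  out[sex %in% c("F", "FEMALE", "2")] <- "F"
  out
}

# Kahn-style layering; all animals whose parents are already placed are
# appended in input order, which both breaks ties deterministically and
# detects cycles (no placeable animal left => a cycle exists).
topological_order <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  placed <- logical(n)
  sire_ok <- is.na(si)
  dam_ok <- is.na(di)
  ord <- integer(0)
  while (length(ord) < n) {
    sire_ok <- sire_ok | (!is.na(si) & placed[ifelse(is.na(si), 1L, si)])
    dam_ok <- dam_ok | (!is.na(di) & placed[ifelse(is.na(di), 1L, di)])
    ready <- which(!placed & sire_ok & dam_ok)
    if (!length(ready)) {
      cyc <- find_cycle_member(which(!placed), si, di, placed)
      abort(paste0("pedigree contains a cycle involving animal: ", id[cyc]),
            class = "greyherit_error_cycle")
    }
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  ord
}

# Walk parent pointers among unplaced animals until an index repeats;
# that index lies on a cycle.
find_cycle_member <- function(remaining, si, di, placed) {
  seen <- integer(0)
  cur <- remaining[1]
  repeat {
    if (cur %in% seen) return(cur)
    seen <- c(seen, cur)
    nxt <- c(si[cur], di[cur])
    nxt <- nxt[!is.na(nxt) & !placed[nxt]]
    cur <- nxt[1]
  }
}

#' Read / write a pedigree CSV
#'
#' The pedigree dialect is a comma-separated UTF-8 file with header columns
#' `id,sire,dam,sex,birth_year` (`sex` and `birth_year` optional). Unknown
#' parents are the empty field or `"0"`.
#'
#' @param path File path.
#' @inheritParams as_pedigree
#' @return `read_pedigree()` returns a validated [as_pedigree()] tibble.
#' @export
read_pedigree <- function(path, undefined_parents = c("add", "error"),
                          quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "greyherit_error_io")
  }
  x <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if ("birth_year" %in% names(x)) {
    x$birth_year <- suppressWarnings(as.integer(x$birth_year))
  }
  as_pedigree(x, undefined_parents = undefined_parents, quiet = quiet)
}

#' @rdname read_pedigree
#' @param ped A `grey_pedigree`.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "grey_pedigree"))
  out <- ped[, intersect(c("id", "sire", "dam", "sex", "birth_year"),
                         names(ped))]
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

parent_index <- function(ped) {
  list(sire = match(ped$sire, ped$id), dam = match(ped$dam, ped$id))
}

#' Inbreeding coefficients
#'
#' Computes each animal's inbreeding coefficient F by the L-row trace
#' method: the pedigree decomposition A = L D L' gives the self-relationship
#' a_ii = sum_k L_ik^2 d_k = 1 + F_i, where L_ik is the expected fraction of
#' animal i's genome derived from ancestor k and d_k is k's
#' Mendelian-sampling variance. Founders (and animals with an unknown
#' parent) have F = 0. This path is independent of the tabular relationship
#' matrix of [relationship_matrix()], which is used as a cross-check in the
#' package tests.
#'
#' @param ped A `grey_pedigree`.
#' @return A tibble with columns `id` and `f`.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "grey_pedigree"))
  pi <- parent_index(ped)
  tibble(id = ped$id, f = inbreeding_vector(pi$sire, pi$dam))
}

inbreeding_vector <- function(si, di) {
  n <- length(si)
  f <- numeric(n)
  dv <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    dv[i] <- mendelian_variance(s, d, f)
    if (is.na(s) || is.na(d)) {
      f[i] <- 0
      next
    }
    # ancestor closure of i
    anc <- logical(i)
    anc[i] <- TRUE
    frontier <- i
    while (length(frontier)) {
      par <- c(si[frontier], di[frontier])
      par <- unique(par[!is.na(par)])
      par <- par[!anc[par]]
      anc[par] <- TRUE
      frontier <- par
    }
    idx <- which(anc)            # ascending
    L <- numeric(i)
    L[i] <- 1
    for (k in rev(idx)) {        # descending: push shares to parents
      lk <- L[k]
      if (lk == 0) next
      if (!is.na(si[k])) L[si[k]] <- L[si[k]] + 0.5 * lk
      if (!is.na(di[k])) L[di[k]] <- L[di[k]] + 0.5 * lk
    }
    f[i] <- sum(L[idx]^2 * dv[idx]) - 1
  }
  f
}

mendelian_variance <- function(s, d, f) {
  if (!is.na(s) && !is.na(d)) {
    0.5 - 0.25 * (f[s] + f[d])
  } else if (!is.na(s)) {
    0.75 - 0.25 * f[s]
  } else if (!is.na(d)) {
    0.75 - 0.25 * f[d]
  } else {
    1
  }
}

#' Additive genetic relationship matrix A
#'
#' Builds the dense numerator relationship matrix by the tabular (recursive)
#' method over the topologically ordered pedigree: founders have
#' `a_ii = 1`; `a_ii = 1 + 0.5 a_{sd}` for offspring of `s` and `d`; and
#' `a_ij = 0.5 (a_{j,sire(i)} + a_{j,dam(i)})` for earlier animals `j`.
#' The diagonal equals `1 + F`. Dense storage is intended for pedigrees up
#' to a few thousand animals (the scale of a single studbook); the sparse
#' [relationship_inverse()] never forms A.
#'
#' @param ped A `grey_pedigree`.
#' @param max_n Guard against accidentally densifying a huge pedigree.
#' @return A symmetric dense matrix with the pedigree ids as dimnames.
#' @export
relationship_matrix <- function(ped, max_n = 8000L) {
  stopifnot(inherits(ped, "grey_pedigree"))
  n <- nrow(ped)
  if (n > max_n) {
    abort(paste0("pedigree too large for a dense A (", n, " > ", max_n, ")"),
          class = "greyherit_error_size")
  }
  pi <- parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- numeric(i - 1)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- if (!is.na(s) && !is.na(d)) 1 + 0.5 * A[s, d] else 1
  }
  A
}

#' Sparse inverse of the relationship matrix
#'
#' Forms A^-1 directly by Henderson's rules, accounting for inbreeding:
#' each animal contributes 1/d_i to its own diagonal, -1/(2 d_i) to
#' animal-parent pairs and 1/(4 d_i) to parent-parent pairs, where d_i is
#' the Mendelian-sampling variance (0.5 - 0.25 (F_s + F_d) with both
#' parents known, 0.75 - 0.25 F_p with one, 1 for founders).
#'
#' @param ped A `grey_pedigree`.
#' @param f Optional precomputed inbreeding coefficients (vector aligned
#'   with `ped`); computed via [inbreeding()] when omitted.
#' @return A sparse symmetric `dgCMatrix` with ids as dimnames.
#' @export
relationship_inverse <- function(ped, f = NULL) {
  pre <- pedigree_precompute(ped, f = f)
  pre$a_inv
}

# Shared precomputation for the mixed-model machinery: inbreeding,
# Mendelian-sampling variances, sparse A^-1 and log det A.
pedigree_precompute <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "grey_pedigree"))
  n <- nrow(ped)
  pi <- parent_index(ped)
  si <- pi$sire
  di <- pi$dam
  if (is.null(f)) f <- inbreeding_vector(si, di)
  dv <- vapply(seq_len(n), function(i) mendelian_variance(si[i], di[i], f),
               numeric(1))
  ii <- vector("list", n)
  jj <- vector("list", n)
  xx <- vector("list", n)
  for (i in seq_len(n)) {
    a <- 1 / dv[i]
    par <- c(si[i], di[i])
    par <- par[!is.na(par)]
    ri <- i
    ci <- i
    vi <- a
    if (length(par)) {
      ri <- c(ri, par, rep(i, length(par)))
      ci <- c(ci, rep(i, length(par)), par)
      vi <- c(vi, rep(-a / 2, 2 * length(par)))
      pp <- expand.grid(par, par)
      ri <- c(ri, pp[[1]])
      ci <- c(ci, pp[[2]])
      vi <- c(vi, rep(a / 4, nrow(pp)))
    }
    ii[[i]] <- ri
    jj[[i]] <- ci
    xx[[i]] <- vi
  }
  a_inv <- sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n, n), dimnames = list(ped$id, ped$id)
  )
  list(ped = ped, n = n, sire = si, dam = di, f = f, d = dv,
       a_inv = a_inv, logdet_a = sum(log(dv)))
}

#' @export
print.grey_pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat("<grey_pedigree> ", nrow(x), " animals (", founders,
      " founders), topologically ordered\n", sep = "")
  NextMethod()
}
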