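# Independent oracles used across the test suite. These deliberately avoid
# the package's mixed-model-equations code path: the REML criterion is
# evaluated through dense variance-matrix projections, and genotype
# deduction through exhaustive enumeration of all Mendelian-consistent
# assignments.

# Dense evaluation of the restricted log-likelihood
#   -0.5 [ (n - p) log 2pi + log|V| + log|X'V^-1X| + y'Py ]
# for stacked trait designs with V = Z (G0 x A) Z' + W (P0 x I) W' + R.
dense_reml_loglik <- function(designs, ped, g0, p0 = NULL, v_e) {
  if (inherits(designs, "grey_design")) designs <- list(designs)
  nt <- length(designs)
  G0 <- as.matrix(g0)
  A <- relationship_matrix(ped)
  q <- nrow(A)
  ids <- rownames(A)
  aidx <- lapply(designs, function(d) match(d$animal, ids))
  recset <- sort(unique(unlist(aidx)))
  m <- length(recset)
  n_t <- vapply(designs, function(d) d$n, 0L)
  n <- sum(n_t)

  Z <- matrix(0, n, nt * q)
  W <- matrix(0, n, nt * m)
  X <- matrix(0, n, sum(vapply(designs, function(d) ncol(d$X), 0L)))
  y <- numeric(n)
  Rdiag <- numeric(n)
  r0 <- 0L
  c0 <- 0L
  for (t in seq_len(nt)) {
    rows <- r0 + seq_len(n_t[t])
    Z[cbind(rows, (t - 1) * q + aidx[[t]])] <- 1
    W[cbind(rows, (t - 1) * m + match(aidx[[t]], recset))] <- 1
    X[rows, c0 + seq_len(ncol(designs[[t]]$X))] <- designs[[t]]$X
    y[rows] <- designs[[t]]$y
    Rdiag[rows] <- v_e[t]
    r0 <- r0 + n_t[t]
    c0 <- c0 + ncol(designs[[t]]$X)
  }
  G <- kronecker(G0, A)
  V <- Z %*% G %*% t(Z) + diag(Rdiag, n)
  if (!is.null(p0)) {
    P0 <- as.matrix(p0)
    V <- V + W %*% kronecker(P0, diag(m)) %*% t(W)
  }
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  as.numeric(
    -0.5 * ((n - ncol(X)) * log(2 * pi) +
              determinant(V, logarithm = TRUE)$modulus +
              determinant(XtVX, logarithm = TRUE)$modulus +
              t(y) %*% P %*% y)
  )
}

# Exhaustive-enumeration deduction oracle for one locus on a small
# pedigree: enumerate every assignment of the 3 genotypes to all animals,
# keep those consistent with Mendelian inheritance and the given
# constraints, and call an animal's genotype forced iff all consistent
# assignments agree on it. Constraints: `known` (named genotype indices,
# 1 = hom-ref, 2 = het, 3 = hom-alt) and, for STX17, `grey` (named logical:
# TRUE = carries >= 1 reference allele, FALSE = hom-alt).
enumerate_deduction <- function(ped, known = integer(0), grey = NULL) {
  n <- nrow(ped)
  stopifnot(n <= 9)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  pass <- list(`1` = 1L, `2` = c(1L, 0L), `3` = 0L)
  counts <- c(2L, 1L, 0L)
  ok_trio <- function(c, s, d) {
    any(outer(pass[[s]], pass[[d]], `+`) == counts[c])
  }
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  keep <- rep(TRUE, nrow(grid))
  for (nm in names(known)) {
    keep <- keep & grid[, match(nm, ped$id)] == known[[nm]]
  }
  if (!is.null(grey)) {
    for (nm in names(grey)) {
      col <- grid[, match(nm, ped$id)]
      keep <- keep & if (grey[[nm]]) col != 3 else col == 3
    }
  }
  grid <- grid[keep, , drop = FALSE]
  ok <- apply(grid, 1, function(g) {
    for (i in seq_len(n)) {
      s <- if (is.na(si[i])) NULL else g[si[i]]
      d <- if (is.na(di[i])) NULL else g[di[i]]
      if (!is.null(s) && !is.null(d)) {
        if (!ok_trio(g[i], s, d)) return(FALSE)
      } else if (!is.null(s)) {
        if (!any(vapply(1:3, function(dd) ok_trio(g[i], s, dd), TRUE))) {
          return(FALSE)
        }
      } else if (!is.null(d)) {
        if (!any(vapply(1:3, function(ss) ok_trio(g[i], ss, d), TRUE))) {
          return(FALSE)
        }
      }
    }
    TRUE
  })
  grid <- grid[ok, , drop = FALSE]
  if (!nrow(grid)) return(NULL)  # inconsistent constraints
  forced <- apply(grid, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1) u else NA_integer_
  })
  stats::setNames(as.integer(forced), ped$id)
}

# Small random pedigree: founders plus randomly mated later animals,
# single-parent records allowed.
random_toy_pedigree <- function(n, seed, p_single = 0.15) {
  withr::with_seed(seed, {
    ids <- paste0("a", seq_len(n))
    sire <- rep(NA_character_, n)
    dam <- rep(NA_character_, n)
    n_found <- max(2, ceiling(n / 3))
    for (i in (n_found + 1):n) {
      if (i > n) break
      prev <- seq_len(i - 1)
      pick <- sample(prev, min(2, length(prev)))
      sire[i] <- ids[pick[1]]
      if (length(pick) > 1 && runif(1) > p_single) dam[i] <- ids[pick[2]]
    }
    as_pedigree(data.frame(id = ids, sire = sire, dam = dam), quiet = TRUE)
  })
}

# Tiny simulated dataset (pedigree + records + design) for oracle tests.
tiny_dataset <- function(seed, n_animals = 8, with_loci = FALSE) {
  withr::with_seed(seed, {
    des <- study_design(
      n_founders = 4, n_generations = 2, n_per_generation = n_animals - 4,
      n_measured = n_animals, mean_records = 2, years = 2000:2002,
      n_studs = 2
    )
    cfg <- default_trait_configs()$melanoma
    st <- simulate_study(cfg, des, seed = seed)
    d <- tryCatch(
      build_design(st$phenotypes, st$pedigree, trait = "melanoma",
                   genotypes = st$genotypes,
                   stx17 = with_loci, asip = with_loci),
      greyherit_error_rank = function(e) {
        # a tiny draw can lack genotype variation; use the plain design
        build_design(st$phenotypes, st$pedigree, trait = "melanoma")
      }
    )
    list(study = st, design = d)
  })
}
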