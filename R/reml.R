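# Average-information REML for univariate and bivariate repeated-records
# animal models, solved through the mixed-model equations (MME).
#
# Model per trait t:  y_t = X_t b_t + Z_t a_t + W_t pe_t + e_t
#   Var(a)  = G0 (x) A      (polygenic, pedigree covariance)
#   Var(pe) = P0 (x) I_m    (permanent environment over recorded animals)
#   Var(e)  = diag(v_e_t)   (residual; no residual covariance across traits,
#                            records of different traits are never paired)
#
# The restricted log-likelihood, its score and the average-information
# matrix are all obtained from one Cholesky factorisation of the MME
# coefficient matrix per iteration, using the standard identities
#   log|V| + log|X'V^-1 X| = log|C| + log|G| + log|R|
#   tr(P Z M Z')           = tr(M (G^-1 - G^-1 C^uu G^-1))
# with C^uu the random-effect block of C^-1.

mme_precompute <- function(designs, ped_pre, pe = TRUE) {
  nt <- length(designs)
  q <- ped_pre$n
  ids <- ped_pre$ped$id
  p_t <- vapply(designs, function(d) ncol(d$X), 0L)
  n_t <- vapply(designs, function(d) d$n, 0L)
  p_tot <- sum(p_t)
  n_tot <- sum(n_t)

  rec_aidx <- lapply(designs, function(d) match(d$animal, ids))
  rec_set <- sort(unique(unlist(rec_aidx)))
  m <- if (pe) length(rec_set) else 0L

  dim_tot <- p_tot + nt * q + nt * m
  a_off <- p_tot
  pe_off <- p_tot + nt * q

  # sparse stacked design T = [X | Z | W]
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  row0 <- 0L
  p0 <- 0L
  rows_t <- vector("list", nt)
  rec_trait <- integer(n_tot)
  rec_widx <- integer(n_tot)
  rec_animal_global <- integer(n_tot)
  for (t in seq_len(nt)) {
    d <- designs[[t]]
    rows <- row0 + seq_len(n_t[t])
    rows_t[[t]] <- rows
    rec_trait[rows] <- t
    X <- d$X
    nz <- which(X != 0, arr.ind = TRUE)
    trip_i[[length(trip_i) + 1L]] <- row0 + nz[, 1]
    trip_j[[length(trip_j) + 1L]] <- p0 + nz[, 2]
    trip_x[[length(trip_x) + 1L]] <- X[nz]
    aidx <- rec_aidx[[t]]
    rec_animal_global[rows] <- aidx
    trip_i[[length(trip_i) + 1L]] <- rows
    trip_j[[length(trip_j) + 1L]] <- a_off + (t - 1L) * q + aidx
    trip_x[[length(trip_x) + 1L]] <- rep(1, n_t[t])
    if (pe) {
      widx <- match(aidx, rec_set)
      rec_widx[rows] <- widx
      trip_i[[length(trip_i) + 1L]] <- rows
      trip_j[[length(trip_j) + 1L]] <- pe_off + (t - 1L) * m + widx
      trip_x[[length(trip_x) + 1L]] <- rep(1, n_t[t])
    }
    row0 <- row0 + n_t[t]
    p0 <- p0 + p_t[t]
  }
  Tmat <- sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(n_tot, dim_tot))
  y <- unlist(lapply(designs, `[[`, "y"), use.names = FALSE)

  TtT <- vector("list", nt)
  Tty <- vector("list", nt)
  TtT_trip <- vector("list", nt)
  for (t in seq_len(nt)) {
    Tt <- Tmat[rows_t[[t]], , drop = FALSE]
    M <- methods::as(Matrix::crossprod(Tt), "generalMatrix")
    M <- methods::as(M, "TsparseMatrix")
    TtT[[t]] <- M
    TtT_trip[[t]] <- list(i = M@i + 1L, j = M@j + 1L, x = M@x,
                          lin = (as.numeric(M@j)) * dim_tot + M@i + 1)
    Tty[[t]] <- as.numeric(Matrix::crossprod(Tt, y[rows_t[[t]]]))
  }

  ainv <- methods::as(methods::as(ped_pre$a_inv, "generalMatrix"),
                      "TsparseMatrix")
  a_dense <- as.matrix(ped_pre$a_inv)

  list(
    nt = nt, q = q, m = m, p_t = p_t, n_t = n_t, p_tot = p_tot,
    n_tot = n_tot, dim = dim_tot, a_off = a_off, pe_off = pe_off,
    pe = pe, rows_t = rows_t, rec_trait = rec_trait,
    rec_animal = rec_animal_global, rec_widx = rec_widx, rec_set = rec_set,
    Tmat = Tmat, y = y, yty = vapply(seq_len(nt), function(t) {
      sum(y[rows_t[[t]]]^2)
    }, 0),
    TtT = TtT, TtT_trip = TtT_trip, Tty = Tty,
    ainv_trip = list(i = ainv@i + 1L, j = ainv@j + 1L, x = ainv@x),
    ainv = ped_pre$a_inv, ainv_dense = a_dense,
    logdet_a = ped_pre$logdet_a, f = ped_pre$f,
    ids = ids, traits = vapply(designs, `[[`, "", "trait"),
    designs = designs
  )
}

theta_pack <- function(G0, P0, E, pe) {
  nt <- length(E)
  out <- list()
  lab <- character(0)
  for (i in seq_len(nt)) {
    for (j in seq_len(i)) {
      out <- c(out, G0[i, j])
      lab <- c(lab, paste0("g", i, j))
    }
  }
  if (pe) {
    for (i in seq_len(nt)) {
      for (j in seq_len(i)) {
        out <- c(out, P0[i, j])
        lab <- c(lab, paste0("p", i, j))
      }
    }
  }
  out <- c(out, E)
  lab <- c(lab, paste0("e", seq_len(nt)))
  setNames(unlist(out), lab)
}

theta_unpack <- function(theta, nt, pe) {
  k <- 1L
  G0 <- matrix(0, nt, nt)
  for (i in seq_len(nt)) {
    for (j in seq_len(i)) {
      G0[i, j] <- G0[j, i] <- theta[k]
      k <- k + 1L
    }
  }
  P0 <- matrix(0, nt, nt)
  if (pe) {
    for (i in seq_len(nt)) {
      for (j in seq_len(i)) {
        P0[i, j] <- P0[j, i] <- theta[k]
        k <- k + 1L
      }
    }
  }
  E <- theta[k:(k + nt - 1L)]
  list(G0 = G0, P0 = P0, E = unname(E))
}

# Clamp a covariance matrix to the valid region: diagonal at least `bound`,
# correlations at most 0.999 in magnitude, PSD via eigenvalue clipping.
sanitize_cov <- function(M, bound) {
  d <- pmax(diag(M), bound)
  nt <- nrow(M)
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i != j) {
        lim <- 0.999 * sqrt(d[i] * d[j])
        M[i, j] <- sign(M[i, j]) * pmin(abs(M[i, j]), lim)
      }
    }
  }
  diag(M) <- d
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(eg$values) <= 0) {
    vals <- pmax(eg$values, 1e-10 * max(eg$values))
    M <- eg$vectors %*% (vals * t(eg$vectors))
    diag(M) <- pmax(diag(M), bound)
  }
  (M + t(M)) / 2
}

cov_valid <- function(M, bound) {
  if (any(diag(M) < bound)) return(FALSE)
  nt <- nrow(M)
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i != j && abs(M[i, j]) >= 0.9995 * sqrt(M[i, i] * M[j, j])) {
        return(FALSE)
      }
    }
  }
  min(eigen((M + t(M)) / 2, symmetric = TRUE,
            only.values = TRUE)$values) > 0
}

# One evaluation of the REML criterion at (G0, P0, E); optionally also the
# score, average-information matrix and EM update targets.
mme_eval <- function(pre, G0, P0, E, derivs = TRUE) {
  nt <- pre$nt
  q <- pre$q
  m <- pre$m
  dim <- pre$dim
  G0inv <- solve(G0)
  P0inv <- if (pre$pe) solve(P0) else NULL

  C <- matrix(0, dim, dim)
  for (t in seq_len(nt)) {
    tr <- pre$TtT_trip[[t]]
    C[cbind(tr$i, tr$j)] <- C[cbind(tr$i, tr$j)] + tr$x / E[t]
  }
  at <- pre$ainv_trip
  for (s in seq_len(nt)) {
    for (t in seq_len(nt)) {
      rows <- pre$a_off + (s - 1L) * q
      cols <- pre$a_off + (t - 1L) * q
      C[cbind(rows + at$i, cols + at$j)] <-
        C[cbind(rows + at$i, cols + at$j)] + G0inv[s, t] * at$x
    }
  }
  if (pre$pe) {
    dseq <- seq_len(m)
    for (s in seq_len(nt)) {
      for (t in seq_len(nt)) {
        rows <- pre$pe_off + (s - 1L) * m + dseq
        cols <- pre$pe_off + (t - 1L) * m + dseq
        C[cbind(rows, cols)] <- C[cbind(rows, cols)] + P0inv[s, t]
      }
    }
  }

  Ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(Ch)) {
    Ch <- chol(C + diag(1e-8 * max(diag(C)), dim))
  }
  rhs <- numeric(dim)
  for (t in seq_len(nt)) rhs <- rhs + pre$Tty[[t]] / E[t]
  sol <- backsolve(Ch, backsolve(Ch, rhs, transpose = TRUE))

  ypy <- sum(pre$yty / E) - sum(sol * rhs)
  logdet_c <- 2 * sum(log(diag(Ch)))
  logdet_g <- q * determinant(G0, logarithm = TRUE)$modulus +
    nt * pre$logdet_a +
    if (pre$pe) m * determinant(P0, logarithm = TRUE)$modulus else 0
  logl <- -0.5 * ((pre$n_tot - pre$p_tot) * log(2 * pi) +
                    sum(pre$n_t * log(E)) + as.numeric(logdet_g) +
                    logdet_c + ypy)

  out <- list(logL = as.numeric(logl), sol = sol, Ch = Ch)
  if (!derivs) return(out)

  Cinv <- chol2inv(Ch)
  umat <- matrix(sol[pre$a_off + seq_len(nt * q)], q, nt)
  pemat <- if (pre$pe) {
    matrix(sol[pre$pe_off + seq_len(nt * m)], m, nt)
  } else NULL
  ehat <- pre$y - as.numeric(pre$Tmat %*% sol)
  E_rec <- E[pre$rec_trait]
  Py <- ehat / E_rec

  # trace building blocks from the selected entries of C^-1
  Kg <- matrix(0, nt, nt)
  for (s in seq_len(nt)) {
    for (t in seq_len(s)) {
      lin <- (pre$a_off + (t - 1) * q + at$j - 1) * dim +
        (pre$a_off + (s - 1) * q + at$i)
      Kg[s, t] <- Kg[t, s] <- sum(at$x * Cinv[lin])
    }
  }
  Kp <- matrix(0, nt, nt)
  if (pre$pe) {
    dseq <- seq_len(m)
    for (s in seq_len(nt)) {
      for (t in seq_len(s)) {
        lin <- (pre$pe_off + (t - 1) * m + dseq - 1) * dim +
          (pre$pe_off + (s - 1) * m + dseq)
        Kp[s, t] <- Kp[t, s] <- sum(Cinv[lin])
      }
    }
  }
  tr_cinv_ttt <- vapply(seq_len(nt), function(t) {
    tr <- pre$TtT_trip[[t]]
    sum(tr$x * Cinv[tr$lin])
  }, 0)

  # EM targets
  Au <- as.matrix(pre$ainv %*% umat)
  G0em <- (crossprod(umat, Au) + Kg) / q
  P0em <- if (pre$pe) (crossprod(pemat) + Kp) / m else NULL
  Eem <- vapply(seq_len(nt), function(t) {
    (sum(ehat[pre$rows_t[[t]]]^2) + tr_cinv_ttt[t]) / pre$n_t[t]
  }, 0)

  # parameter list in theta_pack order
  par_list <- list()
  for (i in seq_len(nt)) {
    for (j in seq_len(i)) par_list <- c(par_list, list(c("g", i, j)))
  }
  if (pre$pe) {
    for (i in seq_len(nt)) {
      for (j in seq_len(i)) par_list <- c(par_list, list(c("p", i, j)))
    }
  }
  for (t in seq_len(nt)) par_list <- c(par_list, list(c("e", t, t)))
  K <- length(par_list)

  eij <- function(i, j, nt) {
    M <- matrix(0, nt, nt)
    M[i, j] <- M[i, j] + 1
    M[j, i] <- M[j, i] + 1
    if (i == j) M[i, j] <- 1
    M
  }

  Fmat <- matrix(0, pre$n_tot, K)
  tr_pv <- numeric(K)
  for (k in seq_len(K)) {
    p <- par_list[[k]]
    i <- as.integer(p[2])
    j <- as.integer(p[3])
    if (p[1] == "g") {
      M <- eij(i, j, nt)
      gmat <- umat %*% t(M %*% G0inv)
      Fmat[, k] <- gmat[cbind(pre$rec_animal, pre$rec_trait)]
      tr_pv[k] <- q * sum(diag(M %*% G0inv)) -
        sum((G0inv %*% M %*% G0inv) * Kg)
    } else if (p[1] == "p") {
      M <- eij(i, j, nt)
      pmat2 <- pemat %*% t(M %*% P0inv)
      Fmat[, k] <- pmat2[cbind(pre$rec_widx, pre$rec_trait)]
      tr_pv[k] <- m * sum(diag(M %*% P0inv)) -
        sum((P0inv %*% M %*% P0inv) * Kp)
    } else {
      rows <- pre$rows_t[[i]]
      Fmat[rows, k] <- ehat[rows] / E[i]
      tr_pv[k] <- pre$n_t[i] / E[i] - tr_cinv_ttt[i] / E[i]^2
    }
  }

  rhs_f <- as.matrix(Matrix::crossprod(pre$Tmat, Fmat / E_rec))
  Zk <- backsolve(Ch, backsolve(Ch, rhs_f, transpose = TRUE))
  PF <- (Fmat - as.matrix(pre$Tmat %*% Zk)) / E_rec
  AI <- 0.5 * crossprod(Fmat, PF)
  AI <- (AI + t(AI)) / 2
  score <- -0.5 * (tr_pv - as.numeric(crossprod(Fmat, Py)))

  c(out, list(
    Cinv = Cinv, umat = umat, pemat = pemat, ehat = ehat,
    G0em = G0em, P0em = P0em, Eem = Eem,
    AI = AI, score = score, par_list = par_list
  ))
}

reml_engine <- function(pre, init = NULL, tol = 1e-6, rel_tol = 1e-5,
                        max_iter = 200L, bound_frac = 1e-8,
                        pe_cov = TRUE, verbose = FALSE) {
  nt <- pre$nt
  vp0 <- vapply(seq_len(nt), function(t) var(pre$y[pre$rows_t[[t]]]), 0)
  bounds <- bound_frac * vp0
  # parameters held fixed at zero (permanent-environment covariance when
  # pe_cov = FALSE)
  theta0 <- theta_pack(diag(nt), diag(nt), rep(1, nt), pre$pe)
  fix <- rep(FALSE, length(theta0))
  if (pre$pe && !pe_cov && nt > 1) {
    fix <- grepl("^p", names(theta0)) &
      !names(theta0) %in% paste0("p", seq_len(nt), seq_len(nt))
  }
  zero_pe_cov <- function(M) {
    if (pre$pe && !pe_cov && nt > 1) {
      d <- diag(M)
      M[] <- 0
      diag(M) <- d
    }
    M
  }

  if (is.null(init)) {
    G0 <- diag(0.3 * vp0, nt)
    P0 <- diag(0.2 * vp0, nt)
    E <- 0.5 * vp0
  } else {
    G0 <- as.matrix(init$g0)
    P0 <- if (!is.null(init$p0)) as.matrix(init$p0) else diag(0.2 * vp0, nt)
    E <- init$v_e %||% (0.5 * vp0)
  }
  bmat <- function(M) sanitize_cov(M, min(bounds))
  G0 <- bmat(G0)
  if (pre$pe) P0 <- zero_pe_cov(bmat(P0))
  E <- pmax(E, bounds)

  trace <- list()
  prev <- NULL
  last_step <- "init"
  converged <- FALSE
  n_iter <- 0L

  for (it in seq_len(max_iter)) {
    n_iter <- it
    ev <- mme_eval(pre, G0, P0, E, derivs = TRUE)
    if (!is.null(prev) && last_step == "AI" &&
        ev$logL < prev$logL - 1e-8) {
      # AI overshoot: restart this step from the previous point with EM
      G0 <- prev$em$G0
      P0 <- prev$em$P0
      E <- prev$em$E
      last_step <- "EM"
      ev <- mme_eval(pre, G0, P0, E, derivs = TRUE)
    }
    theta <- theta_pack(G0, P0, E, pre$pe)
    trace[[it]] <- c(iter = it,
                     step = if (last_step == "init") 0 else
                       if (last_step == "AI") 1 else 2,
                     logL = ev$logL, theta)
    if (verbose) {
      inform(sprintf("iter %d (%s): logL = %.6f", it, last_step, ev$logL))
    }
    if (!is.null(prev)) {
      d_logl <- abs(ev$logL - prev$logL)
      d_par <- max(abs(theta - prev$theta) /
                     pmax(abs(prev$theta), 1e-6 * max(vp0)))
      if (d_logl < tol && d_par < rel_tol) {
        converged <- TRUE
        final <- ev
        break
      }
    }
    em <- list(
      G0 = sanitize_cov(ev$G0em, min(bounds)),
      P0 = if (pre$pe) zero_pe_cov(sanitize_cov(ev$P0em, min(bounds)))
           else P0,
      E = pmax(ev$Eem, bounds)
    )
    prev <- list(logL = ev$logL, theta = theta, em = em)
    free <- !fix
    step_ai <- tryCatch(
      solve(ev$AI[free, free, drop = FALSE], ev$score[free]),
      error = function(e) NULL
    )
    accepted <- FALSE
    if (!is.null(step_ai) && all(is.finite(step_ai))) {
      # damped AI steps, projected onto the parameter space (variances at
      # their lower bounds, covariance matrices PSD); accept the first
      # damping factor that does not decrease the restricted likelihood
      for (kappa in c(1, 0.5, 0.25, 0.1)) {
        cand <- theta
        cand[free] <- cand[free] + kappa * step_ai
        un <- theta_unpack(cand, nt, pre$pe)
        G0c <- sanitize_cov(un$G0, min(bounds))
        P0c <- if (pre$pe) zero_pe_cov(sanitize_cov(un$P0, min(bounds)))
               else P0
        Ec <- pmax(un$E, bounds)
        if (!all(is.finite(G0c)) || !all(is.finite(Ec)) ||
            (pre$pe && !all(is.finite(P0c)))) next
        ll_cand <- tryCatch(
          mme_eval(pre, G0c, P0c, Ec, derivs = FALSE)$logL,
          error = function(e) -Inf
        )
        if (is.finite(ll_cand) && ll_cand >= ev$logL - 1e-10) {
          G0 <- G0c
          P0 <- P0c
          E <- Ec
          last_step <- "AI"
          accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) {
      G0 <- em$G0
      P0 <- em$P0
      E <- em$E
      last_step <- "EM"
    }
    final <- ev
  }

  trace_df <- as_tibble(do.call(rbind, trace))
  if (!converged) {
    abort(
      paste0("REML did not converge in ", max_iter, " iterations"),
      class = "greyherit_error_convergence",
      trace_data = trace_df
    )
  }

  free <- !fix
  cov_theta <- matrix(0, length(fix), length(fix),
                      dimnames = list(names(theta0), names(theta0)))
  cov_free <- tryCatch(
    solve(final$AI[free, free, drop = FALSE]),
    error = function(e) matrix(NA_real_, sum(free), sum(free))
  )
  cov_theta[free, free] <- cov_free
  list(G0 = G0, P0 = P0, E = E, eval = final, trace = trace_df,
       converged = converged, iterations = n_iter,
       cov_theta = cov_theta, bounds = bounds)
}

#' Restricted log-likelihood of an animal model at fixed components
#'
#' Evaluates the REML criterion (including its normalising constant) for
#' given variance components through the mixed-model equations. Intended
#' for validation: an independent dense evaluation of
#' `-0.5 [(n - p) log 2 pi + log|V| + log|X'V^-1 X| + y'Py]`
#' must agree with this value.
#'
#' @param designs A `grey_design` or list of them (one per trait).
#' @param ped The `grey_pedigree` the designs refer to.
#' @param g0 Polygenic variance (scalar) or covariance matrix.
#' @param p0 Permanent-environment variance/covariance, or `NULL` to omit
#'   the permanent-environment term.
#' @param v_e Residual variance(s), one per trait.
#' @return The restricted log-likelihood (numeric scalar).
#' @export
reml_loglik <- function(designs, ped, g0, p0 = NULL, v_e) {
  if (inherits(designs, "grey_design")) designs <- list(designs)
  nt <- length(designs)
  pe <- !is.null(p0)
  pre <- mme_precompute(designs, pedigree_precompute(ped), pe = pe)
  G0 <- as.matrix(g0)
  P0 <- if (pe) as.matrix(p0) else matrix(0, nt, nt)
  mme_eval(pre, G0, P0, as.numeric(v_e), derivs = FALSE)$logL
}

#' Fit a repeated-records animal model by AI-REML
#'
#' Estimates variance components, fixed effects and breeding values for one
#' trait (univariate) or a pair of traits (bivariate) with a pedigree-based
#' additive effect, an optional permanent-environment effect for repeated
#' records, and trait-specific residuals. Updates use the
#' average-information algorithm with expectation-maximisation fallback
#' whenever an AI step leaves the parameter space or decreases the
#' restricted likelihood; variance components are bounded below at
#' `bound_frac` times the phenotypic variance so the equations stay
#' non-singular. In bivariate models the residual covariance is fixed at
#' zero (records of two traits are never paired observations here, e.g.
#' grey level is recorded for young horses, the other traits for old ones);
#' the polygenic and permanent-environment covariances are estimated.
#'
#' @param records Phenotype tibble (`animal`, `trait`, `value`,
#'   `age_months`, `stud`, `sex`, `year`).
#' @param ped A `grey_pedigree` containing every recorded animal.
#' @param traits Character vector of one or two trait names (must match
#'   `records$trait`).
#' @param genotypes Genotype tibble, required when locus covariates are on.
#' @param stx17,asip,asip_dom Logical switches (recycled per trait) for the
#'   major-locus covariates.
#' @param age Include the age-in-years covariate.
#' @param class_terms Columns combined into the fixed class effect.
#' @param pe Include the permanent-environment term.
#' @param pe_cov For bivariate fits, estimate the permanent-environment
#'   covariance (if `FALSE` it is fixed at zero by dropping the off-diagonal
#'   from every update).
#' @param init Optional list with `g0`, `p0`, `v_e` starting values.
#' @param tol Convergence tolerance on the change in restricted
#'   log-likelihood.
#' @param rel_tol Convergence tolerance on the maximum relative parameter
#'   change.
#' @param max_iter Iteration cap; exceeding it is an error carrying the
#'   iteration trace.
#' @param bound_frac Lower bound for variance components, as a fraction of
#'   the trait's phenotypic variance.
#' @param verbose Print the iteration trace.
#' @return An object of class `grey_fit`; see [tidy.grey_fit()],
#'   [glance.grey_fit()], [predict_ebv()].
#' @export
fit_animal_model <- function(records, ped, traits, genotypes = NULL,
                             stx17 = FALSE, asip = FALSE, asip_dom = FALSE,
                             age = TRUE,
                             class_terms = c("stud", "sex", "year"),
                             pe = TRUE, pe_cov = TRUE, init = NULL,
                             tol = 1e-6, rel_tol = 1e-5, max_iter = 200L,
                             bound_frac = 1e-8, verbose = FALSE) {
  nt <- length(traits)
  if (nt > 2) {
    abort("at most two traits are supported (bivariate analysis)",
          class = "greyherit_error_config")
  }
  stx17 <- rep_len(stx17, nt)
  asip <- rep_len(asip, nt)
  asip_dom <- rep_len(asip_dom, nt)
  designs <- lapply(seq_len(nt), function(t) {
    build_design(records, ped, trait = traits[t], genotypes = genotypes,
                 age = age, stx17 = stx17[t], asip = asip[t],
                 asip_dom = asip_dom[t], class_terms = class_terms)
  })
  ped_pre <- pedigree_precompute(ped)
  pre <- mme_precompute(designs, ped_pre, pe = pe)
  res <- reml_engine(pre, init = init, tol = tol, rel_tol = rel_tol,
                     max_iter = max_iter, bound_frac = bound_frac,
                     pe_cov = pe_cov, verbose = verbose)
  assemble_fit(pre, res, ped_pre)
}

assemble_fit <- function(pre, res, ped_pre) {
  nt <- pre$nt
  traits <- pre$traits
  ev <- res$eval
  theta <- theta_pack(res$G0, res$P0, res$E, pre$pe)
  se_theta <- sqrt(pmax(diag(res$cov_theta), 0))
  names(se_theta) <- names(theta)

  comp_rows <- list()
  for (i in seq_len(nt)) {
    for (j in seq_len(i)) {
      nm <- paste0("g", i, j)
      comp_rows[[length(comp_rows) + 1L]] <- tibble(
        component = if (i == j) "v_poly" else "cov_poly",
        trait_1 = traits[i], trait_2 = traits[j],
        estimate = res$G0[i, j], se = se_theta[nm]
      )
    }
  }
  if (pre$pe) {
    for (i in seq_len(nt)) {
      for (j in seq_len(i)) {
        nm <- paste0("p", i, j)
        comp_rows[[length(comp_rows) + 1L]] <- tibble(
          component = if (i == j) "v_pe" else "cov_pe",
          trait_1 = traits[i], trait_2 = traits[j],
          estimate = res$P0[i, j], se = se_theta[nm]
        )
      }
    }
  }
  for (t in seq_len(nt)) {
    comp_rows[[length(comp_rows) + 1L]] <- tibble(
      component = "v_e", trait_1 = traits[t], trait_2 = traits[t],
      estimate = res$E[t], se = se_theta[paste0("e", t)]
    )
  }
  components <- bind_rows(comp_rows)

  # fixed effects with SEs from the fixed block of C^-1
  fixed <- list()
  p0 <- 0L
  for (t in seq_len(nt)) {
    d <- pre$designs[[t]]
    idx <- p0 + seq_len(ncol(d$X))
    est <- res$eval$sol[idx]
    se <- sqrt(pmax(diag(ev$Cinv)[idx], 0))
    fixed[[t]] <- tibble(trait = traits[t], term = colnames(d$X),
                         estimate = est, se = se)
    p0 <- p0 + ncol(d$X)
  }
  fixed <- bind_rows(fixed)

  # EBVs, prediction-error variances and reliabilities
  q <- pre$q
  ebv <- list()
  nrec <- table(factor(pre$rec_animal, levels = seq_len(q)))
  for (t in seq_len(nt)) {
    idx <- pre$a_off + (t - 1L) * q + seq_len(q)
    pev <- pmax(diag(ev$Cinv)[idx], 0)
    denom <- res$G0[t, t] * (1 + pre$f)
    ebv[[t]] <- tibble(
      trait = traits[t], animal = pre$ids,
      ebv = ev$umat[, t], pev = pev,
      reliability = pmax(0, pmin(1, 1 - pev / denom)),
      n_records = as.integer(nrec)
    )
  }
  ebv <- bind_rows(ebv)

  r_poly <- NULL
  if (nt == 2) {
    r <- res$G0[2, 1] / sqrt(res$G0[1, 1] * res$G0[2, 2])
    grad <- c(g11 = -r / (2 * res$G0[1, 1]),
              g21 = 1 / sqrt(res$G0[1, 1] * res$G0[2, 2]),
              g22 = -r / (2 * res$G0[2, 2]))
    gi <- match(c("g11", "g21", "g22"), names(theta))
    vr <- as.numeric(t(grad) %*% res$cov_theta[gi, gi] %*% grad)
    r_poly <- tibble(trait_1 = traits[1], trait_2 = traits[2],
                     r_poly = r, se = sqrt(max(vr, 0)))
  }

  structure(list(
    traits = traits, components = components, fixed = fixed, ebv = ebv,
    g0 = res$G0, p0 = if (pre$pe) res$P0 else NULL, v_e = res$E,
    r_poly = r_poly, logL = ev$logL, converged = res$converged,
    iterations = res$iterations, trace = res$trace,
    cov_theta = res$cov_theta, theta = theta, se_theta = se_theta,
    n_records = pre$n_t, n_fixed = pre$p_tot,
    n_animals = length(unique(pre$rec_animal)),
    n_dropped = vapply(pre$designs, `[[`, 0L, "n_dropped"),
    f = tibble(id = pre$ids, f = pre$f)
  ), class = "grey_fit")
}

#' @export
print.grey_fit <- function(x, ...) {
  cat("<grey_fit> ", paste(x$traits, collapse = " + "), ": ",
      sum(x$n_records), " records on ", x$n_animals, " animals; logL = ",
      sprintf("%.3f", x$logL), " (", x$iterations, " iterations)\n",
      sep = "")
  print(x$components)
  if (!is.null(x$r_poly)) {
    cat(sprintf("polygenic correlation: %.3f (SE %.3f)\n",
                x$r_poly$r_poly, x$r_poly$se))
  }
  invisible(x)
}
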