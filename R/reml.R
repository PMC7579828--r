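# Average-information REML for the mixed models in this package.
#
# The engine works on the mixed-model equations (MME) throughout: one
# sparse Cholesky factorization per iteration provides solutions, the
# restricted log-likelihood, and (via multi-right-hand-side solves) the
# inverse-coefficient blocks needed for first derivatives, EM updates and
# prediction error variances. The average-information matrix is built
# from working vectors (derivatives of V applied to Py), each requiring
# one extra solve against the already-factorized system. When an AI step
# proposes an out-of-bounds parameter set (a non-PD covariance block or a
# non-positive residual variance), the iteration falls back to the
# always-admissible EM update.

# vectorize the free parameters: vech of each term's Gamma, then
# residual variances
theta_pack <- function(gammas, var_e) {
  unlist(c(lapply(gammas, function(g) g[lower.tri(g, diag = TRUE)]),
           list(var_e)))
}

theta_unpack <- function(theta, template, n_trait) {
  gammas <- list()
  pos <- 0L
  for (g in template) {
    t_ <- nrow(g)
    m <- matrix(0, t_, t_)
    nv <- t_ * (t_ + 1L) / 2L
    m[lower.tri(m, diag = TRUE)] <- theta[pos + seq_len(nv)]
    m <- m + t(m) - diag(diag(m), t_)
    dimnames(m) <- dimnames(g)
    gammas[[length(gammas) + 1L]] <- m
    pos <- pos + nv
  }
  list(gammas = gammas, var_e = theta[pos + seq_len(n_trait)])
}

theta_admissible <- function(par, floor_frac = 1e-8) {
  ok_g <- all(vapply(par$gammas, function(g) {
    ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
    min(ev) > floor_frac * max(abs(ev), 1e-12)
  }, TRUE))
  ok_g && all(par$var_e > 0)
}

# log|K| per term, from its sparse precision matrix (0 for identity)
term_logdet_k <- function(tm) {
  if (is.null(tm$Kinv)) return(0)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(tm$Kinv), LDL = FALSE)
  -2 * as.numeric(determinant(ch, sqrt = TRUE)$modulus)
}

#' Estimate variance components by average-information REML
#'
#' Fits the mixed model described by an [build_mme()] system, updating
#' every free (co)variance parameter (per-term covariance blocks and
#' per-trait residual variances) by Newton steps on the restricted
#' likelihood with the average-information matrix as curvature, falling
#' back to EM when a step leaves the parameter space. Approximate
#' standard errors come from the inverse AI matrix at convergence.
#'
#' @param sys an [build_mme()] system (starting values are taken from the
#'   terms' `Gamma` and the system's `var_e`).
#' @param tol convergence tolerance on the relative parameter change.
#' @param max_iter maximum iterations.
#' @param verbose print the likelihood trajectory.
#' @param exact `TRUE` computes first derivatives from exact
#'   inverse-coefficient traces (and enables the EM fallback); `FALSE`
#'   differentiates the cheap restricted likelihood numerically, keeping
#'   the exact average-information curvature, which scales to much
#'   larger systems. Default (`NULL`) chooses by system size.
#' @param pev extract prediction error variances at convergence (one
#'   full inverse; disable for variance-component-only fits).
#' @return An object of class `reml_fit` with elements `gammas`, `var_e`,
#'   `theta`, `theta_vcov`, `logLik` (REML), `logLik_ml`, `n_params`,
#'   `solution` components, `pev` (prediction error variances per term
#'   component), `converged`, `iterations` and `trajectory`.
#' @export
reml_estimate <- function(sys, tol = 1e-8, max_iter = 200L,
                          verbose = FALSE, exact = NULL, pev = TRUE) {
  gammas <- lapply(sys$terms, `[[`, "Gamma")
  var_e <- sys$var_e
  par <- list(gammas = gammas, var_e = var_e)
  if (!theta_admissible(par))
    stop("starting values must be positive definite")
  exact <- exact %||% (sys$n_eq <= 3000L)
  logdet_k <- vapply(sys$terms, term_logdet_k, 0)
  trajectory <- data.frame(iter = integer(), logLik = numeric(),
                           step = character())
  state <- NULL
  conv <- FALSE
  ll_prev <- -Inf
  ll_stall <- 0L
  cache <- new.env(parent = emptyenv())
  stalled <- FALSE
  for (it in seq_len(max_iter)) {
    state <- reml_iteration(sys, par, logdet_k, cache, exact = exact)
    step_kind <- "ai"
    theta <- theta_pack(par$gammas, par$var_e)
    new_par <- NULL
    # Newton step on the AI curvature, with step damping and
    # Levenberg-Marquardt ridging; candidates outside the parameter
    # space are bent onto the PD cone, and a candidate is accepted only
    # if it does not decrease the restricted likelihood (checked with a
    # cheap factorization). EM, which always ascends, is the fallback.
    for (ridge in c(0, 0.1, 1, 10)) {
      H <- state$AI + ridge * diag(pmax(diag(state$AI), 1e-12),
                                   nrow(state$AI))
      delta <- tryCatch(solve(H, state$score), error = function(e) NULL)
      if (is.null(delta)) next
      for (damp in c(1, 0.5, 0.1)) {
        cand <- theta_unpack(theta + damp * delta, par$gammas,
                             length(par$var_e))
        if (!theta_admissible(cand)) cand <- bend_parameters(cand)
        if (!theta_admissible(cand, floor_frac = 1e-10)) next
        ll_cand <- tryCatch(
          suppressWarnings(reml_loglik(sys, cand, logdet_k, cache)),
          error = function(e) -Inf)
        if (is.finite(ll_cand) && ll_cand >= state$logLik - 1e-10) {
          new_par <- cand
          break
        }
      }
      if (!is.null(new_par)) break
    }
    if (is.null(new_par)) {
      if (exact) {
        step_kind <- "em"
        new_par <- list(gammas = state$em_gammas, var_e = state$em_var_e)
        if (!theta_admissible(new_par, floor_frac = 0))
          new_par <- bend_parameters(new_par)
      } else {
        # no candidate improves the likelihood at ladder resolution:
        # the fast path treats this as (boundary) convergence
        step_kind <- "stall"
        new_par <- par
        stalled <- TRUE
      }
    }
    trajectory <- rbind(trajectory,
                        data.frame(iter = it, logLik = state$logLik,
                                   step = step_kind))
    if (verbose)
      message(sprintf("it %3d  logL %.6f  (%s)", it, state$logLik,
                      step_kind))
    new_theta <- theta_pack(new_par$gammas, new_par$var_e)
    # aggregate relative change, so components collapsing towards a
    # zero boundary cannot hold up convergence of the full vector
    rel <- sqrt(sum((new_theta - theta)^2) / max(sum(theta^2), 1e-12))
    # a stalled likelihood over several iterations signals a boundary
    # optimum that the parameter-change criterion cannot certify; the
    # large-system path uses a looser band because its quadratic steps
    # clear it in one or two iterations when the optimum is interior
    stall_band <- if (exact) 1e-7 else 3e-5
    ll_stall <- if (abs(state$logLik - ll_prev) <
                      stall_band * (1 + abs(state$logLik)))
      ll_stall + 1L else 0L
    ll_prev <- state$logLik
    par <- new_par
    if (rel < tol || ll_stall >= 4L || stalled) { conv <- TRUE; break }
  }
  if (!conv && max_iter > 1L) {
    cond <- simpleError(sprintf(
      "REML did not converge in %d iterations", max_iter))
    cond$trajectory <- trajectory
    stop(cond)
  }
  # refresh derived quantities at the converged parameter values
  state <- reml_iteration(sys, par, logdet_k, cache, final = TRUE,
                          exact = exact, want_pev = pev)
  vcov_theta <- tryCatch(solve(state$AI), error = function(e)
    matrix(NA_real_, length(state$score), length(state$score)))
  for (k in seq_along(par$gammas))
    dimnames(par$gammas[[k]]) <- dimnames(sys$terms[[k]]$Gamma)
  structure(list(gammas = par$gammas, var_e = par$var_e,
                 theta = theta_pack(par$gammas, par$var_e),
                 theta_vcov = vcov_theta,
                 logLik = state$logLik, logLik_ml = state$logLik_ml,
                 n_params = length(state$score),
                 solution = state$solution,
                 fixed = setNames(state$solution[seq_len(sys$p)],
                                  colnames(sys$X)),
                 random = extract_random(sys, state$solution),
                 pev = state$pev,
                 converged = conv, iterations = nrow(trajectory),
                 trajectory = trajectory, sys_p = sys$p, n = sys$n),
            class = "reml_fit")
}

# factorize the coefficient matrix, reusing the symbolic analysis held
# in `cache` when the pattern allows it
factorize_c <- function(C, cache = NULL) {
  if (!is.null(cache) && !is.null(cache$ch)) {
    ch <- tryCatch(suppressWarnings(stats::update(cache$ch, C)),
                   error = function(e) NULL)
    if (!is.null(ch)) return(ch)
  }
  ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  if (!is.null(cache)) cache$ch <- ch
  ch
}

# restricted log-likelihood only: one sparse factorization, no traces
reml_loglik <- function(sys, par, logdet_k, cache = NULL) {
  gammas <- par$gammas
  var_e <- par$var_e
  cm <- mme_coefficients(sys, gammas, var_e)
  ch <- factorize_c(cm$C, cache)
  sol <- as.numeric(Matrix::solve(ch, cm$rhs, system = "A"))
  yPy <- sum(sys$yy_t / var_e) - sum(sol * cm$rhs)
  logdet_c <- 2 * as.numeric(determinant(ch, sqrt = TRUE)$modulus)
  logdet_r <- sum(sys$n_t * log(var_e))
  logdet_g <- 0
  for (k in seq_along(sys$terms)) {
    tm <- sys$terms[[k]]
    logdet_g <- logdet_g + tm$q * as.numeric(determinant(
      gammas[[k]], logarithm = TRUE)$modulus) + tm$t * logdet_k[k]
  }
  -(logdet_c + logdet_r + logdet_g + yPy +
      (sys$n - sys$p) * log(2 * pi)) / 2
}

# one REML iteration at fixed parameters: factorize, solve, compute
# likelihoods, scores, AI matrix, EM updates and PEVs. With
# exact = FALSE the inverse-coefficient traces are skipped: the score
# comes from central differences of the restricted likelihood and no EM
# update is produced.
reml_iteration <- function(sys, par, logdet_k, cache = NULL,
                           final = FALSE, exact = TRUE,
                           want_pev = TRUE) {
  gammas <- par$gammas
  var_e <- par$var_e
  n_terms <- length(sys$terms)
  cm <- mme_coefficients(sys, gammas, var_e)
  ch <- factorize_c(cm$C, cache)
  sol <- as.numeric(Matrix::solve(ch, cm$rhs, system = "A"))
  yRy <- sum(sys$yy_t / var_e)
  yPy <- yRy - sum(sol * cm$rhs)
  logdet_c <- 2 * as.numeric(determinant(ch, sqrt = TRUE)$modulus)
  logdet_r <- sum(sys$n_t * log(var_e))
  logdet_g <- 0
  for (k in seq_len(n_terms)) {
    tm <- sys$terms[[k]]
    logdet_g <- logdet_g + tm$q * as.numeric(determinant(
      gammas[[k]], logarithm = TRUE)$modulus) + tm$t * logdet_k[k]
  }
  n <- sys$n; p <- sys$p
  m2ll <- logdet_c + logdet_r + logdet_g + yPy + (n - p) * log(2 * pi)
  logLik <- -m2ll / 2

  # ML profile likelihood needs the determinant of the random-only
  # block; only computed on the final pass
  rnd <- (p + 1L):sys$n_eq
  logLik_ml <- NA_real_
  if (final && length(rnd)) {
    ch_zz <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(
      cm$C[rnd, rnd, drop = FALSE]), LDL = FALSE),
      error = function(e) NULL)
    if (!is.null(ch_zz)) {
      logdet_zz <- 2 * as.numeric(Matrix::determinant(
        ch_zz, sqrt = TRUE)$modulus)
      logLik_ml <- -(n * log(2 * pi) + logdet_r + logdet_g +
                       logdet_zz + yPy) / 2
    }
  }

  # residual projections
  e_hat <- sys$y - as.numeric(sys$W %*% sol)
  Py <- e_hat / var_e[sys$trait]

  # full inverse of the coefficient matrix: needed for exact traces
  # (score, EM) and for prediction error variances
  need_s <- exact || (final && want_pev)
  S <- if (need_s)
    as.matrix(Matrix::solve(ch, diag(sys$n_eq), system = "A")) else NULL

  # per-term pieces: uhat, g = K Z'Py (via Gamma^-1 uhat), traces T
  score <- numeric(0)
  fvec <- list()        # working vectors for the AI matrix
  em_gammas <- vector("list", n_terms)
  pev <- list()
  for (k in seq_len(n_terms)) {
    tm <- sys$terms[[k]]
    t_ <- tm$t; q <- tm$q
    Gi <- solve(gammas[[k]])
    offs <- sys$offsets[[k]]
    uhat <- matrix(sol[unlist(lapply(offs, function(o) o + seq_len(q)))],
                   q, t_)
    gmat <- uhat %*% t(Gi)        # column c = K Z_c' Py
    if (exact) {
      # trace matrix T[c,d] = tr(Kinv %*% Cinv_block(c,d))
      Tm <- matrix(0, t_, t_)
      kin <- if (is.null(tm$Kinv)) NULL else
        methods::as(tm$Kinv, "TsparseMatrix")
      for (c_ in seq_len(t_)) for (d_ in c_:t_) {
        B <- S[offs[c_] + seq_len(q), offs[d_] + seq_len(q), drop = FALSE]
        Tm[c_, d_] <- Tm[d_, c_] <- if (is.null(kin)) sum(diag(B)) else
          sum(kin@x * B[cbind(kin@i + 1L, kin@j + 1L)])
      }
      # u' Kinv u across components
      UKU <- if (is.null(tm$Kinv)) crossprod(uhat) else
        crossprod(uhat, as.matrix(tm$Kinv %*% uhat))
      em_gammas[[k]] <- (UKU + Tm) / q
      dimnames(em_gammas[[k]]) <- dimnames(gammas[[k]])
      Smat <- q * Gi - Gi %*% Tm %*% Gi
      sPy <- matrix(0, q, t_)       # s_c = Z_c' Py
      for (c_ in seq_len(t_)) {
        map <- tm$components[[c_]]
        ok <- !is.na(map)
        sPy[, c_] <- as.numeric(tabulate_weighted(map[ok], Py[ok], q))
      }
      Qmat <- crossprod(sPy, gmat)  # Q[c,d] = s_c' K s_d
      Qmat <- (Qmat + t(Qmat)) / 2
    }
    # parameter order matches theta_pack: column-major lower triangle
    for (d_ in seq_len(t_)) for (c_ in d_:t_) {
      if (exact) {
        mult <- if (c_ == d_) 1 else 2
        score <- c(score, -0.5 * mult * (Smat[c_, d_] - Qmat[c_, d_]))
      }
      # working vector Z_c g_d + Z_d g_c
      f <- scatter_levels(tm$components[[c_]], gmat[, d_], sys$n)
      if (c_ != d_)
        f <- f + scatter_levels(tm$components[[d_]], gmat[, c_], sys$n)
      fvec[[length(fvec) + 1L]] <- f
    }
    # prediction error variances: diagonal of the inverse blocks
    if (final && want_pev)
      pev[[tm$label]] <- lapply(seq_len(t_), function(c_)
        setNames(diag(S)[offs[c_] + seq_len(q)], tm$levels))
  }

  # residual score and working vectors
  em_var_e <- numeric(length(var_e))
  for (t_ in seq_along(sys$tr_levels)) {
    rows <- sys$trait == sys$tr_levels[t_]
    yPPy <- sum(Py[rows]^2)
    if (exact) {
      Mt <- sys$Mg_t[[t_]]
      s_t <- sum(Mt$x * S[cbind(Mt$i, Mt$j)])
      trP <- sys$n_t[t_] / var_e[t_] - s_t / var_e[t_]^2
      score <- c(score, -0.5 * (trP - yPPy))
      em_var_e[t_] <- (sum(e_hat[rows]^2) + s_t) / sys$n_t[t_]
    }
    f <- numeric(sys$n); f[rows] <- Py[rows]
    fvec[[length(fvec) + 1L]] <- f
  }

  # fast path: score by central differences of the cheap restricted
  # likelihood (the AI curvature below stays exact)
  if (!exact) {
    theta <- theta_pack(gammas, var_e)
    typ <- theta_typical(gammas, var_e)
    score <- vapply(seq_along(theta), function(i) {
      h <- max(1e-6 * typ[i], 1e-9)
      up <- theta; up[i] <- up[i] + h
      dn <- theta; dn[i] <- dn[i] - h
      ll_up <- tryCatch(suppressWarnings(reml_loglik(
        sys, theta_unpack(up, gammas, length(var_e)), logdet_k, cache)),
        error = function(e) NA_real_)
      ll_dn <- tryCatch(suppressWarnings(reml_loglik(
        sys, theta_unpack(dn, gammas, length(var_e)), logdet_k, cache)),
        error = function(e) NA_real_)
      if (is.na(ll_up) || is.na(ll_dn)) return(0)
      (ll_up - ll_dn) / (2 * h)
    }, 0)
  }

  # average-information matrix: AI_ij = 0.5 f_i' P f_j
  Fm <- do.call(cbind, fvec)
  Rf <- Fm / var_e[sys$trait]
  rhs_f <- Matrix::crossprod(sys$W, Rf)
  sol_f <- as.matrix(Matrix::solve(ch, rhs_f, system = "A"))
  PF <- Rf - as.matrix(sys$W %*% sol_f) / var_e[sys$trait]
  AI <- 0.5 * crossprod(Fm, PF)
  AI <- (AI + t(AI)) / 2

  list(logLik = logLik, logLik_ml = logLik_ml, solution = sol,
       score = score, AI = AI, em_gammas = em_gammas,
       em_var_e = em_var_e, pev = if (length(pev)) pev else NULL)
}

# characteristic scale of each free parameter, for finite differencing
theta_typical <- function(gammas, var_e) {
  out <- numeric(0)
  for (g in gammas) {
    d <- diag(as.matrix(g))
    t_ <- length(d)
    for (d_ in seq_len(t_)) for (c_ in d_:t_)
      out <- c(out, sqrt(abs(d[c_] * d[d_])) + 1e-12)
  }
  c(out, abs(var_e) + 1e-12)
}

# sum w over levels: out[l] = sum of w where map == l
tabulate_weighted <- function(map, w, nlevels) {
  out <- numeric(nlevels)
  agg <- rowsum(w, map)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# expand level values back onto records (0 where the component is absent)
scatter_levels <- function(map, values, n) {
  out <- numeric(n)
  ok <- !is.na(map)
  out[ok] <- values[map[ok]]
  out
}

# eigenvalue bending onto the PD cone, for EM edge cases
bend_parameters <- function(par, floor_frac = 1e-6) {
  par$gammas <- lapply(par$gammas, function(g) {
    eg <- eigen(g, symmetric = TRUE)
    floor_v <- floor_frac * max(abs(eg$values), 1e-12)
    eg$vectors %*% diag(pmax(eg$values, floor_v),
                        nrow = length(eg$values)) %*% t(eg$vectors)
  })
  par$var_e <- pmax(par$var_e, 1e-10)
  par
}

#' Heritability and repeatability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)` and
#' `repeatability = (sigma2_a + sigma2_pe) / (sigma2_a + sigma2_pe +
#' sigma2_e)`, with delta-method standard errors from the asymptotic
#' covariance of the variance components when available.
#'
#' @param var_a,var_pe,var_e variance components (permanent environment
#'   may be 0).
#' @param vcov optional 3x3 asymptotic covariance of
#'   `(var_a, var_pe, var_e)`.
#' @return A list with `h2`, `repeatability`, and their standard errors
#'   (`NA` without a covariance matrix).
#' @export
genetic_parameters <- function(var_a, var_pe = 0, var_e, vcov = NULL) {
  var_a <- unname(var_a); var_pe <- unname(var_pe); var_e <- unname(var_e)
  tot <- var_a + var_pe + var_e
  if (tot <= 0) stop("total variance must be positive")
  h2 <- var_a / tot
  rep_ <- (var_a + var_pe) / tot
  se_h2 <- se_rep <- NA_real_
  if (!is.null(vcov) && !anyNA(vcov)) {
    grad_h2 <- c((tot - var_a), -var_a, -var_a) / tot^2
    grad_rep <- c(var_e, var_e, -(var_a + var_pe)) / tot^2
    se_h2 <- sqrt(drop(t(grad_h2) %*% vcov %*% grad_h2))
    se_rep <- sqrt(drop(t(grad_rep) %*% vcov %*% grad_rep))
  }
  list(h2 = h2, repeatability = rep_, se_h2 = se_h2,
       se_repeatability = se_rep)
}

#' Genetic correlation with a delta-method standard error
#'
#' @param Gamma 2x2 (or larger) genetic covariance block.
#' @param i,j component indices.
#' @param vcov_vech optional covariance of `vech(Gamma)` (column-major
#'   lower triangle) from the AI matrix.
#' @return list with `r_g` and `se`.
#' @export
genetic_correlation <- function(Gamma, i = 1L, j = 2L, vcov_vech = NULL) {
  v1 <- Gamma[i, i]; v2 <- Gamma[j, j]; cv <- Gamma[i, j]
  r <- cv / sqrt(v1 * v2)
  se <- NA_real_
  if (!is.null(vcov_vech) && !anyNA(vcov_vech)) {
    t_ <- nrow(Gamma)
    idx <- matrix(0L, t_, t_)
    idx[lower.tri(idx, diag = TRUE)] <- seq_len(t_ * (t_ + 1L) / 2L)
    idx <- pmax(idx, t(idx))
    sel <- c(idx[min(i, j), max(i, j)], idx[i, i], idx[j, j])
    grad <- c(1 / sqrt(v1 * v2), -r / (2 * v1), -r / (2 * v2))
    vc <- vcov_vech[sel, sel, drop = FALSE]
    se <- sqrt(drop(t(grad) %*% vc %*% grad))
  }
  list(r_g = r, se = se)
}
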