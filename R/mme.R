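#' Define a random term for the mixed-model equations
#'
#' A term groups one or more trait-components that share a level set and
#' a covariance source: e.g. a genetic term whose components are the two
#' fescue status-traits (levels = pedigree animals, covariance `H^-1` or
#' `A^-1`), or a permanent-environment term with identity covariance.
#' Component `c` maps each record to a level (or `NA` when the component
#' does not touch the record); the between-component covariance is the
#' term's (co)variance matrix `Gamma`, giving `Var(u) = Gamma %x% K`.
#'
#' @param label term name.
#' @param levels character vector of level ids (e.g. animal ids).
#' @param components named list of integer (or character) vectors, one
#'   per trait-component, each of record length, mapping record -> level.
#' @param Kinv sparse precision matrix of the levels (`A^-1`, `H^-1`), or
#'   `NULL` for identity.
#' @param Gamma starting (co)variance matrix across components.
#' @return An object of class `ran_term`.
#' @export
ran_term <- function(label, levels, components, Kinv = NULL, Gamma) {
  q <- length(levels)
  comp <- lapply(components, function(m) {
    if (is.character(m)) m <- match(m, levels)
    if (any(m < 1L | m > q, na.rm = TRUE))
      stop("component maps outside the level set in term ", label)
    as.integer(m)
  })
  if (!is.null(Kinv)) {
    stopifnot(nrow(Kinv) == q, ncol(Kinv) == q)
    Kinv <- methods::as(methods::as(Kinv, "CsparseMatrix"), "generalMatrix")
  }
  Gamma <- as.matrix(Gamma)
  stopifnot(nrow(Gamma) == length(comp), isSymmetric(unname(Gamma)))
  structure(list(label = label, levels = levels, components = comp,
                 Kinv = Kinv, Gamma = Gamma, t = length(comp), q = q),
            class = "ran_term")
}

# incidence matrix of one component
component_z <- function(map, n, q) {
  ok <- which(!is.na(map))
  Matrix::sparseMatrix(i = ok, j = map[ok], x = 1, dims = c(n, q))
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the coefficient matrix
#' `[X'R^-1 X, X'R^-1 Z; Z'R^-1 X, Z'R^-1 Z + Sigma^-1]` and right-hand
#' side for a (possibly multiple-trait) linear mixed model with
#' record-diagonal residual covariance. `Sigma^-1` is assembled per term
#' as `Gamma^-1 %x% Kinv`. Fixed-effect columns that are linearly
#' dependent are dropped (the usual first-level constraint comes from
#' treatment contrasts in the caller's design matrix).
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (dense or sparse).
#' @param terms list of [ran_term()] objects.
#' @param trait integer vector assigning each record to a residual class
#'   (trait); scalar 1 for univariate models.
#' @param var_e residual variance per trait.
#' @return An object of class `mme_system` holding the sparse coefficient
#'   matrix, right-hand side, design blocks and offsets.
#' @export
build_mme <- function(y, X, terms, trait = rep(1L, length(y)),
                      var_e = 1) {
  n <- length(y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y disagree on record count")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("dropping ", length(dropped),
            " dependent fixed-effect column(s): ",
            paste(head(dropped, 5L), collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  p <- ncol(X)
  Zs <- list()
  offsets <- list()
  off <- p
  for (k in seq_along(terms)) {
    tm <- terms[[k]]
    comp_off <- integer(tm$t)
    for (c_ in seq_len(tm$t)) {
      Zs[[length(Zs) + 1L]] <- component_z(tm$components[[c_]], n, tm$q)
      comp_off[c_] <- off
      off <- off + tm$q
    }
    offsets[[k]] <- comp_off
  }
  W <- do.call(cbind, c(list(Matrix::Matrix(X, sparse = TRUE)), Zs))
  n_eq <- off
  trait <- as.integer(trait)
  stopifnot(length(trait) == n)
  tr_levels <- sort(unique(trait))
  M_t <- lapply(tr_levels, function(t_) {
    rows <- which(trait == t_)
    Matrix::crossprod(W[rows, , drop = FALSE])
  })
  v_t <- lapply(tr_levels, function(t_) {
    rows <- which(trait == t_)
    as.numeric(Matrix::crossprod(W[rows, , drop = FALSE], y[rows]))
  })
  yy_t <- vapply(tr_levels, function(t_) sum(y[trait == t_]^2), 0)
  n_t <- vapply(tr_levels, function(t_) sum(trait == t_), 0L)
  # full-pattern triplets of each M_t, for trace computations
  Mg_t <- lapply(M_t, function(m) {
    g <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
    list(i = g@i + 1L, j = g@j + 1L, x = g@x)
  })
  structure(list(y = y, W = W, X = X, terms = terms, trait = trait,
                 tr_levels = tr_levels, M_t = M_t, Mg_t = Mg_t, v_t = v_t,
                 yy_t = yy_t, n_t = n_t, p = p, n = n, n_eq = n_eq,
                 offsets = offsets, var_e = rep_len(var_e,
                                                    length(tr_levels))),
            class = "mme_system")
}

# coefficient matrix and rhs for a given parameter set
mme_coefficients <- function(sys, gammas, var_e) {
  C <- sys$M_t[[1]] / var_e[1]
  rhs <- sys$v_t[[1]] / var_e[1]
  if (length(sys$tr_levels) > 1L) {
    for (t_ in 2:length(sys$tr_levels)) {
      C <- C + sys$M_t[[t_]] / var_e[t_]
      rhs <- rhs + sys$v_t[[t_]] / var_e[t_]
    }
  }
  blocks <- list(Matrix::Matrix(0, sys$p, sys$p, sparse = TRUE))
  for (k in seq_along(sys$terms)) {
    tm <- sys$terms[[k]]
    Gi <- solve(gammas[[k]])
    # keep exact zeros out of the pattern so the sparsity structure of
    # the coefficient matrix is invariant across parameter values
    # (allows symbolic-factorization reuse)
    Gi[Gi == 0] <- 1e-300
    Kinv <- tm$Kinv %||% Matrix::Diagonal(tm$q)
    blocks[[k + 1L]] <- Matrix::kronecker(Gi, Kinv)
  }
  Ginv <- Matrix::bdiag(blocks)
  C <- methods::as(C + Ginv, "CsparseMatrix")
  list(C = Matrix::forceSymmetric(C), rhs = rhs)
}

#' Solve an assembled mixed-model system
#'
#' Direct sparse Cholesky factorization; returns fixed and random
#' solutions and, optionally, the diagonal of the inverse coefficient
#' matrix over the random blocks (the prediction error variances).
#'
#' @param sys an [build_mme()] system.
#' @param gammas list of per-term (co)variance matrices; defaults to the
#'   `Gamma` stored in each term.
#' @param var_e residual variance(s); defaults to the system's.
#' @param inverse_diag return `diag(C^-1)` as well (costs one solve per
#'   equation block).
#' @return A list with `solution` (full vector), `fixed`, `random` (per
#'   term, per component, named by level), and optionally `inv_diag`.
#' @export
solve_mme <- function(sys, gammas = NULL, var_e = NULL,
                      inverse_diag = FALSE) {
  gammas <- gammas %||% lapply(sys$terms, `[[`, "Gamma")
  var_e <- var_e %||% sys$var_e
  cm <- mme_coefficients(sys, gammas, var_e)
  ch <- Matrix::Cholesky(cm$C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(ch, cm$rhs, system = "A"))
  out <- list(solution = sol,
              fixed = setNames(sol[seq_len(sys$p)], colnames(sys$X)),
              random = extract_random(sys, sol))
  if (inverse_diag) {
    S <- as.matrix(Matrix::solve(ch, diag(sys$n_eq), system = "A"))
    out$inv_diag <- diag(S)
  }
  out$cholesky <- ch
  out
}

extract_random <- function(sys, sol) {
  res <- list()
  for (k in seq_along(sys$terms)) {
    tm <- sys$terms[[k]]
    comps <- list()
    for (c_ in seq_len(tm$t)) {
      off <- sys$offsets[[k]][c_]
      comps[[names(tm$components)[c_] %||% paste0("c", c_)]] <-
        setNames(sol[off + seq_len(tm$q)], tm$levels)
    }
    res[[tm$label]] <- comps
  }
  res
}
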