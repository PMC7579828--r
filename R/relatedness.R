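#' Pedigree numerator relationship matrix (A)
#'
#' Builds the additive relationship matrix by the tabular method on a
#' topologically sorted pedigree: founders are unrelated and non-inbred,
#' each animal's row is the average of its parents' rows, and
#' `A[i,i] = 1 + 0.5 * A[sire, dam]`.
#'
#' @param ped pedigree `data.frame` with columns `animal`, `sire`, `dam`,
#'   parents preceding offspring (see [read_pedigree()]).
#' @param ids optional character vector: return only this submatrix
#'   (e.g. the genotyped subset, `A22`).
#' @return A dense symmetric matrix with animal ids as dimnames.
#' @export
a_matrix <- function(ped, ids = NULL) {
  n <- nrow(ped)
  si <- match(normalize_parent(ped$sire), ped$animal)
  di <- match(normalize_parent(ped$dam), ped$animal)
  if (any(si >= seq_len(n) | di >= seq_len(n), na.rm = TRUE))
    stop("pedigree is not sorted with parents before offspring")
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      r <- numeric(i - 1L)
      if (!is.na(s)) r <- r + 0.5 * A[s, j]
      if (!is.na(d)) r <- r + 0.5 * A[d, j]
      A[i, j] <- r
      A[j, i] <- r
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, ped$animal)
    if (length(miss))
      stop("ids not in pedigree: ", paste(head(miss), collapse = ", "))
    A <- A[ids, ids, drop = FALSE]
  }
  A
}

#' Wright's inbreeding coefficients
#'
#' `F = diag(A) - 1` from the tabular relationship matrix; adequate at the
#' scale of pedigrees this package targets.
#'
#' @inheritParams a_matrix
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  diag(a_matrix(ped)) - 1
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Henderson's rules with inbreeding-adjusted Mendelian-sampling
#' variances: for animal `i` with both parents known the sampling variance
#' is `0.5 - 0.25 (F_s + F_d)`, with one parent `0.75 - 0.25 F_p`, and 1
#' otherwise.
#'
#' @inheritParams a_matrix
#' @return A sparse symmetric `Matrix::dsCMatrix` with animal dimnames.
#' @export
a_inverse <- function(ped) {
  n <- nrow(ped)
  f <- inbreeding(ped)
  si <- match(normalize_parent(ped$sire), ped$animal)
  di <- match(normalize_parent(ped$dam), ped$animal)
  fs <- ifelse(is.na(si), 0, f[ifelse(is.na(si), 1L, si)])
  fd <- ifelse(is.na(di), 0, f[ifelse(is.na(di), 1L, di)])
  n_par <- (!is.na(si)) + (!is.na(di))
  m <- ifelse(n_par == 2L, 0.5 - 0.25 * (fs + fd),
              ifelse(n_par == 1L, 0.75 - 0.25 * (fs + fd), 1))
  alpha <- 1 / m
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, x) {
    k <- length(ii) + 1L
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- x
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  for (p in list(si, di)) {
    has <- !is.na(p)
    add(idx[has], p[has], -alpha[has] / 2)
    add(p[has], idx[has], -alpha[has] / 2)
    add(p[has], p[has], alpha[has] / 4)
  }
  both <- !is.na(si) & !is.na(di)
  add(si[both], di[both], alpha[both] / 4)
  add(di[both], si[both], alpha[both] / 4)
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p_j (1 - p_j)))` where `Z` is the allele-count
#' matrix centered by twice the observed allele frequencies. Missing
#' genotypes are mean-imputed per SNP before centering, which preserves a
#' zero column mean.
#'
#' @param geno numeric matrix of allele counts in `{0,1,2,NA}`, animals in
#'   rows (rownames = animal ids), SNPs in columns.
#' @return Dense symmetric genomic relationship matrix.
#' @export
vanraden_g <- function(geno) {
  geno <- as.matrix(geno)
  if (any(colSums(!is.na(geno)) == 0L))
    stop("genotype matrix contains an all-missing SNP; run genotype_qc first")
  p <- colMeans(geno, na.rm = TRUE) / 2
  if (anyNA(geno)) {
    for (j in which(colSums(is.na(geno)) > 0L)) {
      geno[is.na(geno[, j]), j] <- 2 * p[j]
    }
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs are monomorphic; G is undefined")
  Z <- sweep(geno, 2L, 2 * p)
  tcrossprod(Z) / denom
}

#' Blend a genomic relationship matrix with its pedigree counterpart
#'
#' `G_w = (1 - weight) * G + weight * A22`. Blending restores
#' invertibility of `G` when genotyped animals are fewer than markers are
#' informative for, and anchors it to the pedigree base.
#'
#' @param G genomic relationship matrix.
#' @param A22 pedigree relationship submatrix for the same animals, in the
#'   same order.
#' @param weight blending weight on `A22`; default 0.05.
#' @return The blended matrix `G_w`.
#' @export
blend_g <- function(G, A22, weight = 0.05) {
  if (!identical(dim(G), dim(A22)) ||
      !identical(rownames(G), rownames(A22)))
    stop("G and A22 must share the same animal index")
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  (1 - weight) * G + weight * A22
}

#' Single-step blended relationship matrix inverse (H-inverse)
#'
#' Assembles `H^-1 = A^-1 + [0 0; 0 Gw^-1 - A22^-1]`, the single-step
#' GBLUP precision matrix that carries genomic information for genotyped
#' animals while retaining pedigree relationships for the rest.
#'
#' @param ainv sparse `A^-1` over the full pedigree (from [a_inverse()]).
#' @param a22_inv inverse of the pedigree relationship submatrix of the
#'   genotyped animals.
#' @param gw_inv inverse of the blended genomic matrix [blend_g()], same
#'   animal order as `a22_inv`.
#' @param genotyped_ids character ids of the genotyped animals.
#' @return Sparse symmetric `H^-1` with the full pedigree index.
#' @export
h_inverse <- function(ainv, a22_inv, gw_inv, genotyped_ids) {
  all_ids <- rownames(ainv)
  if (!all(genotyped_ids %in% all_ids))
    stop("genotyped_ids must be a subset of the pedigree index")
  if (!identical(dim(a22_inv), dim(gw_inv)) ||
      nrow(a22_inv) != length(genotyped_ids))
    stop("a22_inv and gw_inv must match genotyped_ids")
  corr <- as.matrix(gw_inv) - as.matrix(a22_inv)
  pos <- match(genotyped_ids, all_ids)
  idx <- expand.grid(i = pos, j = pos)
  Hcorr <- Matrix::sparseMatrix(i = idx$i, j = idx$j, x = as.vector(corr),
                                dims = dim(ainv), dimnames = dimnames(ainv))
  Matrix::forceSymmetric(ainv + Hcorr)
}

#' Genotype quality control
#'
#' Applies the marker and animal filters used ahead of genomic evaluation:
#' SNPs and animals with call rate below `call_rate_min` are removed,
#' monomorphic SNPs are removed, and animals whose opposing-homozygote
#' rate with a recorded parent exceeds `mendel_max` have that parentage
#' blanked in the returned pedigree.
#'
#' @param geno allele-count matrix (`{0,1,2,NA}`), animals in rows.
#' @param ped pedigree `data.frame` (`animal`, `sire`, `dam`).
#' @param call_rate_min minimum call rate for SNPs and animals (0.85).
#' @param mendel_max maximum tolerated opposing-homozygote rate with a
#'   listed parent (0.02).
#' @return A list with elements `geno` (filtered matrix), `ped` (pedigree
#'   with offending parent links removed) and `report` (dropped SNPs and
#'   animals with reasons, and unlinked parent pairs with their error
#'   rates).
#' @export
genotype_qc <- function(geno, ped, call_rate_min = 0.85, mendel_max = 0.02) {
  geno <- as.matrix(geno)
  dropped_snps <- data.frame(snp = character(), reason = character())
  dropped_animals <- data.frame(animal = character(), reason = character())

  cr_snp <- colMeans(!is.na(geno))
  bad <- cr_snp < call_rate_min
  if (any(bad)) {
    dropped_snps <- rbind(dropped_snps,
                          data.frame(snp = colnames(geno)[bad],
                                     reason = "call_rate"))
    geno <- geno[, !bad, drop = FALSE]
  }
  cr_ani <- rowMeans(!is.na(geno))
  bad <- cr_ani < call_rate_min
  if (any(bad)) {
    dropped_animals <- rbind(dropped_animals,
                             data.frame(animal = rownames(geno)[bad],
                                        reason = "call_rate"))
    geno <- geno[!bad, , drop = FALSE]
  }
  mono <- apply(geno, 2L, function(g) {
    g <- g[!is.na(g)]
    length(g) == 0L || all(g == g[1])
  })
  if (any(mono)) {
    dropped_snps <- rbind(dropped_snps,
                          data.frame(snp = colnames(geno)[mono],
                                     reason = "monomorphic"))
    geno <- geno[, !mono, drop = FALSE]
  }
  if (nrow(geno) == 0L || ncol(geno) == 0L)
    stop("no genotypes remain after quality control")

  unlinked <- data.frame(animal = character(), parent = character(),
                         which = character(), rate = numeric())
  ped_out <- ped
  for (which_par in c("sire", "dam")) {
    par <- normalize_parent(ped[[which_par]])
    check <- which(ped$animal %in% rownames(geno) & par %in% rownames(geno))
    for (k in check) {
      gc <- geno[ped$animal[k], ]
      gp <- geno[par[k], ]
      ok <- !is.na(gc) & !is.na(gp)
      if (!any(ok)) next
      opp <- sum((gc[ok] == 0 & gp[ok] == 2) | (gc[ok] == 2 & gp[ok] == 0))
      rate <- opp / sum(ok)
      if (rate > mendel_max) {
        unlinked <- rbind(unlinked,
                          data.frame(animal = ped$animal[k], parent = par[k],
                                     which = which_par, rate = rate))
        ped_out[[which_par]][k] <- NA_character_
      }
    }
  }
  list(geno = geno, ped = ped_out,
       report = list(dropped_snps = dropped_snps,
                     dropped_animals = dropped_animals,
                     unlinked_parents = unlinked))
}
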