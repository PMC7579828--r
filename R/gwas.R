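#' Deregress breeding values for association analysis
#'
#' Reliability is `r2 = 1 - PEV / sigma2_a`; the deregressed proof is
#' `ebv / r2` (simple reliability deregression) and each animal carries
#' its reliability as the weight of its single pseudo-record. Animals
#' whose reliability falls below `min_reliability` are excluded.
#'
#' @param ebv_table `data.frame` with `animal`, `ebv`, `pev` (from
#'   [fit_univariate()]).
#' @param sigma2_a additive genetic variance used for the reliabilities.
#' @param min_reliability exclusion floor (default 0.05).
#' @return `data.frame` with `animal_id`, `debv`, `weight`.
#' @export
deregress <- function(ebv_table, sigma2_a, min_reliability = 0.05) {
  if (sigma2_a <= 0) stop("sigma2_a must be positive")
  r2 <- 1 - ebv_table$pev / sigma2_a
  r2 <- pmin(1, r2)
  keep <- r2 >= min_reliability
  data.frame(animal_id = ebv_table$animal[keep],
             debv = ebv_table$ebv[keep] / r2[keep],
             weight = r2[keep], stringsAsFactors = FALSE)
}

#' Single-SNP genome-wide association on deregressed breeding values
#'
#' For each SNP, a generalized least-squares fit of
#' `y = 1 mu + x beta + g + e` with `Var(g) = G sigma2_a` (the genomic
#' relationship matrix controlling family structure) and
#' `Var(e_i) = sigma2_e / w_i` (reliability weights). The heritability on
#' this pseudo-phenotype scale is constrained to `h2_fixed`: the total
#' variance is taken from the sample variance of the deregressed proofs
#' and split `h2_fixed : 1 - h2_fixed`. Wald tests give p-values;
#' [bh_fdr()] supplies q-values.
#'
#' @param debv `data.frame` from [deregress()].
#' @param geno allele-count matrix with rownames covering
#'   `debv$animal_id`.
#' @param map SNP map (`snp`, `chr`, `pos`) matching `geno` columns.
#' @param grm genomic relationship matrix over the same animals; computed
#'   with [vanraden_g()] from `geno` when `NULL`.
#' @param h2_fixed constrained heritability (default 0.40).
#' @param varcomp optional explicit `c(sigma2_a, sigma2_e)`; overrides
#'   the sample-variance scaling (the `h2_fixed` constraint is then not
#'   applied).
#' @return `data.frame` of class `gwas_result`: `snp`, `chr`, `pos`,
#'   `beta`, `se`, `p`, `q`; monomorphic SNPs are skipped and flagged in
#'   the `skipped` attribute.
#' @export
single_snp_scan <- function(debv, geno, map = NULL, grm = NULL,
                            h2_fixed = 0.40, varcomp = NULL) {
  ids <- intersect(debv$animal_id, rownames(geno))
  if (length(ids) < 10L) stop("too few genotyped animals with proofs")
  debv <- debv[match(ids, debv$animal_id), , drop = FALSE]
  M <- geno[ids, , drop = FALSE]
  G <- grm %||% vanraden_g(M)
  if (is.null(rownames(G))) {
    if (nrow(G) != nrow(geno))
      stop("grm without dimnames must match the genotype matrix rows")
    dimnames(G) <- list(rownames(geno), rownames(geno))
  }
  G <- G[ids, ids]
  y <- debv$debv
  w <- debv$weight
  # anchor the scale on the sample variance of the proofs, allocating
  # it between G and the weighted residual so that the mean modelled
  # variance matches while sigma2_a / (sigma2_a + sigma2_e) = h2_fixed
  if (is.null(varcomp)) {
    v_tot <- var(y)
    ratio <- h2_fixed / (1 - h2_fixed)
    s2e <- v_tot / (ratio * mean(diag(G)) + mean(1 / w))
    s2a <- ratio * s2e
  } else {
    s2a <- varcomp[1]
    s2e <- varcomp[2]
  }
  V <- s2a * G + diag(s2e / w)
  Vi <- chol2inv(chol(V))
  one <- rep(1, length(y))
  Viy <- Vi %*% y
  Vi1 <- Vi %*% one
  mono <- apply(M, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || all(x == x[1])
  })
  snps <- colnames(M)[!mono]
  res <- matrix(NA_real_, length(snps), 3,
                dimnames = list(snps, c("beta", "se", "p")))
  for (s in snps) {
    x <- M[, s]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    Vix <- Vi %*% x
    XtVX <- rbind(c(sum(one * Vi1), sum(x * Vi1)),
                  c(sum(one * Vix), sum(x * Vix)))
    XtVy <- c(sum(one * Viy), sum(x * Viy))
    XtVXi <- tryCatch(solve(XtVX), error = function(e) NULL)
    if (is.null(XtVXi)) next
    bhat <- XtVXi %*% XtVy
    se <- sqrt(XtVXi[2, 2])
    z <- bhat[2] / se
    res[s, ] <- c(bhat[2], se, 2 * pnorm(-abs(z)))
  }
  out <- data.frame(snp = snps,
                    chr = if (!is.null(map)) map$chr[match(snps, map$snp)]
                          else NA,
                    pos = if (!is.null(map)) map$pos[match(snps, map$snp)]
                          else NA,
                    beta = res[, "beta"], se = res[, "se"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$p), , drop = FALSE]
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  attr(out, "skipped") <- colnames(M)[mono]
  class(out) <- c("gwas_result", class(out))
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate q-values with enforced monotonicity,
#' computed through [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return q-values in the input order (empty input gives empty output).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Genes within a window of significant SNPs
#'
#' Reports every gene whose interval lies within `window` base pairs of
#' a hit SNP position (inclusive at exactly the window width; distance 0
#' for SNPs inside the gene). Distance is strand-agnostic.
#'
#' @param hits `data.frame` with `snp`, `chr`, `pos` (e.g. the
#'   `q < 0.05` rows of a [single_snp_scan()] result).
#' @param annotations `data.frame` from [read_annotations()] (1-based
#'   closed coordinates).
#' @param window search radius in bp (default 50000).
#' @return `data.frame` with `snp`, `gene_id`, `distance`; the
#'   deduplicated gene list is in the `genes` attribute. Chromosome
#'   names present in hits but absent from the annotation trigger a
#'   warning.
#' @export
genes_near_hits <- function(hits, annotations, window = 50000L) {
  un <- setdiff(unique(hits$chr), unique(annotations$chr))
  if (length(un))
    warning(length(un), " hit chromosome(s) missing from annotation: ",
            paste(un, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    ann <- annotations[annotations$chr == hits$chr[i], , drop = FALSE]
    if (!nrow(ann)) next
    p <- hits$pos[i]
    inside <- p >= ann$start & p <= ann$end
    dist <- ifelse(inside, 0L,
                   pmin(abs(p - ann$start), abs(p - ann$end)))
    sel <- dist <= window
    if (any(sel))
      rows[[length(rows) + 1L]] <-
        data.frame(snp = hits$snp[i], gene_id = ann$gene_id[sel],
                   distance = as.integer(dist[sel]),
                   stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), gene_id = character(),
               distance = integer(), stringsAsFactors = FALSE)
  attr(out, "genes") <- sort(unique(out$gene_id))
  out
}
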