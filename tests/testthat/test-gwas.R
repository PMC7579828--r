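test_that("deregression follows the reliability rules", {
  tab <- data.frame(animal = c("a", "b", "c"),
                    ebv = c(0.5, 0.2, 0.1),
                    pev = c(0, 0.2, 0.4))
  out <- deregress(tab, sigma2_a = 0.4)
  # pev = 0 -> weight 1, proof = ebv
  expect_equal(out$weight[out$animal_id == "a"], 1)
  expect_equal(out$debv[out$animal_id == "a"], 0.5)
  # pev = 0.5 * sigma2_a -> weight 0.5, proof doubled
  expect_equal(out$weight[out$animal_id == "b"], 0.5)
  expect_equal(out$debv[out$animal_id == "b"], 0.4)
  # pev = sigma2_a -> reliability 0 -> excluded
  expect_false("c" %in% out$animal_id)
  expect_error(deregress(tab, 0), "positive")
})

test_that("BH q-values equal the brute-force step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.30)), c(0.03, 0.03, 0.30))
  set.seed(71)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p), bh_brute(p))
  }
  # invariant to SNP ordering
  p <- runif(30)
  o <- sample(30)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  expect_length(bh_fdr(numeric(0)), 0L)
  expect_error(bh_fdr(c(0.5, 0)), "p-values")
})

test_that("the scan equals a dense per-SNP GLS fit on a toy set", {
  set.seed(72)
  n <- 20; m <- 12
  M <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(sprintf("a%02d", 1:n),
                              sprintf("s%02d", 1:m)))
  G <- vanraden_g(M)
  y <- rnorm(n)
  w <- runif(n, 0.4, 1)
  debv <- data.frame(animal_id = rownames(M), debv = y, weight = w)
  vc <- c(0.3, 0.7)
  scan <- single_snp_scan(debv, M, grm = G, varcomp = vc)
  V <- vc[1] * G + diag(vc[2] / w)
  for (s in scan$snp) {
    x <- M[, s]
    Xs <- cbind(1, x)
    Vi <- solve(V)
    bhat <- solve(t(Xs) %*% Vi %*% Xs, t(Xs) %*% Vi %*% y)
    se <- sqrt(solve(t(Xs) %*% Vi %*% Xs)[2, 2])
    k <- scan$snp == s
    expect_equal(scan$beta[k], bhat[2], tolerance = 1e-8)
    expect_equal(scan$se[k], se, tolerance = 1e-8)
    expect_equal(scan$p[k], 2 * pnorm(-abs(bhat[2] / se)),
                 tolerance = 1e-8)
  }
})

test_that("monomorphic SNPs are skipped with a log entry", {
  set.seed(73)
  n <- 25
  M <- cbind(mono = rep(2, n),
             ok = rbinom(n, 2, 0.5))
  rownames(M) <- sprintf("a%02d", 1:n)
  debv <- data.frame(animal_id = rownames(M), debv = rnorm(n), weight = 1)
  scan <- single_snp_scan(debv, M, grm = diag(n) + 0.01,
                          varcomp = c(0.2, 0.8))
  expect_false("mono" %in% scan$snp)
  expect_equal(attr(scan, "skipped"), "mono")
})

test_that("duplicating a record with half weights reproduces the fit", {
  set.seed(74)
  n <- 15; m <- 8
  M <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(sprintf("a%02d", 1:n),
                              sprintf("s%02d", 1:m)))
  y <- rnorm(n); w <- runif(n, 0.5, 1)
  G <- vanraden_g(M)
  vc <- c(0.25, 0.75)
  base <- single_snp_scan(data.frame(animal_id = rownames(M),
                                     debv = y, weight = w),
                          M, grm = G, varcomp = vc)
  # duplicate animal 1 as a new id with the same genotype row,
  # splitting its weight in half across the two records
  M2 <- rbind(M, dup = M[1, ])
  G2 <- rbind(cbind(G, G[, 1]), c(G[1, ], G[1, 1]))
  dimnames(G2) <- list(rownames(M2), rownames(M2))
  debv2 <- data.frame(animal_id = c(rownames(M), "dup"),
                      debv = c(y, y[1]),
                      weight = c(w[1] / 2, w[-1], w[1] / 2))
  dup <- single_snp_scan(debv2, M2, grm = G2, varcomp = vc)
  expect_equal(base$beta, dup$beta, tolerance = 1e-6)
  expect_equal(base$p, dup$p, tolerance = 1e-6)
})

test_that("scan p-values are uniform under a pure-noise null with GRM = I", {
  set.seed(75)
  n <- 300; m <- 1500
  M <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)), n, m, byrow = TRUE,
              dimnames = list(sprintf("a%03d", 1:n),
                              sprintf("s%04d", 1:m)))
  debv <- data.frame(animal_id = rownames(M), debv = rnorm(n), weight = 1)
  scan <- single_snp_scan(debv, M, grm = diag(n), varcomp = c(0, 1))
  ks <- suppressWarnings(ks.test(scan$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(scan$q >= scan$p - 1e-12))
})

test_that("a causal SNP explaining 10% of variance tops the scan", {
  hits <- sapply(1:3, function(r) {
    set.seed(760 + r)
    cfg <- sim_config(n_founders = 250, n_generations = 1, n_snps = 800,
                      seed = 760 + r)
    ped <- simulate_pedigree(cfg)
    gen <- simulate_genotypes(ped, cfg)
    ids <- sample(ped$animal, 400)
    M <- gen$geno[ids, ]
    G <- vanraden_g(M)
    L <- chol(0.4 * (G + diag(1e-6, nrow(G))))
    y <- drop(crossprod(L, rnorm(length(ids)))) + rnorm(length(ids), 0,
                                                        sqrt(0.6))
    x <- M[, 400]
    y <- y + (x - mean(x)) * sqrt(0.1 * var(y) / max(var(x), 1e-8))
    scan <- single_snp_scan(data.frame(animal_id = ids, debv = y,
                                       weight = 1), M, map = gen$map)
    scan$snp[which.min(scan$q)] == "SNP00400"
  })
  expect_gte(sum(hits), 2L)
})

test_that("gene lookup respects the 50 kb inclusive window", {
  ann <- data.frame(gene_id = c("inside", "at50k", "beyond", "otherchr"),
                    chr = c("1", "1", "1", "2"),
                    start = c(900, 899000, 898000, 900),
                    end = c(1100, 950000 - 50000, 950000 - 50001, 1100),
                    strand = "+")
  hits <- data.frame(snp = c("s1", "s2"), chr = "1",
                     pos = c(1000, 950000))
  out <- genes_near_hits(hits, ann, window = 50000)
  expect_equal(out$distance[out$snp == "s1" & out$gene_id == "inside"], 0L)
  expect_true("at50k" %in% out$gene_id[out$snp == "s2"])
  expect_false("beyond" %in% out$gene_id)
  expect_setequal(attr(out, "genes"), c("inside", "at50k"))
  expect_warning(
    genes_near_hits(data.frame(snp = "s", chr = "9", pos = 1), ann),
    "missing")
})
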