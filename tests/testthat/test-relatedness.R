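test_that("tabular A matches closed-form relationships", {
  ped <- ped_df(c("f1", "f2", "kid"), c(NA, NA, "f1"), c(NA, NA, "f2"))
  A <- a_matrix(ped)
  expect_equal(unname(A[1:2, 1:2]), diag(2))
  expect_equal(A["kid", "f1"], 0.5)
  expect_equal(A["kid", "kid"], 1)

  # offspring of full sibs: parents related 0.5 => diagonal 1.25
  ped2 <- ped_df(c("s", "d", "b1", "b2", "x"),
                 c(NA, NA, "s", "s", "b1"),
                 c(NA, NA, "d", "d", "b2"))
  A2 <- a_matrix(ped2)
  expect_equal(A2["b1", "b2"], 0.5)
  expect_equal(A2["x", "x"], 1.25)
  expect_equal(inbreeding(ped2)[["x"]], 0.25)

  # offspring of half sibs: F = 0.125 by path counting
  ped3 <- ped_df(c("s", "d1", "d2", "h1", "h2", "y"),
                 c(NA, NA, NA, "s", "s", "h1"),
                 c(NA, NA, NA, "d1", "d2", "h2"))
  expect_equal(inbreeding(ped3)[["y"]], 0.125)
})

test_that("Henderson's A-inverse inverts the tabular A", {
  # founders only -> identity
  ped0 <- ped_df(c("a", "b", "c"))
  expect_equal(as.matrix(a_inverse(ped0)), diag(3), ignore_attr = TRUE)

  # non-inbred trio closed form
  ped1 <- ped_df(c("s", "d", "k"), c(NA, NA, "s"), c(NA, NA, "d"))
  Ai <- as.matrix(a_inverse(ped1))
  expect_equal(unname(diag(Ai)), c(1.5, 1.5, 2))
  expect_equal(Ai["s", "k"], -1)
  expect_equal(Ai["s", "d"], 0.5)

  # random pedigrees (with inbreeding): A_inv . A = I to 1e-8
  for (seed in 1:3) {
    ped <- random_pedigree(50, seed = seed)
    prod <- as.matrix(a_inverse(ped) %*% a_matrix(ped))
    expect_lt(max(abs(prod - diag(50))), 1e-8)
  }
})

test_that("VanRaden G reproduces the hand-worked toy and its identities", {
  M <- rbind(a1 = c(0, 2), a2 = c(1, 1), a3 = c(2, 0))
  colnames(M) <- c("s1", "s2")
  G <- vanraden_g(M)
  # p = (0.5, 0.5); Z = M - 1; denominator 2 * (0.25 + 0.25) = 1
  Z <- M - 1
  expect_equal(unname(G), unname(tcrossprod(Z) / 1))
  # centering: G %*% 1 = 0 when p is the observed frequency
  expect_lt(max(abs(rowSums(G))), 1e-12)

  cfg <- sim_config(n_founders = 30, n_generations = 1, n_snps = 80,
                    seed = 3)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)$geno
  G1 <- vanraden_g(geno)
  # invariant to SNP order
  expect_equal(vanraden_g(geno[, sample(ncol(geno))]), G1)
  # invariant to which allele is counted
  expect_equal(vanraden_g(2 - geno), G1)
  # identical genotypes give identical rows
  M2 <- geno[c(1, 1, 2:10), ]
  rownames(M2)[2] <- "copy"
  G2 <- vanraden_g(M2)
  expect_equal(G2[1, 2], G2[1, 1])
})

test_that("blending interpolates between G and A22", {
  G <- matrix(c(1, 0.8, 0.8, 1), 2, 2, dimnames = rep(list(c("a", "b")), 2))
  A22 <- matrix(c(1, 0.5, 0.5, 1), 2, 2, dimnames = dimnames(G))
  expect_equal(blend_g(G, A22, 0), G)
  expect_equal(blend_g(G, A22, 1), A22)
  expect_equal(blend_g(G, A22, 0.05)["a", "b"], 0.785)
  expect_error(blend_g(G, A22[2:1, 2:1]), "index")
})

test_that("H-inverse reduces to A-inverse when genomics add nothing", {
  ped <- random_pedigree(20, seed = 6)
  ainv <- a_inverse(ped)
  gids <- ped$animal[seq(2, 20, by = 2)]
  A22 <- a_matrix(ped, ids = gids)
  hinv <- h_inverse(ainv, solve(A22), solve(A22), gids)
  expect_lt(max(abs(as.matrix(hinv) - as.matrix(ainv))), 1e-10)
})

test_that("H-inverse matches the direct joint-distribution H", {
  # 6 animals, 3 genotyped; oracle: dense H built by conditioning the
  # non-genotyped on the genotyped animals
  ped <- ped_df(c("f1", "f2", "f3", "k1", "k2", "k3"),
                c(NA, NA, NA, "f1", "f1", "k1"),
                c(NA, NA, NA, "f2", "f3", "k2"))
  gids <- c("k1", "k2", "k3")
  A <- a_matrix(ped)
  A22 <- A[gids, gids]
  set.seed(8)
  B <- matrix(rnorm(9), 3)
  Gw <- 0.95 * (tcrossprod(B) / 3 + diag(3) * 0.3 + A22) / 2 + 0.05 * A22
  dimnames(Gw) <- dimnames(A22)
  free <- setdiff(ped$animal, gids)
  A11 <- A[free, free]; A12 <- A[free, gids]
  A22i <- solve(A22)
  H11 <- A11 + A12 %*% A22i %*% (Gw - A22) %*% A22i %*% t(A12)
  H12 <- A12 %*% A22i %*% Gw
  H <- rbind(cbind(H11, H12), cbind(t(H12), Gw))
  idx <- c(free, gids)
  hinv <- h_inverse(a_inverse(ped), A22i, solve(Gw), gids)
  expect_lt(max(abs(solve(as.matrix(hinv)[idx, idx]) - H)), 1e-8)
})

test_that("H-inverse correction is linear in its genotyped block", {
  ped <- random_pedigree(15, seed = 10)
  gids <- ped$animal[1:6]
  A22 <- a_matrix(ped, ids = gids)
  Gw <- 0.95 * (A22 + diag(0.2, 6)) + 0.05 * A22
  ainv <- a_inverse(ped)
  corr1 <- as.matrix(h_inverse(ainv, solve(A22), solve(Gw), gids) - ainv)
  doubled <- solve(A22) + 2 * (solve(Gw) - solve(A22))
  corr2 <- as.matrix(h_inverse(ainv, solve(A22), doubled, gids) - ainv)
  expect_equal(corr2, 2 * corr1, tolerance = 1e-10)
})

test_that("genotype QC drops by call rate, monomorphism and Mendel errors", {
  set.seed(12)
  n <- 30; m <- 100
  geno <- matrix(rbinom(n * m, 2, 0.4), n, m,
                 dimnames = list(sprintf("a%02d", 1:n),
                                 sprintf("s%03d", 1:m)))
  geno[, 1] <- 2                       # monomorphic
  geno[1, seq(1, m, by = 5)] <- NA     # animal 20% missing -> call rate 0.80
  geno[2:n, 2] <- NA                   # SNP call rate < 0.85
  ped <- ped_df(rownames(geno))
  # plant a parent-offspring pair with 5% opposing homozygotes
  ped$sire[3] <- "a04"
  geno["a03", ] <- geno["a04", ]
  opp <- 3:7
  geno["a03", opp] <- 0; geno["a04", opp] <- 2
  qc <- genotype_qc(geno, ped)
  expect_true("s001" %in% qc$report$dropped_snps$snp)
  expect_true("s002" %in% qc$report$dropped_snps$snp)
  expect_true("a01" %in% qc$report$dropped_animals$animal)
  expect_equal(qc$report$unlinked_parents$animal, "a03")
  expect_gt(qc$report$unlinked_parents$rate, 0.02)
  expect_true(is.na(qc$ped$sire[qc$ped$animal == "a03"]))
  # every dropped item carries exactly one reason
  expect_false(anyDuplicated(qc$report$dropped_snps$snp) > 0)
})
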