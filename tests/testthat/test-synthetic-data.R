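test_that("pedigree simulation handles the founder-only case", {
  cfg <- sim_config(n_founders = 10, n_generations = 0, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10L)
  expect_true(all(is.na(ped$sire)))
  expect_true(all(is.na(ped$dam)))
})

test_that("simulation is reproducible from its seed", {
  cfg <- sim_config(n_founders = 30, n_generations = 2, seed = 7)
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
  ped <- simulate_pedigree(cfg)
  expect_identical(simulate_genotypes(ped, cfg)$geno,
                   simulate_genotypes(ped, cfg)$geno)
  expect_identical(simulate_phenotypes(ped, cfg)$records,
                   simulate_phenotypes(ped, cfg)$records)
})

test_that("offspring counts match direct enumeration of the matings", {
  cfg <- sim_config(n_founders = 10, n_generations = 2,
                    progeny_per_dam = 2, seed = 3)
  ped <- simulate_pedigree(cfg)
  # oracle: each generation produces progeny_per_dam offspring per female
  # of the preceding generation
  for (g in 1:2) {
    n_dams <- sum(ped$generation == g - 1 & ped$sex == "F")
    expect_equal(sum(ped$generation == g), n_dams * 2L)
  }
  # parents precede offspring and no animal is its own ancestor
  expect_silent(sort_pedigree(ped))
  idx <- match(ped$animal, ped$animal)
  expect_true(all(match(ped$sire, ped$animal) < idx, na.rm = TRUE))
})

test_that("gene dropping respects Hardy-Weinberg and Mendelian rules", {
  cfg <- sim_config(n_founders = 400, n_generations = 1, n_snps = 60,
                    maf_range = c(0.5, 0.5), seed = 11)
  ped <- simulate_pedigree(cfg)
  gen <- simulate_genotypes(ped, cfg)
  founders <- gen$geno[ped$generation == 0, ]
  # founder mean genotype ~ 2 * 0.5 within 3 binomial SE
  se <- sqrt(2 * 0.5 * 0.5 / length(founders))
  expect_lt(abs(mean(founders) - 1), 3 * se)
  # both parents homozygous reference => offspring homozygous reference
  off <- ped[!is.na(ped$sire), ]
  s <- gen$geno[off$sire, , drop = FALSE]
  d <- gen$geno[off$dam, , drop = FALSE]
  o <- gen$geno[off$animal, , drop = FALSE]
  both0 <- s == 0 & d == 0
  expect_true(all(o[both0] == 0))
  both2 <- s == 2 & d == 2
  expect_true(all(o[both2] == 2))
})

test_that("marker-based kinship converges to the pedigree A matrix", {
  ped <- simulate_pedigree(sim_config(n_founders = 8, n_generations = 2,
                                      seed = 5))
  ped <- ped[seq_len(min(nrow(ped), 20)), ]
  A <- a_matrix(ped)
  mad <- sapply(c(200, 3000), function(m) {
    cfg <- sim_config(n_founders = 8, n_generations = 2, n_snps = m,
                      seed = 5)
    g <- simulate_genotypes(ped, cfg)
    # expected-kinship oracle: correlation-scale estimator against the
    # founder allele frequencies used in the drop
    p <- g$founder_freq
    Z <- sweep(g$geno, 2, 2 * p)
    K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
    mean(abs(K - A))
  })
  expect_lt(mad[2], mad[1])
})

test_that("simulated phenotype components realize their configured variances", {
  cfg <- sim_config(n_founders = 2000, n_generations = 1,
                    progeny_per_dam = 1, seed = 13)
  ped <- simulate_pedigree(cfg)
  phen <- simulate_phenotypes(ped, cfg)
  bv <- setNames(phen$truth$true_bv$true_bv, phen$truth$true_bv$animal)
  founders <- ped$animal[ped$generation == 0]
  # founder breeding values are iid: variance within 3 MC SE
  v <- var(bv[founders])
  se <- cfg$var_additive * sqrt(2 / (length(founders) - 1))
  expect_lt(abs(v - cfg$var_additive), 3 * se)
  # parent-offspring regression slope of true bv ~ 0.5
  off <- ped[!is.na(ped$sire), ]
  slope <- coef(lm(bv[off$animal] ~ bv[off$sire]))[2]
  expect_lt(abs(slope - 0.5), 0.1)
  # realized ratios coherent with configuration
  expect_lt(abs(phen$truth$realized_h2 - 0.40), 0.05)
  expect_lt(abs(phen$truth$realized_repeatability - 0.44), 0.05)
})

test_that("with no animal effects the within-animal variance is residual", {
  cfg <- sim_config(n_founders = 400, n_generations = 1, var_additive = 0,
                    var_pe = 0, cg_effect_sd = 0, fescue_effect = 0,
                    records_per_animal = c(3, 3), seed = 17)
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, cfg)$records
  within <- unlist(tapply(rec$score, rec$animal_id,
                          function(s) s - mean(s)))
  n_an <- length(unique(rec$animal_id))
  v <- sum(within^2) / (length(within) - n_an)
  expect_lt(abs(v - cfg$var_residual), 3 * cfg$var_residual *
              sqrt(2 / (length(within) - n_an)))
})

test_that("ordinal scoring stays on the 1-5 appraisal scale", {
  cfg <- sim_config(n_founders = 100, n_generations = 1,
                    score_scale = "ordinal", seed = 19)
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, cfg)$records
  expect_true(all(rec$score %in% 1:5))
})

test_that("fescue status-trait generator hits its configured correlation", {
  cfg <- sim_config(n_founders = 1500, n_generations = 1, seed = 23)
  ped <- simulate_pedigree(cfg)
  fs <- simulate_fescue_traits(ped, cfg)
  r <- cor(fs$truth$true_bv[, "yes"], fs$truth$true_bv[, "no"])
  expect_lt(abs(r - 0.93), 0.03)
})

test_that("maternal design recovers configured correlations in truth", {
  cfg <- sim_config(n_founders = 400, n_generations = 2, seed = 29)
  ped <- simulate_pedigree(cfg)
  ww <- simulate_ww_bivariate(ped, cfg)
  bv <- ww$truth$true_bv
  r_dm <- cor(bv[, "ww_d"], bv[, "ww_m"])
  expect_lt(abs(r_dm - (-0.43)), 0.1)
  r_hm <- cor(bv[, "hs"], bv[, "ww_m"])
  expect_lt(abs(r_hm - (-0.19)), 0.1)
  # uncorrelated configuration gives uncorrelated truth
  cfg0 <- sim_config(n_founders = 400, n_generations = 2, seed = 29,
                     ww = list(corr_hs_maternal = 0,
                               corr_direct_maternal = 0,
                               corr_hs_direct = 0))
  ww0 <- simulate_ww_bivariate(ped, cfg0)
  expect_lt(abs(cor(ww0$truth$true_bv[, "hs"],
                    ww0$truth$true_bv[, "ww_m"])), 0.1)
  # dummy calves exist: missing weight and unknown sire
  dummies <- ww$ww_records$calf_id[is.na(ww$ww_records$weight)]
  if (length(dummies)) {
    sires <- ww$ped$sire[match(dummies, ww$ped$animal)]
    expect_true(all(is.na(sires)))
  }
})

test_that("configuration errors are rejected", {
  expect_error(sim_config(n_founders = 1), "n_founders")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(var_additive = -1), "variance")
  expect_error(sim_config(records_per_animal = c(3, 1)),
               "records_per_animal")
  bad_corr <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sim_config(genetic_corr = bad_corr), "genetic_corr")
})
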