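test_that("MME solutions equal dense GLS on a small instance", {
  set.seed(21)
  ped <- random_pedigree(8, seed = 2)
  A <- a_matrix(ped)
  n <- 12
  ids <- sample(ped$animal, n, replace = TRUE)
  cg <- sample(c("g1", "g2"), n, replace = TRUE)
  y <- rnorm(n, 3)
  X <- model.matrix(~ cg)
  s2a <- 0.4; s2p <- 0.1; s2e <- 0.6
  Zu <- matrix(0, n, nrow(ped)); Zu[cbind(1:n, match(ids, ped$animal))] <- 1
  pe_lv <- sort(unique(ids))
  Zp <- matrix(0, n, length(pe_lv)); Zp[cbind(1:n, match(ids, pe_lv))] <- 1
  oracle <- gls_oracle(y, X, list(Zu, Zp),
                       list(s2a * A, s2p * diag(length(pe_lv))),
                       s2e * diag(n))
  terms <- list(
    ran_term("u", ped$animal, list(u = match(ids, ped$animal)),
             Kinv = a_inverse(ped), Gamma = matrix(s2a, 1, 1)),
    ran_term("pe", pe_lv, list(pe = match(ids, pe_lv)),
             Kinv = NULL, Gamma = matrix(s2p, 1, 1)))
  sys <- build_mme(y, X, terms, var_e = s2e)
  sol <- solve_mme(sys)
  expect_equal(unname(sol$fixed), unname(oracle$beta), tolerance = 1e-8)
  expect_equal(unname(sol$random$u$u), unname(oracle$u[[1]]),
               tolerance = 1e-8)
  expect_equal(unname(sol$random$pe$pe), unname(oracle$u[[2]]),
               tolerance = 1e-8)
})

test_that("the MME solver honours its contracts", {
  set.seed(22)
  n <- 40
  grp <- sample(letters[1:4], n, replace = TRUE)
  lvl <- sprintf("l%02d", sample(1:10, n, replace = TRUE))
  y <- rnorm(n)
  X <- model.matrix(~ grp)
  lv <- sort(unique(lvl))
  tm <- ran_term("r", lv, list(r = match(lvl, lv)), NULL,
                 matrix(0.5, 1, 1))
  sys <- build_mme(y, X, list(tm), var_e = 0.8)
  sol <- solve_mme(sys, inverse_diag = TRUE)
  # normal-equation residual
  cm <- hairshed:::mme_coefficients(sys, list(matrix(0.5, 1, 1)), 0.8)
  expect_lt(max(abs(as.numeric(cm$C %*% sol$solution) - cm$rhs)),
            1e-8 * max(abs(cm$rhs)))
  # inverse diagonal vs dense inversion
  expect_equal(unname(sol$inv_diag),
               unname(diag(solve(as.matrix(cm$C)))), tolerance = 1e-8)
  # permuting record order leaves solutions unchanged
  p <- sample(n)
  tm2 <- ran_term("r", lv, list(r = match(lvl[p], lv)), NULL,
                  matrix(0.5, 1, 1))
  sol2 <- solve_mme(build_mme(y[p], X[p, ], list(tm2), var_e = 0.8))
  expect_equal(sol$solution, sol2$solution, tolerance = 1e-10)
})

test_that("REML on a balanced half-sib design equals the ANOVA closed form", {
  set.seed(23)
  ns <- 50; npro <- 20
  sire <- rep(seq_len(ns), each = npro)
  y <- 2 + rnorm(ns, 0, sqrt(0.2))[sire] + rnorm(ns * npro, 0, sqrt(0.8))
  X <- matrix(1, length(y), 1, dimnames = list(NULL, "mu"))
  tm <- ran_term("sire", as.character(1:ns), list(s = sire), NULL,
                 matrix(0.3, 1, 1))
  fit <- reml_estimate(build_mme(y, X, list(tm), var_e = 0.5))
  msq <- anova(lm(y ~ factor(sire)))$`Mean Sq`
  expect_equal(fit$gammas[[1]][1, 1], (msq[1] - msq[2]) / npro,
               tolerance = 1e-6)
  expect_equal(fit$var_e[1], msq[2], tolerance = 1e-6)
  # the large-system path agrees with the exact-trace path
  fit2 <- reml_estimate(build_mme(y, X, list(tm), var_e = 0.5),
                        exact = FALSE, tol = 1e-7)
  expect_equal(fit2$gammas[[1]][1, 1], fit$gammas[[1]][1, 1],
               tolerance = 1e-5)
  expect_equal(fit2$var_e[1], fit$var_e[1], tolerance = 1e-5)
})

test_that("REML is invariant to response rescaling", {
  st <- small_study(seed = 41, n_founders = 220, n_generations = 2,
                    n_farms = 2)
  f1 <- fit_univariate(st$records, st$ainv, tol = 1e-7)
  rec2 <- st$records
  rec2$score <- rec2$score * 3
  f2 <- fit_univariate(rec2, st$ainv, tol = 1e-7)
  expect_equal(unname(f2$varcomp), unname(f1$varcomp) * 9,
               tolerance = 1e-3)
  expect_equal(f2$params$h2, f1$params$h2, tolerance = 1e-4)
  expect_equal(f2$params$repeatability, f1$params$repeatability,
               tolerance = 1e-4)
})

test_that("reliabilities stay within [0, 1]", {
  st <- small_study(seed = 43, n_founders = 220, n_generations = 2,
                    n_farms = 2)
  fit <- fit_univariate(st$records, st$ainv, varcomp = c(0.4, 0.04, 0.56))
  expect_true(all(fit$ebv$reliability >= 0 & fit$ebv$reliability <= 1))
  expect_true(all(fit$ebv$pev >= 0))
})

test_that("fitting with H-inverse equals A-inverse when G_w = A22", {
  st <- small_study(seed = 47, n_founders = 220, n_generations = 2,
                    n_farms = 2)
  gids <- st$ped$animal[seq(1, nrow(st$ped), by = 2)]
  A22 <- a_matrix(st$ped, ids = gids)
  hinv <- h_inverse(st$ainv, solve(A22), solve(A22), gids)
  vc <- c(0.4, 0.04, 0.56)
  fa <- fit_univariate(st$records, st$ainv, varcomp = vc, pev = FALSE)
  fh <- fit_univariate(st$records, hinv, varcomp = vc, pev = FALSE)
  expect_equal(fa$ebv$ebv, fh$ebv$ebv, tolerance = 1e-8)
})

test_that("genetic parameters follow their defining ratios", {
  gp <- genetic_parameters(0.38, 0.04, 0.53)
  expect_equal(gp$h2, 0.4, tolerance = 1e-12)
  expect_equal(gp$repeatability, 0.42 / 0.95, tolerance = 1e-12)
  expect_equal(genetic_parameters(0.3, 0, 0.58)$h2, 0.3 / 0.88)
  gp0 <- genetic_parameters(0.5, 0, 0.5)
  expect_equal(gp0$repeatability, gp0$h2)
  expect_error(genetic_parameters(0, 0, 0), "total variance")
})

test_that("model comparison computes AIC and detects a real age effect", {
  # arithmetic: logL = -100, k = 5 -> AIC = 210
  f <- list(logLik_ml = -100, logLik = -100, n_params = 2L, sys_p = 3L)
  class(f) <- "reml_fit"
  out <- compare_models(list(m = f))
  expect_equal(out$AIC, 210)
  # identical models: LRT statistic 0 (df forced positive via k_fixed)
  out2 <- compare_models(list(a = f, b = f), k_fixed = c(3L, 4L))
  expect_equal(out2$lrt[2], 0)

  # a simulated four-class age effect is detected against the null
  cfg <- sim_config(n_founders = 250, n_generations = 3, n_farms = 2,
                    records_per_animal = c(2, 4), seed = 51)
  ped <- simulate_pedigree(cfg)
  phen <- simulate_phenotypes(ped, cfg)
  meta <- data.frame(animal = ped$animal, sex = ped$sex,
                     birth_date = ped$birth_date)
  rec <- prep_records(phen$records, meta)$records
  # the age-model contemporary group excludes the age class, otherwise
  # the age effect would be confounded with the groups
  rec$cg_noage <- paste(rec$farm_id, format(as.Date(rec$date), "%Y"),
                        rec$calving_season, rec$fescue_status,
                        rec$score_group, sep = "_")
  ainv <- a_inverse(ped)
  null_fit <- fit_univariate(rec, ainv, cg = "cg_noage", tol = 1e-6)
  age_fit <- fit_univariate(rec, ainv, cg = "cg_noage",
                            extra_fixed = "age_four_class", tol = 1e-6)
  cmp <- compare_models(list(null = null_fit, age = age_fit))
  expect_lt(cmp$AIC[2], cmp$AIC[1])
  expect_gt(cmp$neg_log10_p[2], 3)
})

test_that("degenerate bivariate truth is recovered at the boundary", {
  cfg <- sim_config(n_founders = 250, n_generations = 2, n_farms = 3,
                    records_per_animal = c(2, 4), seed = 53)
  ped <- simulate_pedigree(cfg)
  fs <- simulate_fescue_traits(ped, cfg,
                               var_a = c(yes = 0.35, no = 0.35),
                               var_pe = c(yes = 0.05, no = 0.05),
                               var_e = c(yes = 0.55, no = 0.55),
                               genetic_corr = 1)
  fit <- fit_bivariate_fescue(fs$records, a_inverse(ped), tol = 1e-5)
  expect_gt(fit$r_g, 0.85)
  ebv_cor <- cor(fit$ebv$yes$ebv, fit$ebv$no$ebv)
  expect_gt(ebv_cor, 0.9)
})

test_that("phenotypic regression recovers exact and null slopes", {
  s <- rep(1:5, each = 10)
  noiseless <- suppressWarnings(phenotypic_regression(s, 300 - 2 * s))
  expect_equal(noiseless$slope, -2, tolerance = 1e-10)
  set.seed(55)
  w <- rnorm(2000, 250, 20)
  s2 <- sample(1:5, 2000, replace = TRUE)
  fit <- phenotypic_regression(s2, w)
  expect_lt(abs(fit$slope), 3 * fit$se)
  expect_error(phenotypic_regression(1:2, c(3, 4)), "at least 3")
})

test_that("non-convergence raises an error carrying the trajectory", {
  set.seed(57)
  y <- rnorm(30)
  X <- matrix(1, 30, 1, dimnames = list(NULL, "mu"))
  tm <- ran_term("g", sprintf("l%d", 1:10),
                 list(g = rep(1:10, 3)), NULL, matrix(0.5, 1, 1))
  err <- tryCatch(
    reml_estimate(build_mme(y, X, list(tm), var_e = 0.5),
                  tol = 0, max_iter = 3L),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_true(!is.null(err$trajectory))
  expect_equal(nrow(err$trajectory), 3L)
})
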