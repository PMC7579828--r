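#' Fit the univariate repeated-records animal model
#'
#' `y = Xb + Z1 u + Z2 p + e` with `u ~ N(0, K sigma2_a)` (K the
#' pedigree or single-step blended relationship matrix, supplied through
#' its sparse inverse), `p ~ N(0, I sigma2_pe)` and i.i.d. residuals.
#' The fixed effects are the contemporary groups plus any extra
#' categorical terms (age class, fescue grazing status). Variance
#' components are estimated by [reml_estimate()] unless `varcomp` is
#' given, in which case a single BLUP solve is performed.
#'
#' @param records prepared record `data.frame` with `animal_id`, `score`
#'   and the fixed-term columns.
#' @param precision sparse relationship precision (`A^-1` from
#'   [a_inverse()] or `H^-1` from [h_inverse()]), dimnames = animal ids.
#' @param cg column name holding the contemporary group (default
#'   `"cg_id"`).
#' @param extra_fixed character vector of extra fixed-term columns.
#' @param start starting values `c(var_a, var_pe, var_e)`.
#' @param varcomp optional fixed variance components `c(var_a, var_pe,
#'   var_e)`; skips REML.
#' @param pev with fixed `varcomp`, also extract prediction error
#'   variances (costs a full inverse; disable for plain BLUP solves).
#' @param tol,max_iter REML controls, see [reml_estimate()].
#' @return An object of class `shed_fit`: the `reml_fit` (or BLUP
#'   solution), variance components, genetic parameters with
#'   delta-method standard errors, and the EBV table.
#' @export
fit_univariate <- function(records, precision, cg = "cg_id",
                           extra_fixed = NULL,
                           start = c(0.3, 0.1, 0.6), varcomp = NULL,
                           pev = TRUE, tol = 1e-8, max_iter = 200L) {
  stopifnot(all(records$animal_id %in% rownames(precision)))
  X <- fixed_design(records, c(cg, extra_fixed))
  animals <- rownames(precision)
  pheno <- sort(unique(records$animal_id))
  vc <- varcomp %||% start
  terms <- list(
    ran_term("u", animals, list(u = match(records$animal_id, animals)),
             Kinv = precision, Gamma = matrix(vc[1], 1, 1)),
    ran_term("pe", pheno, list(pe = match(records$animal_id, pheno)),
             Kinv = NULL, Gamma = matrix(vc[2], 1, 1)))
  sys <- build_mme(records$score, X, terms, var_e = vc[3])
  if (is.null(varcomp)) {
    fit <- reml_estimate(sys, tol = tol, max_iter = max_iter)
    vc_hat <- c(var_a = fit$gammas[[1]][1, 1],
                var_pe = fit$gammas[[2]][1, 1], var_e = fit$var_e[1])
    vcv <- fit$theta_vcov
    gp <- genetic_parameters(vc_hat[1], vc_hat[2], vc_hat[3], vcov = vcv)
    ebv <- data.frame(animal = animals,
                      ebv = unname(fit$random$u$u),
                      pev = unname(fit$pev$u[[1]]))
  } else {
    sol <- solve_mme(sys, inverse_diag = pev)
    fit <- sol
    vc_hat <- c(var_a = vc[1], var_pe = vc[2], var_e = vc[3])
    gp <- genetic_parameters(vc[1], vc[2], vc[3])
    off <- sys$offsets[[1]][1]
    ebv <- data.frame(animal = animals,
                      ebv = unname(sol$random$u$u),
                      pev = if (pev)
                        unname(sol$inv_diag[off + seq_along(animals)])
                      else NA_real_)
  }
  ebv$se <- sqrt(pmax(ebv$pev, 0))
  ebv$reliability <- pmin(1, pmax(0, 1 - ebv$pev / vc_hat[["var_a"]]))
  structure(list(fit = fit, varcomp = vc_hat, params = gp, ebv = ebv,
                 reml = is.null(varcomp), n_records = nrow(records)),
            class = "shed_fit")
}

# treatment-contrast design for a set of categorical columns
fixed_design <- function(records, cols) {
  df <- records[, cols, drop = FALSE]
  df[] <- lapply(df, function(x) factor(as.character(x)))
  stats::model.matrix(~ ., data = df)
}

#' Fit the bivariate fescue-status model
#'
#' Hair shedding recorded while grazing and while not grazing toxic
#' fescue are treated as two traits of the same animal. The genetic
#' covariance across statuses is free (`Var(u) = G0 %x% K`), permanent
#' environment is status-specific with its covariance fixed at zero, and
#' the residual covariance is likewise fixed at zero because the two
#' statuses are never observed on the same record (a free residual
#' covariance would be unidentifiable here).
#'
#' @param records records with `animal_id`, `score`, `fescue_status`
#'   ("yes"/"no") and a contemporary-group column `cg`.
#' @param precision sparse relationship precision over all animals.
#' @param cg contemporary-group column name.
#' @param start list with `Gamma` (2x2 genetic start), `var_pe` (length
#'   2), `var_e` (length 2).
#' @param tol,max_iter REML controls.
#' @return A list of class `fescue_fit` with the `reml_fit`, the genetic
#'   covariance `G0`, the genetic correlation `r_g` (+ SE), per-status
#'   heritability and repeatability, and per-status EBV tables.
#' @export
fit_bivariate_fescue <- function(records, precision, cg = "cg",
                                 start = list(Gamma = matrix(c(0.3, 0.15,
                                                               0.15, 0.3),
                                                             2, 2),
                                              var_pe = c(0.1, 0.1),
                                              var_e = c(0.5, 0.5)),
                                 tol = 1e-8, max_iter = 200L) {
  st <- factor(records$fescue_status, levels = c("yes", "no"))
  if (any(is.na(st))) stop("fescue_status must be yes/no")
  if (nlevels(droplevels(st)) < 2L)
    warning("only one fescue status present; model reduces to univariate")
  animals <- rownames(precision)
  trait <- as.integer(st)
  X <- stats::model.matrix(~ 0 + factor(as.character(records[[cg]])))
  colnames(X) <- sub("^factor\\(.*\\)\\)?", "cg", colnames(X))
  yes_map <- ifelse(trait == 1L, match(records$animal_id, animals), NA)
  no_map <- ifelse(trait == 2L, match(records$animal_id, animals), NA)
  pheno_yes <- sort(unique(records$animal_id[trait == 1L]))
  pheno_no <- sort(unique(records$animal_id[trait == 2L]))
  Gamma0 <- start$Gamma
  dimnames(Gamma0) <- rep(list(c("yes", "no")), 2)
  terms <- list(
    ran_term("u", animals, list(yes = yes_map, no = no_map),
             Kinv = precision, Gamma = Gamma0),
    ran_term("pe_yes", pheno_yes,
             list(yes = ifelse(trait == 1L,
                               match(records$animal_id, pheno_yes), NA)),
             Kinv = NULL, Gamma = matrix(start$var_pe[1], 1, 1)),
    ran_term("pe_no", pheno_no,
             list(no = ifelse(trait == 2L,
                              match(records$animal_id, pheno_no), NA)),
             Kinv = NULL, Gamma = matrix(start$var_pe[2], 1, 1)))
  sys <- build_mme(records$score, X, terms, trait = trait,
                   var_e = start$var_e)
  fit <- reml_estimate(sys, tol = tol, max_iter = max_iter)
  G0 <- fit$gammas[[1]]
  # slice of the parameter covariance belonging to the genetic block
  rg <- genetic_correlation(G0, 1L, 2L,
                            vcov_vech = fit$theta_vcov[1:3, 1:3,
                                                       drop = FALSE])
  by_status <- lapply(1:2, function(s) {
    va <- G0[s, s]
    vpe <- fit$gammas[[s + 1L]][1, 1]
    ve <- fit$var_e[s]
    c(var_a = va, var_pe = vpe, var_e = ve,
      h2 = va / (va + vpe + ve),
      repeatability = (va + vpe) / (va + vpe + ve))
  })
  names(by_status) <- c("yes", "no")
  ebv <- lapply(1:2, function(s) {
    data.frame(animal = animals, ebv = unname(fit$random$u[[s]]),
               pev = unname(fit$pev$u[[s]]))
  })
  names(ebv) <- c("yes", "no")
  structure(list(fit = fit, G0 = G0, r_g = rg$r_g, r_g_se = rg$se,
                 by_status = by_status, ebv = ebv),
            class = "fescue_fit")
}

#' Fit the maternal-effect hair shedding / weaning weight model
#'
#' Bivariate model linking a dam's hair shedding score to the weaning
#' weight of the calf she weaned that year. The genetic term is a 3x3
#' covariance over (dam hair shedding, maternal weaning weight, calf
#' direct weaning weight) so the hair-shedding/maternal correlation and
#' the direct/maternal correlation are both estimated; hair shedding has
#' no direct (calf) genetic effect. The cow's permanent-environment
#' block is 2x2 with free covariance. Residual covariance across the two
#' record types is fixed at zero; the dam-year tie enters through the
#' shared cow effects. Calves with missing weights (dummy calves)
#' contribute no residual row but stay estimable through relatives.
#'
#' @param hs_records dam score records: `animal_id`, `score`, `cg`.
#' @param ww_records calf records: `calf_id`, `dam_id`, `weight`
#'   (NA = dummy calf), `cg`.
#' @param precision sparse relationship precision over all animals
#'   (including calves).
#' @param start list with `Gamma` (3x3: hs, ww_m, ww_d), `Mpe` (2x2),
#'   `var_e` (length 2: hs, ww). The defaults are literature-informed
#'   values typical of Angus field data (hair-shedding additive variance
#'   0.40, maternal/direct weaning-weight variances 160 / 350 kg^2 with
#'   moderately negative correlations), which shortens the REML path.
#' @param tol,max_iter REML controls.
#' @return A list of class `maternal_fit` with the `reml_fit`, the
#'   genetic covariance `G0`, and the genetic correlations
#'   `r_g_hs_maternal`, `r_g_direct_maternal`, `r_g_hs_direct` (+ SEs).
#' @export
fit_maternal_ww <- function(hs_records, ww_records, precision,
                            start = list(
                              Gamma = outer(sqrt(c(0.40, 160, 350)),
                                            sqrt(c(0.40, 160, 350))) *
                                matrix(c(1, -0.19, -0.03,
                                         -0.19, 1, -0.43,
                                         -0.03, -0.43, 1), 3, 3),
                              Mpe = diag(c(0.04, 90)),
                              var_e = c(0.56, 400)),
                            tol = 1e-8, max_iter = 200L) {
  obs <- !is.na(ww_records$weight)
  if (!any(obs)) stop("no weighed calves: dam-calf links missing")
  ww <- ww_records[obs, , drop = FALSE]
  y <- c(hs_records$score, ww$weight)
  trait <- rep(1:2, c(nrow(hs_records), nrow(ww)))
  cg <- c(paste0("hs:", hs_records$cg), paste0("ww:", ww$cg))
  X <- stats::model.matrix(~ 0 + factor(cg))
  animals <- rownames(precision)
  n <- length(y)
  hs_rows <- seq_len(nrow(hs_records))
  ww_rows <- nrow(hs_records) + seq_len(nrow(ww))
  map_of <- function(rows, ids) {
    m <- rep(NA_integer_, n)
    m[rows] <- match(ids, animals)
    m
  }
  dams <- sort(unique(c(hs_records$animal_id, ww$dam_id)))
  dam_map <- function(rows, ids) {
    m <- rep(NA_integer_, n)
    m[rows] <- match(ids, dams)
    m
  }
  Gamma0 <- start$Gamma
  dimnames(Gamma0) <- rep(list(c("hs", "ww_m", "ww_d")), 2)
  Mpe0 <- start$Mpe
  dimnames(Mpe0) <- rep(list(c("hs", "ww")), 2)
  terms <- list(
    ran_term("g", animals,
             list(hs = map_of(hs_rows, hs_records$animal_id),
                  ww_m = map_of(ww_rows, ww$dam_id),
                  ww_d = map_of(ww_rows, ww$calf_id)),
             Kinv = precision, Gamma = Gamma0),
    ran_term("mpe", dams,
             list(hs = dam_map(hs_rows, hs_records$animal_id),
                  ww = dam_map(ww_rows, ww$dam_id)),
             Kinv = NULL, Gamma = Mpe0))
  sys <- build_mme(y, X, terms, trait = trait, var_e = start$var_e)
  fit <- reml_estimate(sys, tol = tol, max_iter = max_iter, pev = FALSE)
  G0 <- fit$gammas[[1]]
  vc6 <- fit$theta_vcov[1:6, 1:6, drop = FALSE]
  r_hm <- genetic_correlation(G0, 1L, 2L, vcov_vech = vc6)
  r_dm <- genetic_correlation(G0, 3L, 2L, vcov_vech = vc6)
  r_hd <- genetic_correlation(G0, 1L, 3L, vcov_vech = vc6)
  structure(list(fit = fit, G0 = G0, Mpe = fit$gammas[[2]],
                 var_e = fit$var_e,
                 r_g_hs_maternal = r_hm$r_g, r_g_hs_maternal_se = r_hm$se,
                 r_g_direct_maternal = r_dm$r_g,
                 r_g_direct_maternal_se = r_dm$se,
                 r_g_hs_direct = r_hd$r_g, r_g_hs_direct_se = r_hd$se),
            class = "maternal_fit")
}

#' Compare fitted models by AIC and likelihood-ratio test
#'
#' Models differing in fixed effects are compared on their maximum
#' likelihood (REML likelihoods are not comparable across different
#' fixed-effect structures); models sharing fixed effects are compared
#' on the restricted likelihood. `AIC = -2 logL + 2 k`.
#'
#' @param fits named list of `reml_fit` (or `shed_fit`) objects sharing
#'   the same data.
#' @param k_fixed integer vector: number of estimated fixed effects per
#'   fit (used in the AIC penalty and LRT df).
#' @param use `"ml"` (default) or `"reml"` likelihoods.
#' @return A `data.frame` with logLik, k, AIC, and for each model after
#'   the first a likelihood-ratio statistic, df and `-log10(p)` against
#'   the preceding (nested) model.
#' @export
compare_models <- function(fits, k_fixed = NULL, use = c("ml", "reml")) {
  use <- match.arg(use)
  fits <- lapply(fits, function(f) if (inherits(f, "shed_fit")) f$fit else f)
  ll <- vapply(fits, function(f)
    if (use == "ml") f$logLik_ml else f$logLik, 0)
  if (anyNA(ll)) stop("a model lacks the requested likelihood")
  kv <- vapply(fits, `[[`, 0L, "n_params")
  kf <- k_fixed %||% vapply(fits, `[[`, 0L, "sys_p")
  k <- kv + if (use == "ml") kf else 0L
  aic <- -2 * ll + 2 * k
  out <- data.frame(model = names(fits) %||% paste0("m", seq_along(fits)),
                    logLik = ll, k = k, AIC = aic,
                    lrt = NA_real_, df = NA_integer_,
                    neg_log10_p = NA_real_)
  if (length(fits) > 1L) {
    for (i in 2:length(fits)) {
      stat <- 2 * (ll[i] - ll[i - 1L])
      df <- k[i] - k[i - 1L]
      if (df <= 0) next
      p <- stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
      out$lrt[i] <- stat
      out$df[i] <- df
      out$neg_log10_p[i] <- -log10(max(p, .Machine$double.xmin))
    }
  }
  out
}

#' Simple regression of calf weaning weight on dam hair shedding score
#'
#' Ordinary least squares on paired dam-year score / calf weight
#' observations, returning the slope in kilograms per score unit.
#'
#' @param dam_scores numeric dam hair shedding scores.
#' @param calf_weights numeric calf weaning weights, same length.
#' @return list with `slope`, `se`, `intercept`, `n`.
#' @export
phenotypic_regression <- function(dam_scores, calf_weights) {
  ok <- complete.cases(dam_scores, calf_weights)
  if (sum(ok) < 3L) stop("need at least 3 complete score/weight pairs")
  fit <- lm(calf_weights[ok] ~ dam_scores[ok])
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]),
       intercept = unname(sm[1, 1]), n = sum(ok))
}
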