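#' Simulate repeated hair-shedding score records
#'
#' Generates cow-year score records following the repeated-records animal
#' model the package fits: each record is the sum of a contemporary-group
#' effect, an age-class effect, a fescue grazing-status effect, the cow's
#' breeding value (gene-dropped through the pedigree with
#' Mendelian-sampling variance), her permanent-environment effect and a
#' fresh residual. Scores stay continuous by default; `score_scale =
#' "ordinal"` rounds them onto the 1-5 appraisal scale.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param config a [sim_config()] object.
#' @return A list of class `sim_phenotypes`: `records` (one row per
#'   cow-year with the covariates the preparation stage expects) and
#'   `truth` (true breeding values, permanent-environment effects,
#'   realized variance components, realized heritability and
#'   repeatability).
#' @export
simulate_phenotypes <- function(ped, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$var_additive) || is.null(config$var_pe) ||
      is.null(config$var_residual))
    stop_config("variance components must be set to simulate phenotypes")
  set.seed(derive_seed(config$seed, "phenotypes"))

  bv <- if (!is.null(ped$true_bv)) {
    setNames(ped$true_bv, ped$animal)
  } else {
    drop(sim_breeding_values(ped, matrix(config$var_additive, 1, 1)))
  }
  pe <- setNames(rnorm(nrow(ped), 0, sqrt(config$var_pe)), ped$animal)

  cows <- ped[ped$sex == "F" & ped$generation >= min(1L, config$n_generations), ,
              drop = FALSE]
  if (nrow(cows) == 0L) stop_config("no female animals available to score")
  farm <- setNames(sample(sprintf("F%02d", seq_len(config$n_farms)),
                          nrow(cows), replace = TRUE), cows$animal)
  nrec <- sample(seq(config$records_per_animal[1],
                     config$records_per_animal[2]),
                 nrow(cows), replace = TRUE)
  first_age <- sample(1:3, nrow(cows), replace = TRUE)

  rows <- vector("list", nrow(cows))
  for (i in seq_len(nrow(cows))) {
    a <- cows$animal[i]
    byear <- as.integer(format(cows$birth_date[i], "%Y"))
    years <- byear + seq(first_age[i], length.out = nrec[i])
    rows[[i]] <- data.frame(animal_id = a, year = years,
                            farm_id = farm[[a]],
                            sex = "F",
                            birth_date = cows$birth_date[i],
                            stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  rec <- rec[rec$year <= max(as.integer(format(cows$birth_date, "%Y"))) +
               config$n_years + 3L, , drop = FALSE]

  # farm-year scoring days (mid-May window); grazing status varies at the
  # pasture-group level, i.e. within farm-years, as producers report it
  fy <- unique(rec[, c("farm_id", "year")])
  fy$day <- sample(10:24, nrow(fy), replace = TRUE)
  k <- match(paste(rec$farm_id, rec$year),
             paste(fy$farm_id, fy$year))
  rec$fescue_status <- sample(c("yes", "no"), nrow(rec), replace = TRUE)
  rec$date <- as.Date(sprintf("%d-05-%02d", rec$year, fy$day[k]))

  age_days <- as.integer(rec$date - rec$birth_date)
  keep <- age_days >= 275L
  rec <- rec[keep, , drop = FALSE]
  age_days <- age_days[keep]
  cls <- vapply(age_days, function(d) assign_age_class(d)$four_class, "")
  age_eff <- unname(config$age_class_effects[cls])
  age_eff[is.na(age_eff)] <- 0

  rec$calving_season <- ifelse(as.integer(format(rec$birth_date, "%m")) <= 6,
                               "spring", "fall")
  # management (contemporary-group) effects are keyed without grazing
  # status so the fescue effect enters the records only through the
  # configured fixed effect
  cg_key <- paste(rec$farm_id, rec$year, rec$calving_season, cls, sep = "_")
  cg_levels <- unique(cg_key)
  cg_eff <- setNames(rnorm(length(cg_levels), 0, config$cg_effect_sd),
                     cg_levels)

  resid <- rnorm(nrow(rec), 0, sqrt(config$var_residual))
  score <- config$mean_score + cg_eff[cg_key] + age_eff +
    config$fescue_effect * (rec$fescue_status == "no") +
    bv[rec$animal_id] + pe[rec$animal_id] + resid
  if (config$score_scale == "ordinal")
    score <- pmin(5, pmax(1, round(score)))
  rec$score <- unname(score)
  rec$breeder_reported_age <- floor((age_days + 90) / 365)
  rec <- rec[, c("animal_id", "score", "date", "farm_id", "calving_season",
                 "fescue_status", "sex", "birth_date",
                 "breeder_reported_age")]
  rownames(rec) <- NULL

  scored <- unique(rec$animal_id)
  comp <- c(additive = var(bv[scored]), pe = var(pe[scored]),
            residual = var(resid))
  truth <- list(true_bv = data.frame(animal = ped$animal, trait = "hs",
                                     true_bv = unname(bv[ped$animal])),
                true_pe = data.frame(animal = ped$animal,
                                     true_pe = unname(pe[ped$animal])),
                true_fixed = list(cg = cg_eff,
                                  age = config$age_class_effects,
                                  fescue = config$fescue_effect),
                realized_components = comp,
                realized_h2 = comp[["additive"]] / sum(comp),
                realized_repeatability =
                  (comp[["additive"]] + comp[["pe"]]) / sum(comp))
  structure(list(records = rec, truth = truth), class = "sim_phenotypes")
}

#' Simulate hair shedding as two status-traits
#'
#' Treats hair shedding recorded while grazing versus not grazing toxic
#' fescue as two genetically correlated traits, the structure assumed by
#' the bivariate repeated-records model. Defaults are the estimates of
#' that model on real data: additive variances 0.38 (grazing) and 0.30
#' (not grazing), permanent-environment and residual variances derived
#' from the phenotypic variances 0.90 / 0.95 and repeatabilities
#' 0.45 / 0.34, and a genetic correlation of 0.93. Grazing status is
#' drawn per cow-year, so some cows carry records under both statuses.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param config a [sim_config()] object (pedigree/recording structure).
#' @param var_a,var_pe,var_e named per-status variance components
#'   (`yes`/`no`).
#' @param genetic_corr genetic correlation between the two status-traits.
#' @return A list of class `sim_fescue`: `records` (with `fescue_status`
#'   marking the trait) and `truth` (per-status true breeding values and
#'   the genetic covariance matrix).
#' @export
simulate_fescue_traits <- function(ped, config,
                                   var_a = c(yes = 0.38, no = 0.30),
                                   var_pe = c(yes = 0.025, no = 0.023),
                                   var_e = c(yes = 0.495, no = 0.627),
                                   genetic_corr = 0.93) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "fescue"))
  cov_g <- genetic_corr * sqrt(var_a[["yes"]] * var_a[["no"]])
  Gamma <- matrix(c(var_a[["yes"]], cov_g, cov_g, var_a[["no"]]), 2, 2,
                  dimnames = rep(list(c("yes", "no")), 2))
  if (!is_psd(Gamma)) stop_config("genetic covariance is not PSD")
  bv <- sim_breeding_values(ped, Gamma)
  pe <- cbind(yes = rnorm(nrow(ped), 0, sqrt(var_pe[["yes"]])),
              no = rnorm(nrow(ped), 0, sqrt(var_pe[["no"]])))
  rownames(pe) <- ped$animal

  cows <- ped[ped$sex == "F" & ped$generation >= 1L, , drop = FALSE]
  farm <- setNames(sample(sprintf("F%02d", seq_len(config$n_farms)),
                          nrow(cows), replace = TRUE), cows$animal)
  nrec <- sample(seq(config$records_per_animal[1],
                     config$records_per_animal[2]),
                 nrow(cows), replace = TRUE)
  rows <- vector("list", nrow(cows))
  for (i in seq_len(nrow(cows))) {
    byear <- as.integer(format(cows$birth_date[i], "%Y"))
    years <- byear + seq(sample(2:3, 1L), length.out = nrec[i])
    rows[[i]] <- data.frame(animal_id = cows$animal[i], year = years,
                            farm_id = farm[[cows$animal[i]]],
                            stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  rec$fescue_status <- sample(c("yes", "no"), nrow(rec), replace = TRUE)
  rec$cg <- paste(rec$farm_id, rec$year, rec$fescue_status, sep = "_")
  cg_levels <- unique(rec$cg)
  cg_eff <- setNames(rnorm(length(cg_levels), 0, config$cg_effect_sd),
                     cg_levels)
  st <- rec$fescue_status
  rec$score <- config$mean_score + cg_eff[rec$cg] +
    bv[cbind(rec$animal_id, st)] + pe[cbind(rec$animal_id, st)] +
    rnorm(nrow(rec), 0, sqrt(unname(var_e[st])))
  rec$score <- unname(rec$score)
  rownames(rec) <- NULL
  structure(list(records = rec,
                 truth = list(true_bv = bv, true_pe = pe, Gamma = Gamma,
                              var_pe = var_pe, var_e = var_e)),
            class = "sim_fescue")
}

#' Simulate linked dam hair-shedding and calf weaning-weight records
#'
#' Emulates the maternal-effect design: each dam-year yields one hair
#' shedding record for the dam and one weaning-weight record for the calf
#' she weaned that year, and every scored cow also carries her own
#' weaning-weight record as a calf of her pedigree dam -- animals
#' appearing in both the direct and the maternal role are what identify
#' the direct-maternal genetic covariance. The genetic truth is a 3x3
#' covariance over (dam hair shedding, maternal weaning weight, calf
#' direct weaning weight) gene-dropped through the pedigree, so the
#' correlation between a dam's shedding and the maternal component of
#' weaning weight -- and between the direct and maternal components --
#' is under direct control. Calf sires are reused across matings (a
#' small service-sire pool), giving paternal half-sib families. Dams
#' without a weighed calf in a scored year receive a dummy calf with
#' missing weight and unknown sire, keeping the dam-year link estimable.
#'
#' @param ped base pedigree from [simulate_pedigree()].
#' @param config a [sim_config()] object; see its `ww` argument.
#' @return A list of class `sim_ww`: `hs_records`, `ww_records` (weight
#'   `NA` for dummy calves), `ped` (base pedigree extended with calves)
#'   and `truth` (true effects and the genetic covariance used).
#' @export
simulate_ww_bivariate <- function(ped, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "ww"))
  w <- config$ww
  sds <- sqrt(c(config$var_additive, w$var_maternal, w$var_direct))
  R <- matrix(c(1, w$corr_hs_maternal, w$corr_hs_direct,
                w$corr_hs_maternal, 1, w$corr_direct_maternal,
                w$corr_hs_direct, w$corr_direct_maternal, 1), 3, 3)
  Gamma <- diag(sds) %*% R %*% diag(sds)
  dimnames(Gamma) <- rep(list(c("hs", "ww_m", "ww_d")), 2)
  if (!is_psd(Gamma))
    stop_config("genetic covariance for the maternal design is not PSD")

  dams <- ped[ped$sex == "F" & ped$generation >= 1L, , drop = FALSE]
  if (nrow(dams) == 0L) stop_config("no dams available")
  males <- ped$animal[ped$sex == "M"]
  sires_pool <- sample(males, max(2L, ceiling(nrow(dams) / 8)))
  nrec <- sample(seq(config$records_per_animal[1],
                     config$records_per_animal[2]),
                 nrow(dams), replace = TRUE)
  first_age <- sample(2:3, nrow(dams), replace = TRUE)

  links <- vector("list", nrow(dams))
  for (i in seq_len(nrow(dams))) {
    byear <- as.integer(format(dams$birth_date[i], "%Y"))
    years <- byear + seq(first_age[i], length.out = nrec[i])
    links[[i]] <- data.frame(dam = dams$animal[i], year = years,
                             stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, links)
  links$weighed <- runif(nrow(links)) < w$p_calf_weighed
  links$calf <- sprintf("C%05d", seq_len(nrow(links)))
  links$sire <- ifelse(links$weighed,
                       sample(sires_pool, nrow(links), replace = TRUE),
                       NA_character_)

  calves <- data.frame(animal = links$calf, sire = links$sire,
                       dam = links$dam, sex = "M",
                       generation = max(ped$generation) + 1L,
                       birth_date = as.Date(sprintf("%d-03-01", links$year)),
                       stringsAsFactors = FALSE)
  ped_ext <- rbind(ped[, names(calves)], calves)

  bv <- sim_breeding_values(ped_ext, Gamma)
  # maternal permanent-environment effects for every animal that can
  # appear in the dam role (scored dams and their own dams)
  mothers <- unique(c(dams$animal,
                      na.omit(normalize_parent(dams$dam))))
  mpe <- cbind(hs = rnorm(length(mothers), 0, sqrt(config$var_pe)),
               ww = rnorm(length(mothers), 0, sqrt(w$var_mpe)))
  rownames(mpe) <- mothers

  farm <- setNames(sample(sprintf("F%02d", seq_len(config$n_farms)),
                          nrow(dams), replace = TRUE), dams$animal)
  links$farm <- farm[links$dam]
  fy <- unique(links[, c("farm", "year")])
  fy$cg_hs <- rnorm(nrow(fy), 0, config$cg_effect_sd)
  fy$cg_ww <- rnorm(nrow(fy), 0, w$cg_sd)
  k <- match(paste(links$farm, links$year), paste(fy$farm, fy$year))

  hs <- data.frame(animal_id = links$dam,
                   score = config$mean_score + fy$cg_hs[k] +
                     bv[links$dam, "hs"] + mpe[links$dam, "hs"] +
                     rnorm(nrow(links), 0, sqrt(config$var_residual)),
                   year = links$year, farm_id = links$farm,
                   cg = paste(links$farm, links$year, "hs", sep = "_"),
                   stringsAsFactors = FALSE)
  ww <- data.frame(calf_id = links$calf, dam_id = links$dam,
                   weight = ifelse(links$weighed,
                                   w$mean + fy$cg_ww[k] +
                                     bv[links$calf, "ww_d"] +
                                     bv[links$dam, "ww_m"] +
                                     mpe[links$dam, "ww"] +
                                     rnorm(nrow(links), 0,
                                           sqrt(w$var_residual)),
                                   NA_real_),
                   year = links$year, farm_id = links$farm,
                   cg = paste(links$farm, links$year, "ww", sep = "_"),
                   stringsAsFactors = FALSE)

  # own weaning weight of each scored cow, recorded in her birth cohort
  own <- dams[!is.na(normalize_parent(dams$dam)), , drop = FALSE]
  if (nrow(own)) {
    own_year <- as.integer(format(own$birth_date, "%Y"))
    own_farm <- farm[own$animal]
    own_cg <- paste(own_farm, own_year, "ww0", sep = "_")
    cg0 <- setNames(rnorm(length(unique(own_cg)), 0, w$cg_sd),
                    unique(own_cg))
    own_dam <- normalize_parent(own$dam)
    ww_own <- data.frame(calf_id = own$animal, dam_id = own_dam,
                         weight = w$mean + cg0[own_cg] +
                           bv[own$animal, "ww_d"] +
                           bv[own_dam, "ww_m"] +
                           mpe[own_dam, "ww"] +
                           rnorm(nrow(own), 0, sqrt(w$var_residual)),
                         year = own_year, farm_id = own_farm,
                         cg = own_cg, stringsAsFactors = FALSE)
    ww <- rbind(ww, ww_own)
  }
  rownames(ww) <- NULL
  truth <- list(true_bv = bv, true_mpe = mpe, Gamma = Gamma,
                links = links)
  structure(list(hs_records = hs, ww_records = ww, ped = ped_ext,
                 truth = truth), class = "sim_ww")
}
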