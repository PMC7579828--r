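#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the
#' synthetic-data generators. Defaults reproduce the structure of the
#' hair-shedding study population the package's models were designed for:
#' a multi-generation pedigree, roughly half of animals genotyped, one to
#' three yearly scores per cow, contemporary groups built from
#' farm x year x season x fescue status x age group x score group, a
#' U-shaped age effect, a fescue grazing-status effect of -0.59 score
#' units, and additive / permanent-environment / residual variances of
#' 0.40 / 0.04 / 0.56 (heritability 0.40, repeatability 0.44).
#'
#' @param n_founders number of founder animals (half female).
#' @param n_generations number of generations bred after the founders.
#' @param progeny_per_dam progeny produced per dam per generation.
#' @param genotyped_fraction proportion of animals carrying genotypes.
#' @param n_snps number of simulated unlinked SNPs.
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param var_additive additive genetic variance (score units squared).
#' @param var_pe permanent-environment variance.
#' @param var_residual residual variance.
#' @param genetic_corr genetic correlation matrix when simulating several
#'   correlated traits (unit diagonal, positive semi-definite).
#' @param fescue_effect fixed effect of not grazing toxic fescue, in score
#'   units (grazing animals are the baseline).
#' @param age_class_effects named vector of age-class effects (classes
#'   "1","2","3","other"), score units.
#' @param n_farms,n_years number of farms and scoring years.
#' @param cg_effect_sd standard deviation of contemporary-group effects.
#' @param records_per_animal integer vector `c(min, max)` of scored years
#'   per cow.
#' @param mean_score intercept on the 1-5 score scale.
#' @param score_scale `"continuous"` (default) keeps scores on the linear
#'   scale for clean parameter recovery; `"ordinal"` thresholds them into
#'   integers 1-5.
#' @param selection `"none"` (default) mates at random; `"truncation"`
#'   selects the later-shedding half of each generation as parents, a
#'   negative control for LR-method calibration.
#' @param ww weaning-weight settings used by [simulate_ww_bivariate()]:
#'   a list with direct/maternal/permanent-environment/residual variances
#'   (kg^2), the genetic correlations tying hair shedding to the maternal
#'   component, and the calf-weighing probability.
#' @param seed integer seed; identical configuration implies bit-identical
#'   simulated output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_founders = 100L,
                       n_generations = 3L,
                       progeny_per_dam = 2L,
                       genotyped_fraction = 0.5,
                       n_snps = 1000L,
                       maf_range = c(0.05, 0.5),
                       var_additive = 0.40,
                       var_pe = 0.04,
                       var_residual = 0.56,
                       genetic_corr = NULL,
                       fescue_effect = -0.59,
                       age_class_effects = c(`1` = 0.30, `2` = 0.45,
                                             `3` = 0.25, other = 0),
                       n_farms = 8L,
                       n_years = 3L,
                       cg_effect_sd = 0.30,
                       records_per_animal = c(1L, 3L),
                       mean_score = 3.0,
                       score_scale = c("continuous", "ordinal"),
                       selection = c("none", "truncation"),
                       ww = list(var_direct = 350, var_maternal = 160,
                                 var_mpe = 90, var_residual = 400,
                                 mean = 250, cg_sd = 15,
                                 corr_hs_maternal = -0.19,
                                 corr_direct_maternal = -0.43,
                                 corr_hs_direct = -0.03,
                                 p_calf_weighed = 0.85),
                       seed = 1L) {
  score_scale <- match.arg(score_scale)
  selection <- match.arg(selection)
  if (n_founders < 2L) stop_config("n_founders must be at least 2")
  if (n_generations < 0L) stop_config("n_generations must be >= 0")
  if (progeny_per_dam < 1L) stop_config("progeny_per_dam must be >= 1")
  if (genotyped_fraction < 0 || genotyped_fraction > 1)
    stop_config("genotyped_fraction must lie in [0, 1]")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_config("maf_range must be an increasing pair within (0, 0.5]")
  vars <- c(var_additive = var_additive, var_pe = var_pe,
            var_residual = var_residual)
  if (any(vars < 0)) stop_config("variance components must be >= 0")
  if (!is.null(genetic_corr)) {
    if (!is_psd(genetic_corr) || any(abs(diag(genetic_corr) - 1) > 1e-8))
      stop_config("genetic_corr must be symmetric PSD with unit diagonal")
  }
  if (length(records_per_animal) != 2L ||
      records_per_animal[1] < 1L ||
      records_per_animal[1] > records_per_animal[2])
    stop_config("records_per_animal must be c(min, max) with 1 <= min <= max")
  defaults <- eval(formals(sim_config)$ww)
  ww <- utils::modifyList(defaults, ww %||% list())
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              progeny_per_dam = as.integer(progeny_per_dam),
              genotyped_fraction = genotyped_fraction,
              n_snps = as.integer(n_snps),
              maf_range = maf_range,
              var_additive = var_additive,
              var_pe = var_pe,
              var_residual = var_residual,
              genetic_corr = genetic_corr,
              fescue_effect = fescue_effect,
              age_class_effects = age_class_effects,
              n_farms = as.integer(n_farms),
              n_years = as.integer(n_years),
              cg_effect_sd = cg_effect_sd,
              records_per_animal = as.integer(records_per_animal),
              mean_score = mean_score,
              score_scale = score_scale,
              selection = selection,
              ww = ww,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}
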