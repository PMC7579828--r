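#' Simulate a multi-generation pedigree
#'
#' Breeds `n_generations` discrete generations from a founder population by
#' random mating (each dam mated to one randomly drawn sire of her own
#' generation, `progeny_per_dam` offspring each). With
#' `selection = "truncation"` the later-shedding half of each sex is used
#' as parents instead, selecting on a simulated true breeding value; this
#' deliberately violates the no-selection assumption of the LR-method
#' calibration and serves as a negative control.
#'
#' @param config a [sim_config()] object.
#' @return A `data.frame` with columns `animal`, `sire`, `dam`, `sex`
#'   ("F"/"M"), `generation` and `birth_date`; parents always precede their
#'   offspring. Under truncation selection an extra `true_bv` column holds
#'   the breeding values selection acted on, which
#'   [simulate_phenotypes()] then reuses.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "pedigree"))
  nf <- config$n_founders
  sex <- rep(c("F", "M"), length.out = nf)
  ped <- data.frame(animal = sprintf("A%05d", seq_len(nf)),
                    sire = NA_character_, dam = NA_character_,
                    sex = sex, generation = 0L,
                    stringsAsFactors = FALSE)
  select_on_bv <- identical(config$selection, "truncation")
  if (select_on_bv) {
    ped$true_bv <- rnorm(nf, 0, sqrt(config$var_additive))
  }
  next_id <- nf + 1L
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1L, , drop = FALSE]
    dams <- prev[prev$sex == "F", , drop = FALSE]
    sires <- prev[prev$sex == "M", , drop = FALSE]
    if (nrow(dams) == 0L || nrow(sires) == 0L)
      stop_config("generation %d has no available %s", g - 1L,
                  if (nrow(dams) == 0L) "dams" else "sires")
    if (select_on_bv) {
      keep_top <- function(df) {
        n_keep <- max(1L, ceiling(nrow(df) / 2))
        df[order(df$true_bv, decreasing = TRUE)[seq_len(n_keep)], ,
           drop = FALSE]
      }
      dams <- keep_top(dams)
      sires <- keep_top(sires)
    }
    n_off <- nrow(dams) * config$progeny_per_dam
    dam_id <- rep(dams$animal, each = config$progeny_per_dam)
    sire_id <- sample(sires$animal, n_off, replace = TRUE)
    off <- data.frame(animal = sprintf("A%05d", seq(next_id,
                                                    next_id + n_off - 1L)),
                      sire = sire_id, dam = dam_id,
                      sex = sample(c("F", "M"), n_off, replace = TRUE),
                      generation = g, stringsAsFactors = FALSE)
    if (select_on_bv) {
      pa <- (ped$true_bv[match(off$sire, ped$animal)] +
               ped$true_bv[match(off$dam, ped$animal)]) / 2
      off$true_bv <- pa + rnorm(n_off, 0, sqrt(config$var_additive / 2))
    }
    ped <- rbind(ped, off)
    next_id <- next_id + n_off
  }
  # spring-weighted birth dates, one calendar year per generation
  months <- sample(c(2L, 3L, 4L, 9L, 10L), nrow(ped), replace = TRUE,
                   prob = c(0.25, 0.25, 0.2, 0.15, 0.15))
  ped$birth_date <- as.Date(sprintf("%d-%02d-%02d",
                                    2010L + 2L * ped$generation, months,
                                    sample(1:28, nrow(ped), replace = TRUE)))
  ped
}

# Gene-drop multi-trait breeding values down a pedigree.
# Gamma is the t x t genetic covariance; Mendelian-sampling variance is
# 0.5 * Gamma * (1 - (F_s + F_d)/2) using pedigree inbreeding coefficients.
# Returns a matrix (animals x traits) in pedigree order.
sim_breeding_values <- function(ped, Gamma) {
  Gamma <- as.matrix(Gamma)
  t_k <- ncol(Gamma)
  n <- nrow(ped)
  L <- t(chol(Gamma + diag(1e-12, t_k)))
  f <- inbreeding(ped)
  bv <- matrix(0, n, t_k)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  z <- matrix(rnorm(n * t_k), n, t_k)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) && is.na(d)) {
      bv[i, ] <- L %*% z[i, ]
    } else {
      pa <- 0; fpar <- 0; known <- 0L
      if (!is.na(s)) { pa <- pa + bv[s, ]; fpar <- fpar + f[s]; known <- known + 1L }
      if (!is.na(d)) { pa <- pa + bv[d, ]; fpar <- fpar + f[d]; known <- known + 1L }
      pa <- pa / 2
      ms_scale <- if (known == 2L) 0.5 * (1 - fpar / 2) else 0.75
      bv[i, ] <- pa + sqrt(ms_scale) * (L %*% z[i, ])
    }
  }
  dimnames(bv) <- list(ped$animal, colnames(Gamma))
  bv
}
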