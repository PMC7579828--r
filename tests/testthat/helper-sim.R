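# Shared fixture builders: everything is generated in code at test time.

# a small pedigree + scored records + sparse A-inverse
small_study <- function(seed = 1, n_founders = 150, n_generations = 3,
                        n_farms = 3, ...) {
  cfg <- sim_config(n_founders = n_founders,
                    n_generations = n_generations,
                    n_farms = n_farms, seed = seed, ...)
  ped <- simulate_pedigree(cfg)
  phen <- simulate_phenotypes(ped, cfg)
  meta <- data.frame(animal = ped$animal, sex = ped$sex,
                     birth_date = ped$birth_date)
  prep <- prep_records(phen$records, meta)
  list(cfg = cfg, ped = ped, phen = phen, records = prep$records,
       ainv = a_inverse(ped))
}

# hand-built pedigree data.frame
ped_df <- function(animal, sire = NA, dam = NA) {
  data.frame(animal = animal,
             sire = rep_len(as.character(sire), length(animal)),
             dam = rep_len(as.character(dam), length(animal)),
             stringsAsFactors = FALSE)
}

# random valid pedigree of n animals (parents drawn among earlier animals)
random_pedigree <- function(n, seed = 1, p_known = 0.7) {
  set.seed(seed)
  animal <- sprintf("R%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (runif(1) < p_known) {
      pool <- seq_len(i - 1L)
      sire[i] <- animal[sample(pool, 1)]
      dam_i <- sample(pool, 1)
      if (animal[dam_i] != sire[i]) dam[i] <- animal[dam_i]
    }
  }
  data.frame(animal = animal, sire = sire, dam = dam,
             stringsAsFactors = FALSE)
}

# dense GLS oracle: solutions of the mixed model computed from the
# variance of y directly (V = sum Z G Z' + R), independent of the MME path
gls_oracle <- function(y, X, Zs, Gs, R) {
  V <- R
  for (k in seq_along(Zs)) V <- V + Zs[[k]] %*% Gs[[k]] %*% t(Zs[[k]])
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  resid <- y - X %*% beta
  u <- lapply(seq_along(Zs), function(k)
    Gs[[k]] %*% t(Zs[[k]]) %*% Vi %*% resid)
  list(beta = drop(beta), u = lapply(u, drop))
}

# brute-force Benjamini-Hochberg step-up, written independently of the
# package implementation
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (r in m:1) {
    val <- min(prev, p[o[r]] * m / r)
    q[o[r]] <- val
    prev <- val
  }
  q
}
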