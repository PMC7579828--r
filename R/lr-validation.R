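#' Random whole/partial partitions for LR-method validation
#'
#' Draws `n_iter` independent partitions of the phenotyped animals:
#' in each, a random `fraction` of animals form the validation set and
#' have all their phenotypes masked when fitting the partial model.
#' Partitioning is by animal, so every repeated record of a validation
#' animal is masked together.
#'
#' @param animals character vector of phenotyped animal ids.
#' @param n_iter number of iterations (default 10).
#' @param fraction proportion of animals masked (default 0.25).
#' @param seed integer seed.
#' @return A list of partitions, each with `iteration`, `validation`,
#'   `reference`.
#' @export
make_partitions <- function(animals, n_iter = 10L, fraction = 0.25,
                            seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  if (length(animals) < 8L)
    stop("need at least 8 phenotyped animals to partition")
  set.seed(seed)
  n_val <- round(length(animals) * fraction)
  lapply(seq_len(n_iter), function(i) {
    val <- sample(animals, n_val)
    list(iteration = i, validation = sort(val),
         reference = sort(setdiff(animals, val)))
  })
}

#' LR-method statistics for one whole/partial comparison
#'
#' For both the validation and the reference set: `d` is the mean
#' difference between whole and partial breeding values (its absolute
#' value is the bias statistic), `b` is the slope of the regression of
#' whole on partial breeding values (dispersion; expectation 1), and
#' `rho` is their Pearson correlation (the validation-set value is the
#' prediction accuracy).
#'
#' @param whole_ebv named numeric vector of whole-data EBVs.
#' @param partial_ebv named numeric vector of partial-data EBVs.
#' @param scheme one partition from [make_partitions()].
#' @return A one-row `data.frame` with `d_val`, `d_ref`, `b_val`,
#'   `b_ref`, `rho_val`, `rho_ref`.
#' @export
lr_stats <- function(whole_ebv, partial_ebv, scheme) {
  one_set <- function(ids) {
    w <- whole_ebv[ids]
    p <- partial_ebv[ids]
    if (any(is.na(w)) || any(is.na(p)))
      stop("EBV tables do not cover the partition")
    d_raw <- mean(w - p)
    if (var(p) <= 0)
      return(c(d = abs(d_raw), d_raw = d_raw, b = NA_real_,
               rho = NA_real_))
    c(d = abs(d_raw), d_raw = d_raw,
      b = unname(coef(lm(w ~ p))[2]),
      rho = cor(w, p))
  }
  v <- one_set(scheme$validation)
  r <- one_set(scheme$reference)
  data.frame(iteration = scheme$iteration,
             d_val = v[["d"]], d_ref = r[["d"]],
             d_val_signed = v[["d_raw"]], d_ref_signed = r[["d_raw"]],
             b_val = v[["b"]], b_ref = r[["b"]],
             rho_val = v[["rho"]], rho_ref = r[["rho"]])
}

#' Run the full LR-method validation
#'
#' Fits the whole model once (estimating variance components by REML
#' unless supplied), then refits breeding values with each partition's
#' validation phenotypes excluded, reusing the whole-data variance
#' components, and summarizes the LR statistics across iterations.
#'
#' @param records prepared records (`animal_id`, `score`, `cg_id`).
#' @param precision sparse relationship precision.
#' @param n_iter,fraction,seed see [make_partitions()].
#' @param varcomp optional `c(var_a, var_pe, var_e)`; skips whole-data
#'   REML.
#' @param cg contemporary-group column.
#' @return A list of class `lr_validation`: `per_iteration`
#'   `data.frame`, `summary` (means and ranges), and the whole-data fit.
#' @export
run_lr_validation <- function(records, precision, n_iter = 10L,
                              fraction = 0.25, seed = 1L,
                              varcomp = NULL, cg = "cg_id") {
  whole <- fit_univariate(records, precision, cg = cg, varcomp = varcomp)
  vc <- unname(whole$varcomp)
  whole_ebv <- setNames(whole$ebv$ebv, whole$ebv$animal)
  animals <- unique(records$animal_id)
  parts <- make_partitions(animals, n_iter = n_iter, fraction = fraction,
                           seed = seed)
  per_iter <- do.call(rbind, lapply(parts, function(sc) {
    keep <- !(records$animal_id %in% sc$validation)
    sub <- records[keep, , drop = FALSE]
    partial <- fit_univariate(sub, precision, cg = cg, varcomp = vc,
                              pev = FALSE)
    partial_ebv <- setNames(partial$ebv$ebv, partial$ebv$animal)
    lr_stats(whole_ebv, partial_ebv, sc)
  }))
  summ <- data.frame(
    stat = names(per_iter)[-1],
    mean = vapply(per_iter[, -1], mean, 0, na.rm = TRUE),
    min = vapply(per_iter[, -1], min, 0, na.rm = TRUE),
    max = vapply(per_iter[, -1], max, 0, na.rm = TRUE))
  rownames(summ) <- NULL
  structure(list(per_iteration = per_iter, summary = summ,
                 whole = whole), class = "lr_validation")
}
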