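#' @import Matrix
#' @importFrom methods as is new
#' @importFrom stats aggregate as.formula coef cor lm na.omit optim pnorm
#'   pchisq rbinom rnorm runif sd setNames var vcov p.adjust qnorm
#'   complete.cases model.matrix
#' @importFrom utils read.table write.table modifyList
#' @importFrom tools md5sum
NULL

# sentinel used for unknown parents throughout the package
NA_PARENT <- NA_character_

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a pipeline seed
#'
#' Deterministically maps a top-level seed and a stage label to a
#' 32-bit-safe integer seed, so every stage of a pipeline run has its own
#' reproducible stream.
#'
#' @param seed integer top-level seed.
#' @param stage character stage label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(as.integer(charToRaw(as.character(stage))) *
             (seq_along(charToRaw(as.character(stage))) %% 31L + 1L))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# normalize a parent id column: "", "0", NA all mean unknown
normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# symmetric positive semi-definite check with tolerance
is_psd <- function(m, tol = 1e-8) {
  if (!isSymmetric(unname(m), tol = 1e-7)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}
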