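#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generators are pure functions of
#' their `seed` argument and never disturb the caller's RNG stream. A `NULL`
#' seed leaves the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting keeps the 999-replicate nulls and permutation tests
#' reproducible from a single pipeline seed. Result is always < 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer seed.
#' @export
split_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 7919 + h * 104729) %% 2147483629L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# z-score a vector; errors on zero variance unless allow_constant
zscore <- function(x, label = "variable") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("zero variance in %s", label)
  (x - mean(x)) / s
}
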