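# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that generators are pure
#' functions of their `seed` argument without disturbing the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Stop unless a scalar satisfies a predicate
#' @noRd
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

#' Coerce an EBImage object or matrix to a plain matrix
#' @noRd
as_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}
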