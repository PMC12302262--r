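#' Normalise a preferred-term string
#'
#' Lowercases, trims surrounding whitespace and collapses internal runs of
#' whitespace, so that term matching is exact on the normalised form.
#'
#' @param x character vector of preferred terms.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_term("  Taste   Disorder ")
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_domain <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
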