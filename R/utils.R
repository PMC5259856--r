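# evaluate expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Normalize gene symbols for matching
#'
#' Upper-cases and strips surrounding whitespace, so symbols from different
#' species conventions (e.g. mouse \code{Abcd3} vs human \code{ABCD3}) and
#' hand-edited tables compare reliably.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalizeSymbols <- function(x) toupper(trimws(as.character(x)))

# row medians without extra dependencies; x is a numeric matrix
rowMedians_ <- function(x) apply(x, 1L, stats::median)
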