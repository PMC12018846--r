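#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream of reproducible sub-seeds from one master seed.
#'
#' Keeps every derived seed in the 32-bit signed integer range so it can be
#' passed back to [set.seed()].
#' @noRd
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Canonical unordered hybrid identifier "parent1/parent2".
#' @noRd
hybrid_id <- function(p1, p2) {
  a <- pmin(p1, p2)
  b <- pmax(p1, p2)
  paste(a, b, sep = "/")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
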