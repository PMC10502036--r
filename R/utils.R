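#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministically mix a base seed with a stream index
#'
#' All randomness in the package funnels through one user-visible seed;
#' independent streams (per-sample generation, per-epoch shuffling) derive
#' their own 31-bit seeds from it so that prefixes of a run are reproducible
#' in isolation.
#'
#' @param seed integer base seed.
#' @param index non-negative integer stream index.
#' @return an integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
mix_seed <- function(seed, index = 0L) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807 + 1
  as.integer(s %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

# promote a (H,W,C) array to (1,H,W,C); remember whether it had a batch axis
with_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a vector", call. = FALSE)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) == 3L) {
    x <- array(x, dim = c(d, 1L))          # (H,W,C) -> (H,W,C,1)
    x <- aperm(x, c(4L, 1L, 2L, 3L))       # -> (1,H,W,C)
    attr(x, "had_batch") <- FALSE
    return(x)
  }
  if (length(d) == 4L) {
    attr(x, "had_batch") <- TRUE
    return(x)
  }
  stop("expected a rank-3 (H,W,C) or rank-4 (N,H,W,C) array", call. = FALSE)
}

drop_batch <- function(x, had_batch) {
  if (had_batch) return(x)
  d <- dim(x)
  array(aperm(x, c(2L, 3L, 4L, 1L)), dim = d[2:4])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)
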