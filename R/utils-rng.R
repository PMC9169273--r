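#' Seeded random source
#'
#' A self-contained pseudo-random stream wrapping R's Mersenne-Twister.
#' Every stochastic operation in the package draws from one of these
#' objects, never from the global RNG, so the global `.Random.seed` is
#' left untouched and results are reproducible given the seed alone.
#'
#' @param seed single integer-valued seed.
#' @return an object of class `cd_rng`.
#' @export
cd_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  e$state <- local({
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    orig <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(abs(seed) %% 2147483646))
    s <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", orig, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    s
  })
  class(e) <- "cd_rng"
  e
}

#' Evaluate an expression with a cd_rng's stream installed
#'
#' Swaps the stream state in, evaluates, captures the advanced state and
#' restores the caller's global RNG state.
#'
#' @param rng a `cd_rng`.
#' @param expr expression using base R random functions.
#' @keywords internal
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "cd_rng"))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  orig <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", orig, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Seeded draws from a cd_rng
#'
#' Thin wrappers over base R draws that consume a [cd_rng()] stream:
#' `rng_runif` (uniform reals), `rng_int` (uniform integers in
#' `[lo, hi]`), `rng_pick` (uniform subset without replacement by
#' default) and `rng_bits` (fair coin bits).
#'
#' @param rng a [cd_rng()].
#' @param n number of draws.
#' @param min,max,lo,hi range bounds.
#' @param x vector or list to pick from.
#' @param replace pick with replacement.
#' @name rng_draws
NULL

#' @rdname rng_draws
#' @export
rng_runif <- function(rng, n = 1L, min = 0, max = 1) {
  with_rng(rng, stats::runif(n, min, max))
}

#' @rdname rng_draws
#' @export
rng_int <- function(rng, lo, hi, n = 1L) {
  with_rng(rng, lo + floor(stats::runif(n) * (hi - lo + 1)))
}

#' @rdname rng_draws
#' @export
rng_pick <- function(rng, x, n = 1L, replace = FALSE) {
  idx <- with_rng(rng, sample.int(length(x), n, replace = replace))
  x[idx]
}

#' @rdname rng_draws
#' @export
rng_bits <- function(rng, n) {
  as.integer(rng_runif(rng, n) < 0.5)
}

## ---- 32-bit arithmetic on doubles -----------------------------------------
## R has no native unsigned 32-bit integers; doubles represent integers up to
## 2^53 exactly, so 32-bit modular arithmetic is done via 16-bit half-words.

TWO32 <- 4294967296
TWO16 <- 65536

xor32 <- function(a, b) {
  ah <- a %/% TWO16; al <- a %% TWO16
  bh <- b %/% TWO16; bl <- b %% TWO16
  bitwXor(as.integer(ah), as.integer(bh)) * TWO16 +
    bitwXor(as.integer(al), as.integer(bl))
}

mul32 <- function(a, b) {
  ah <- a %/% TWO16; al <- a %% TWO16
  (((ah * b) %% TWO16) * TWO16 + al * b) %% TWO32
}

shr32 <- function(a, k) a %/% (2^k)

## lowbias32-style avalanche mix: a bijection on [0, 2^32), so distinct
## inputs always yield distinct outputs (collision-free seed streams).
mix32 <- function(x) {
  x <- x %% TWO32
  x <- xor32(x, shr32(x, 16))
  x <- mul32(x, 2135587861) # 0x7feb352d
  x <- xor32(x, shr32(x, 15))
  x <- mul32(x, 2222552459) # 0x846ca68b
  x <- xor32(x, shr32(x, 16))
  x
}

TWO31 <- 2147483648

## 31-bit variant: xorshifts and odd multiplications mod 2^31 are each
## bijective, so the composition is too. Outputs fit set.seed() directly.
mix31 <- function(x) {
  x <- x %% TWO31
  x <- xor32(x, shr32(x, 15))
  x <- mul32(x, 2135587861) %% TWO31
  x <- xor32(x, shr32(x, 14))
  x <- mul32(x, 76132347) %% TWO31   # odd
  x <- xor32(x, shr32(x, 16))
  x
}
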