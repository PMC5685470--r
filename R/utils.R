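#' Wrap angles into [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
wrap360 <- function(x) x %% 360

#' Signed circular difference in degrees
#'
#' Reduces an angular difference into the half-open interval `(-180, 180]`,
#' so the sign of the result is unambiguous.
#'
#' @param x numeric vector of angular differences in degrees.
#' @return equivalent differences in `(-180, 180]`.
#' @export
wrap180 <- function(x) {
  d <- x %% 360
  ifelse(d > 180, d - 360, d)
}

#' Circular mean of angles
#'
#' @param x angles in degrees.
#' @return mean direction in `[0, 360)`, or `NA` if the mean resultant
#'   length is (numerically) zero.
#' @export
circ_mean_deg <- function(x) {
  r <- x * pi / 180
  s <- mean(sin(r)); c <- mean(cos(r))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap360(atan2(s, c) * 180 / pi)
}

#' Circular standard deviation of angles
#'
#' Computed as `sqrt(-2 * log(Rbar))` where `Rbar` is the mean resultant
#' length, and converted to degrees.
#'
#' @param x angles in degrees.
#' @return circular SD in degrees (`Inf` when `Rbar` is zero).
#' @export
circ_sd_deg <- function(x) {
  r <- x * pi / 180
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  if (rbar <= 0) return(Inf)
  sqrt(-2 * log(rbar)) * 180 / pi
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.  NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset) %% 2147483629L)
}
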