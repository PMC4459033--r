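# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv())))
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  else
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index; stays within
# 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + as.double(k) * 9176) %% 2147483647L)
}

# Indices of grid values inside a closed interval; errors if empty.
closedIndices <- function(grid, interval, what = "interval") {
  stopifnot(length(interval) == 2L)
  idx <- which(grid >= min(interval) - 1e-9 & grid <= max(interval) + 1e-9)
  if (!length(idx))
    stop(what, " [", interval[1L], ", ", interval[2L],
         "] does not intersect the available grid", call. = FALSE)
  idx
}

# Wrap angles into (-pi, pi].
wrapPhase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# Mean resultant length of the von Mises distribution, I1(kappa)/I0(kappa).
# Scaled Bessel functions keep this stable for large concentration.
besselRatio <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}
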