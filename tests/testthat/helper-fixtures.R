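# Shared fixtures, built once per test run. Generators are deterministic,
# so caching is purely a speed matter.

.cache <- new.env(parent = emptyenv())

cachedFixture <- function(kind, ...) {
  key <- paste(kind, ..., sep = "_")
  if (is.null(.cache[[key]])) .cache[[key]] <- makeFixture(kind, ...)
  .cache[[key]]
}

# coarse, small-padding PB settings that keep grid solves at test scale
testPB <- function(gridDensity = 2, padding = 5, ...) {
  pbParams(gridDensity = gridDensity, padding = padding, ...)
}

# a right-handed rotation matrix about an arbitrary axis
rotationMatrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  outer(u, u) * (1 - c) + diag(c, 3) +
    matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3) * s
}

applyRigid <- function(coords, R, t) sweep(coords %*% t(R), 2, t, "+")
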