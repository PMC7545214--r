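## Half-up rounding at a given number of decimals.  Printed report values
## (distances to 0.1 A, ratios to 1-2 d.p.) use commercial half-up
## rounding; base round() is round-half-even.
.roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Euclidean distance between rows of two coordinate matrices: returns
## the minimum and the arg-min pair.  Used for chain contacts and
## minimal-step selection; plain dense arithmetic, sizes here are small.
.minCrossDist <- function(a, b) {
  ## a, b: n x 3 matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  i <- arrayInd(which.min(d2), dim(d2))
  list(dist = sqrt(d2[i[1], i[2]]), i = i[1], j = i[2])
}

.coordMatrix <- function(df) {
  cbind(df$x, df$y, df$z)
}
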