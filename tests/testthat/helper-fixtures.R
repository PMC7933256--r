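## Shared fixtures: all generated in code, nothing stored on disk.

## n points exactly on the sphere |x - center| = radius
spherePoints <- function(n, center = c(0, 0, 0), radius = 1) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(u * radius, 2, center, "+")
}

## uniformly random rotation matrix
randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

applyToLandmarks <- function(lm, rotation = diag(3),
                             translation = c(0, 0, 0), scale = 1) {
  tf <- function(p) drop(rotation %*% (scale * p)) + translation
  LandmarkSet(t(apply(lm@pvOstia, 1, tf)), tf(lm@laaOstium),
              tf(lm@inferiorReference))
}

## canonical landmark set for a sphere of radius R centred at the origin:
## PVs posterior (+y), LAA anterolateral, inferior reference below
canonicalLandmarks <- function(R = 32) {
  LandmarkSet(
    pvOstia = rbind(c(-R * 0.4, R * 0.8, R * 0.4),
                    c(R * 0.4, R * 0.8, R * 0.4),
                    c(-R * 0.45, R * 0.8, -R * 0.3),
                    c(R * 0.45, R * 0.8, -R * 0.3)),
    laaOstium = c(-R * 0.6, -R * 0.5, R * 0.5),
    inferiorReference = c(0, 0, -(R + 15)))
}

zeroAmplitudes <- function() setNames(rep(0, 6), segmentNames())

## brute-force Spearman permutation p-value (independent oracle, recursive
## permutation generation, nothing shared with the package implementation)
bruteSpearmanP <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  robs <- stats::cor(rx, ry)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rs <- vapply(perms(ry), function(p) stats::cor(rx, p), numeric(1))
  mean(abs(rs) >= abs(robs) - 1e-12)
}
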