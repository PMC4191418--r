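## Independent oracles and small fixtures used across the test files.

## Quaternion (Horn) rigid superposition: independent of the SVD route
## used by the package.
horn_superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  S <- t(xc) %*% yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  R <- matrix(c(
    1 - 2 * (yq^2 + zq^2), 2 * (xq * yq + w * zq), 2 * (xq * zq - w * yq),
    2 * (xq * yq - w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq + w * xq),
    2 * (xq * zq + w * yq), 2 * (yq * zq - w * xq), 1 - 2 * (xq^2 + yq^2)),
    3, 3)
  list(R = R, t = cy - as.numeric(R %*% cx))
}

## random proper rotation
random_rotation <- function() {
  ax <- stats::rnorm(3)
  stepflip:::rot_axis(ax, stats::runif(1, 0, pi))
}

## i.i.d. umbrella-window sampler by inverse-CDF on a fine grid: an
## independent route to biased samples (no Markov chain).
iid_windows <- function(pmf, centers, k, n, seed, temperature = 300) {
  set.seed(seed)
  kT <- 0.0019872041 * temperature
  grid <- seq(-179.975, 180, by = 0.05)
  samples <- sapply(centers, function(ci) {
    d <- ((grid - ci + 180) %% 360 - 180) * pi / 180
    e <- pmf(grid) + k / 2 * d^2
    p <- exp(-(e - min(e)) / kT)
    grid[sample.int(length(grid), n, replace = TRUE, prob = p)] +
      stats::runif(n, -0.025, 0.025)
  })
  structure(list(centers = centers, k = k, temperature = temperature,
                 samples = samples, acceptance = rep(1, length(centers))),
            class = "umbrella_windows")
}

## analytic accessible area of sphere 1 in a two-sphere system (spherical
## cap removed where sphere 2 with radius r2 at distance d overlaps)
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  ca <- (d^2 + r1^2 - r2^2) / (2 * d * r1)  # cos of half-opening angle
  4 * pi * r1^2 * (1 + ca) / 2
}

## Monte-Carlo polygon overlap oracle (even-odd point-in-polygon)
mc_overlap <- function(p1, p2, n = 1e6, seed = 99) {
  set.seed(seed)
  in_poly <- function(pts, poly) {
    np <- nrow(poly)
    inside <- rep(FALSE, nrow(pts))
    j <- np
    for (i in seq_len(np)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
        (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
      j <- i
    }
    inside
  }
  lo <- pmin(apply(p1, 2, min), apply(p2, 2, min))
  hi <- pmax(apply(p1, 2, max), apply(p2, 2, max))
  pts <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]))
  frac <- mean(in_poly(pts, p1) & in_poly(pts, p2))
  frac * prod(hi - lo)
}

## short example-system fixtures (built once per test run)
example_duplex <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      sysd <- purine_triplex_system(with_tfo = FALSE)
      val <<- rebuild_helix(paste(sysd$duplex_seq, collapse = ""))
    }
    val
  }
})
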