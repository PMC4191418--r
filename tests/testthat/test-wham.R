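test_that("a single unbiased window reduces WHAM to the log-histogram", {
  set.seed(71)
  x <- runif(4000, -180, 180)
  w <- structure(list(centers = 0, k = 0, temperature = 300,
                      samples = matrix(x, ncol = 1),
                      acceptance = 1), class = "umbrella_windows")
  p <- wham(w, n_bins = 36)
  kT <- 0.0019872041 * 300
  edges <- seq(-180, 180, length.out = 37)
  h <- hist(x, breaks = edges, plot = FALSE)$counts
  ref <- -kT * log(h / sum(h))
  ref <- ref - min(ref)
  expect_equal(unname(p$W), unname(ref), tolerance = 1e-9)
  ## flat truth: profile flat within sampling error
  expect_lt(max(p$W), 4 * kT)
})

test_that("overlapping harmonic-only windows recover equal constants", {
  flat <- function(x) 0 * x
  w <- iid_windows(flat, c(-20, 20), k = 20, n = 40000, seed = 72)
  ## the two windows deliberately cover only part of the domain, so the
  ## profile's far bins are masked
  p <- suppressWarnings(wham(w, n_bins = 360))
  ## for a flat landscape the window free energies are analytically equal
  expect_lt(abs(diff(p$f)), 0.03)
  ## and each equals -kT ln of the Boltzmann-weighted bias integral
  kT <- 0.0019872041 * 300
  grid <- seq(-179.5, 179.5, by = 1)
  fa <- -kT * log(mean(exp(-20 / 2 * (((grid + 20 + 180) %% 360 - 180) *
                                        pi / 180)^2 / kT)))
  expect_equal(unname(p$f[2] - p$f[1]), 0, tolerance = 0.03)
  expect_true(is.finite(fa))
})

test_that("WHAM recovers a known double-well from independent sampling", {
  truth <- double_well_pmf(dg = 3, b = 4)
  w <- iid_windows(truth, schedule_windows(spacing = 10), k = 500,
                   n = 8000, seed = 73)
  p <- wham(w, n_bins = 360)
  wt <- truth(p$x); wt <- wt - min(wt)
  expect_lt(max(abs(p$W - wt), na.rm = TRUE), 0.35)
  ## doubling the bin count leaves the profile essentially unchanged
  p2 <- wham(w, n_bins = 720)
  on360 <- approx(p2$x, p2$W, xout = p$x)$y
  expect_lt(stats::median(abs(on360 - p$W), na.rm = TRUE), 0.1)
  ## barrier of the estimate near the analytic barrier
  b_true <- max(wt) - min(wt)
  expect_equal(barrier(p)$total, b_true, tolerance = 0.4)
})

test_that("non-convergence at the iteration cap is an error", {
  w <- iid_windows(double_well_pmf(), schedule_windows(spacing = 30),
                   k = 50, n = 500, seed = 74)
  expect_error(suppressWarnings(wham(w, max_iter = 3)), "did not converge")
})

test_that("blocked errors are zero for duplicated data and scale as 1/sqrt(n)", {
  truth <- double_well_pmf()
  base <- iid_windows(truth, schedule_windows(spacing = 15), k = 300,
                      n = 1000, seed = 75)
  ## four identical parts
  dup <- base
  dup$samples <- do.call(rbind, rep(list(base$samples), 4))
  pr <- pmf_error(dup, n_bins = 180)
  expect_lt(max(pr$error, na.rm = TRUE), 1e-9)
  ## error magnitude shrinks with sample size roughly as 1/sqrt(n)
  small <- iid_windows(truth, schedule_windows(spacing = 15), k = 300,
                       n = 2000, seed = 76)
  big <- iid_windows(truth, schedule_windows(spacing = 15), k = 300,
                     n = 32000, seed = 77)
  es <- median(pmf_error(small, n_bins = 180)$error, na.rm = TRUE)
  eb <- median(pmf_error(big, n_bins = 180)$error, na.rm = TRUE)
  expect_equal(es / eb, 4, tolerance = 2)
  ## coverage: truth within 3 blocked errors for >= 95% of usable bins
  pb <- pmf_error(big, n_bins = 180)
  wt <- truth(pb$x)
  ref <- which.min(pb$W)
  dev <- abs((pb$W - pb$W[ref]) - (wt - wt[ref]))
  ok <- is.finite(dev) & pb$error > 0
  expect_gte(mean(dev[ok] <= pmax(3 * pb$error[ok], 0.05)), 0.95)
  expect_error(pmf_error(small, n_blocks = 300), "too few")
})

test_that("opening free energies follow the closed forms and invariances", {
  kT <- 0.0019872041 * 300
  nb <- 360
  x <- seq(-179.5, 179.5, by = 1)
  mkpmf <- function(W) structure(list(x = x, W = W - min(W),
                                      error = rep(0, nb),
                                      temperature = 300, f = 0,
                                      iterations = 1, n_bins = nb),
                                 class = "pmf_profile")
  ## square well: closed half at 0, open half at +5 -> dG = 5
  W <- ifelse(abs(x) <= 90, 0, 5)
  closed <- abs(x) <= 90
  expect_equal(delta_g_open(mkpmf(W), closed), 5, tolerance = 1e-9)
  ## symmetric two-state profile with symmetric partition -> 0
  Ws <- double_well_pmf(dg = 0, b = 3)(x)
  expect_equal(delta_g_open(mkpmf(Ws), closed), 0, tolerance = 1e-9)
  ## invariance under adding a constant
  p1 <- mkpmf(W)
  p2 <- p1; p2$W <- p2$W + 7.3
  expect_equal(delta_g_open(p1, closed), delta_g_open(p2, closed),
               tolerance = 1e-9)
  expect_error(delta_g_open(p1, rep(TRUE, nb)), "empty open")
  ## barrier: flat -> 0; cosine amplitude A -> 2A
  expect_equal(barrier(mkpmf(rep(1, nb)))$total, 0)
  Wc <- 1.75 * (1 + cos(x * pi / 180))
  expect_equal(barrier(mkpmf(Wc))$total, 3.5, tolerance = 1e-3)
})
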