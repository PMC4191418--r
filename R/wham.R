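## Periodic weighted-histogram analysis (WHAM) of umbrella-sampled windows,
## and blocked per-bin errors.

#' Periodic WHAM
#'
#' Self-consistent unbiasing of the window histograms on a periodic grid.
#' The window free-energy constants are iterated (damped fixed point) until
#' the largest change is below `tolerance` (kcal/mol); the unbiased density
#' is then converted to `W(x) = -kT ln p(x)` anchored at min 0.  Bias
#' energies use the minimum-image angular difference.  Bins not covered by
#' any sample are masked (`NA`) with a warning.
#'
#' @param windows an `umbrella_windows` object (or compatible list with
#'   `centers`, `k`, `samples`, `temperature`).
#' @param n_bins number of bins on `(-180, 180]` (default 720).
#' @param tolerance convergence tolerance on the window constants,
#'   kcal/mol (default 1e-6).
#' @param temperature Kelvin; defaults to the windows' temperature.
#' @param max_iter iteration cap (default 1e6); non-convergence is an error
#'   reporting the residual.
#' @param damping fixed-point damping factor in (0, 1] (default 1).
#' @param f_init optional warm-start window constants.
#' @return object of class `pmf_profile`: data frame fields `x` (bin
#'   centers, degrees), `W` (kcal/mol, min 0), `error` (NA until
#'   [pmf_error()]), plus attributes `f` (window constants), `iterations`,
#'   `temperature`.
#' @export
wham <- function(windows, n_bins = 720, tolerance = 1e-6,
                 temperature = NULL, max_iter = 1e6, damping = 1,
                 f_init = NULL) {
  if (is.null(temperature)) temperature <- windows$temperature
  kT <- .KB_KCAL * temperature
  centers <- windows$centers
  nw <- length(centers)
  if (nw < 1 || is.null(windows$samples) || !nrow(windows$samples))
    stop("need at least one window with samples")
  edges <- seq(-180, 180, length.out = n_bins + 1)
  xmid <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  counts <- matrix(0, nw, n_bins)
  for (w in seq_len(nw)) {
    s <- wrap180(windows$samples[, w])
    b <- findInterval(s, edges, rightmost.closed = TRUE, left.open = TRUE)
    b[b == 0] <- 1
    tb <- tabulate(b, nbins = n_bins)
    counts[w, ] <- tb
  }
  N <- rowSums(counts)
  h <- colSums(counts)
  B <- (spread_bias(xmid, centers, windows$k))  # nw x n_bins, kcal/mol
  expB <- exp(-B / kT)
  f <- if (is.null(f_init)) rep(0, nw) else f_init
  iter <- 0
  repeat {
    iter <- iter + 1
    denom <- as.numeric(crossprod(N * exp(f / kT), expB))
    p <- h / denom
    p <- p / sum(p)
    fn <- -kT * log(as.numeric(expB %*% p))
    fn <- fn - fn[1]
    res <- max(abs(fn - f))
    f <- f + damping * (fn - f)
    if (res < tolerance) break
    if (iter >= max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                   iter, res))
  }
  empty <- h == 0
  if (any(empty))
    warning(sum(empty), " empty bin(s) masked in the WHAM profile")
  W <- -kT * log(p)
  W[empty] <- NA_real_
  W <- W - min(W, na.rm = TRUE)
  structure(list(x = xmid, W = W, error = rep(NA_real_, n_bins),
                 temperature = temperature, f = f, iterations = iter,
                 n_bins = n_bins),
            class = "pmf_profile")
}

#' @keywords internal
#' @noRd
spread_bias <- function(xmid, centers, k) {
  d <- outer(centers, xmid, function(ci, x) ang_diff(x, ci) * DEG2RAD)
  k / 2 * d^2
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %d bins, %g K; barrier %.2f kcal/mol (%d WHAM iterations)\n",
              x$n_bins, x$temperature, max(x$W, na.rm = TRUE),
              x$iterations))
  invisible(x)
}

#' Blocked per-bin PMF errors
#'
#' Splits each window's series into `n_blocks` contiguous parts, runs WHAM
#' per part (warm-started from the full-data constants), anchors every part
#' profile at the same reference bin (the full profile's minimum), and
#' reports the per-bin standard deviation over the parts.
#'
#' @param windows an `umbrella_windows` object.
#' @param n_blocks number of contiguous parts (default 4).
#' @param profile optional full-data `pmf_profile` (recomputed if NULL).
#' @param n_bins,tolerance,temperature,max_iter,damping as in [wham()].
#' @return the `pmf_profile` with its `error` field filled in, plus
#'   attribute `block_profiles`.
#' @export
pmf_error <- function(windows, n_blocks = 4, profile = NULL, n_bins = 720,
                      tolerance = 1e-6, temperature = NULL, max_iter = 1e6,
                      damping = 1) {
  ns <- nrow(windows$samples)
  if (ns < n_blocks * 10)
    stop("too few samples per window (", ns, ") for ", n_blocks, " blocks")
  if (is.null(profile))
    profile <- wham(windows, n_bins = n_bins, tolerance = tolerance,
                    temperature = temperature, max_iter = max_iter,
                    damping = damping)
  ref_bin <- which.min(profile$W)
  split_ix <- split(seq_len(ns),
                    rep(seq_len(n_blocks), each = ceiling(ns / n_blocks),
                        length.out = ns))
  Wb <- matrix(NA_real_, length(profile$x), n_blocks)
  for (b in seq_len(n_blocks)) {
    sub <- windows
    sub$samples <- windows$samples[split_ix[[b]], , drop = FALSE]
    pb <- suppressWarnings(wham(sub, n_bins = profile$n_bins,
                                tolerance = tolerance,
                                temperature = profile$temperature,
                                max_iter = max_iter, damping = damping,
                                f_init = profile$f))
    Wb[, b] <- pb$W - pb$W[ref_bin]
  }
  profile$error <- apply(Wb, 1, stats::sd)
  attr(profile, "block_profiles") <- Wb
  profile
}
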