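## Umbrella-window scheduling and seeded Metropolis sampling of a scalar
## periodic coordinate under harmonic biases.

.KB_KCAL <- 0.0019872041  # kcal/(mol K)

#' Umbrella window centers on a periodic domain
#'
#' Centers from `start` to `stop` in `spacing` steps, with the two ends of
#' the periodic domain counted once (-180 is identified with +180), so the
#' default schedule gives 72 windows.
#'
#' @param start,stop domain limits in degrees.
#' @param spacing window spacing in degrees; must divide the span.
#' @return numeric vector of window centers in `(-180, 180]`.
#' @export
schedule_windows <- function(start = -180, stop = 180, spacing = 5) {
  span <- stop - start
  if (spacing <= 0 || abs(span / spacing - round(span / spacing)) > 1e-9)
    stop("spacing ", spacing, " does not divide the span ", span)
  wrap180(seq(start + spacing, stop, by = spacing))
}

#' Specify a biased sampler run
#'
#' @param pmf function of angle (degrees) returning the true potential of
#'   mean force in kcal/mol; must be periodic with period 360.
#' @param centers window centers, degrees (see [schedule_windows()]).
#' @param k harmonic force constant, kcal/(mol rad^2).
#' @param n_samples samples recorded per window.
#' @param temperature Kelvin (default 300).
#' @param seed RNG seed.
#' @return object of class `sampler_spec`.
#' @export
sampler_spec <- function(pmf, centers, k, n_samples, temperature = 300,
                         seed = 1) {
  stopifnot(is.function(pmf), k >= 0)
  if (n_samples < 1) stop("zero samples requested")
  structure(list(pmf = pmf, centers = centers, k = k,
                 n_samples = as.integer(n_samples),
                 temperature = temperature, seed = as.integer(seed)),
            class = "sampler_spec")
}

#' Sample umbrella windows by a periodic Metropolis walk
#'
#' One Metropolis chain per window, run in lockstep, targeting
#' `exp(-(U(x) + k/2 (x - x_i)^2) / kT)` on `(-180, 180]` with the bias
#' argument taken as the minimum-image angular difference (radians).  The
#' proposal step is adapted during burn-in toward 30-60% acceptance.
#' Seeded and reproducible.
#'
#' @param spec a [sampler_spec()].
#' @param burn_in burn-in sweeps (default 2000).
#' @param thin record every `thin`-th sweep (default 1).
#' @return object of class `umbrella_windows`: list with `centers`, `k`,
#'   `temperature`, `samples` (`n_samples x n_windows` matrix, degrees),
#'   and per-window `acceptance`.
#' @export
sample_biased_windows <- function(spec, burn_in = 2000, thin = 1) {
  stopifnot(inherits(spec, "sampler_spec"))
  set.seed(spec$seed)
  kT <- .KB_KCAL * spec$temperature
  nw <- length(spec$centers)
  energy <- function(x) {
    spec$pmf(x) + spec$k / 2 * (ang_diff(x, spec$centers) * DEG2RAD)^2
  }
  x <- spec$centers
  E <- energy(x)
  step <- rep(if (spec$k > 0)
    max(1, 3 * sqrt(kT / spec$k) * RAD2DEG) else 60, nw)
  acc_win <- rep(0, nw)
  n_win <- 0
  total_acc <- rep(0, nw)
  total_n <- 0
  samples <- matrix(NA_real_, spec$n_samples, nw)
  got <- 0
  sweeps <- burn_in + spec$n_samples * thin
  for (it in seq_len(sweeps)) {
    prop <- wrap180(x + stats::runif(nw, -1, 1) * step)
    Ep <- energy(prop)
    acc <- stats::runif(nw) < exp((E - Ep) / kT)
    x[acc] <- prop[acc]
    E[acc] <- Ep[acc]
    if (it <= burn_in) {
      acc_win <- acc_win + acc
      n_win <- n_win + 1
      if (n_win == 100) {
        rate <- acc_win / n_win
        step <- pmin(180, pmax(0.05, step * (0.5 + rate / 0.9)))
        acc_win[] <- 0; n_win <- 0
      }
    } else {
      total_acc <- total_acc + acc
      total_n <- total_n + 1
      if ((it - burn_in) %% thin == 0) {
        got <- got + 1
        samples[got, ] <- x
      }
    }
  }
  structure(list(centers = spec$centers, k = spec$k,
                 temperature = spec$temperature, samples = samples,
                 acceptance = total_acc / total_n),
            class = "umbrella_windows")
}

#' @export
print.umbrella_windows <- function(x, ...) {
  cat(sprintf("<umbrella_windows> %d windows x %d samples, k = %g kcal/(mol rad^2), %g K\n",
              length(x$centers), nrow(x$samples), x$k, x$temperature))
  cat(sprintf("  acceptance: %.2f-%.2f\n", min(x$acceptance),
              max(x$acceptance)))
  invisible(x)
}

#' Write umbrella windows as plain-text series
#'
#' One file per window (one angle in degrees per line) plus a JSON sidecar
#' with centers, force constant and temperature.
#'
#' @param windows an `umbrella_windows` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nw <- length(windows$centers)
  files <- sprintf("window_%03d.dat", seq_len(nw))
  for (w in seq_len(nw))
    writeLines(format(windows$samples[, w], digits = 15),
               file.path(dir, files[w]))
  meta <- list(centers = windows$centers, k = windows$k,
               temperature = windows$temperature, files = files)
  jsonlite::write_json(meta, file.path(dir, "windows.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read umbrella windows written by [write_windows()]
#' @param dir directory containing `windows.json` and the series files.
#' @return an `umbrella_windows` object.
#' @export
read_windows <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "windows.json"),
                              simplifyVector = TRUE)
  series <- lapply(file.path(dir, meta$files),
                   function(f) as.numeric(readLines(f)))
  n <- unique(vapply(series, length, 1L))
  if (length(n) != 1) stop("window series differ in length")
  structure(list(centers = meta$centers, k = meta$k,
                 temperature = meta$temperature,
                 samples = do.call(cbind, series),
                 acceptance = rep(NA_real_, length(meta$centers))),
            class = "umbrella_windows")
}
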