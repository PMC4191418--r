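## Shrake-Rupley solvent-accessible surface areas with per-element radii,
## and SASA-based open/closed classification of a flipping base pair.

#' Default per-element radii (nm)
#'
#' Carbon 0.14, oxygen and phosphorus 0.13, nitrogen 0.13, hydrogen 0.10 nm,
#' rolled with a zero additional probe.
#' @return named numeric vector, nm.
#' @export
default_sasa_radii <- function() {
  c(C = 0.14, O = 0.13, P = 0.13, N = 0.13, H = 0.10)
}

## deterministic quasi-uniform unit-sphere points (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area per atom (Shrake-Rupley)
#'
#' Numerical sphere-point accessibility with a deterministic point set.
#' Radii are per-element (nm) plus an optional uniform probe; coordinates
#' are Angstrom, areas are returned in nm^2.
#'
#' @param structure a `dna_structure`.
#' @param atoms atom row indices to evaluate (default: all).
#' @param frame frame index.
#' @param radii named per-element radii in nm (see [default_sasa_radii()]).
#' @param probe additional probe radius in nm (default 0).
#' @param n_points sphere points per atom (default 960).
#' @return numeric vector of areas (nm^2) for the requested atoms.
#' @export
sasa <- function(structure, atoms = NULL, frame = 1,
                 radii = default_sasa_radii(), probe = 0, n_points = 960) {
  stopifnot(inherits(structure, "dna_structure"))
  if (is.null(atoms)) atoms <- seq_len(nrow(structure$atoms))
  elem <- structure$atoms$element
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown))
    stop("no radius for element(s): ", paste(unknown, collapse = ", "))
  r <- (radii[elem] + probe) * 10  # Angstrom
  crd <- frame_coords(structure, frame)
  pts <- .sphere_points(n_points)
  out <- numeric(length(atoms))
  for (t in seq_along(atoms)) {
    i <- atoms[t]
    d2 <- rowSums(sweep(crd, 2, crd[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & d2 > 0)
    sp <- sweep(pts * r[i], 2, crd[i, ], `+`)
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(sp, 2, crd[j, ])^2)
        free <- free & dj2 > r[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    out[t] <- 4 * pi * (r[i] / 10)^2 * frac  # nm^2
  }
  out
}

#' Open/closed definition for base-pair flipping
#'
#' A base pair is closed when the SASA of its reporter atom (H3 of a
#' pyrimidine, N1 of a purine) is below the threshold.
#'
#' @param threshold nm^2 (default 0.001).
#' @param radii per-element radii, nm.
#' @param probe probe radius, nm.
#' @param n_points sphere points per atom.
#' @return object of class `open_close_definition`.
#' @export
open_close_definition <- function(threshold = 0.001,
                                  radii = default_sasa_radii(), probe = 0,
                                  n_points = 960) {
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(threshold = threshold, radii = radii, probe = probe,
                 n_points = n_points), class = "open_close_definition")
}

#' Reporter atom of a residue for opening classification
#' @keywords internal
#' @noRd
reporter_atom <- function(structure, resno) {
  atoms <- structure$atoms
  ix <- which(atoms$resno == resno)
  if (!length(ix)) stop("no residue ", resno)
  base <- resname_base(atoms$resname[ix[1]])
  nm <- if (is_purine(base)) "N1" else "H3"
  hit <- ix[atoms$name[ix] == nm]
  if (!length(hit))
    stop("reporter atom ", nm, " missing in residue ", resno)
  hit[1]
}

#' Classify frames as open or closed by reporter SASA
#'
#' @param structure a (multi-frame) `dna_structure`.
#' @param resno residue whose flipping is monitored.
#' @param definition an [open_close_definition()].
#' @param frames frame indices (default all).
#' @return data frame with `frame`, `sasa` (nm^2), `closed` (logical).
#' @export
classify_open_closed <- function(structure, resno,
                                 definition = open_close_definition(),
                                 frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(structure))
  rep_ix <- reporter_atom(structure, resno)
  out <- data.frame(frame = frames, sasa = NA_real_, closed = NA)
  for (k in seq_along(frames)) {
    a <- sasa(structure, atoms = rep_ix, frame = frames[k],
              radii = definition$radii, probe = definition$probe,
              n_points = definition$n_points)
    out$sasa[k] <- a
    out$closed[k] <- a < definition$threshold
  }
  out
}

#' Closed-state partition of the reaction coordinate from window labels
#'
#' Given per-window closed/open labels at the window centers, returns a
#' periodic partition of the coordinate: each bin of a profile grid is
#' assigned the label of its nearest window center, with boundary bins
#' going to the closed state (conservative for the opening free energy).
#'
#' @param centers window centers, degrees.
#' @param closed logical per window.
#' @param x grid (degrees) to label, e.g. a `pmf_profile`'s `$x`.
#' @return logical vector along `x`: TRUE = closed.
#' @export
opening_partition <- function(centers, closed, x) {
  if (!any(closed) || all(closed))
    stop("partition needs both open and closed windows")
  lab <- vapply(x, function(xx) {
    d <- abs(ang_diff(xx, centers))
    near <- which(d < min(d) + 1e-9)
    any(closed[near])  # ties -> closed
  }, TRUE)
  lab
}
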