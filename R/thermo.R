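## Base-flipping reaction coordinate and opening thermodynamics.

#' Pseudo-dihedral specification for a flipping base
#'
#' Builds the four center-of-mass groups of the flipping coordinate: the
#' flipping base, its sugar, the first neighboring sugar (3' by default),
#' and the first neighboring base pair.
#'
#' @param structure a `dna_structure`.
#' @param annotation a `pairing_annotation`.
#' @param resno flipping residue number (either duplex strand).
#' @param neighbor `"3p"` (default) or `"5p"`.
#' @param sign `+1` (default) maps positive rotation to the major-groove
#'   flipping direction; `-1` flips the convention.
#' @return object of class `pseudo_dihedral_spec` (list of four atom index
#'   groups plus the sign).
#' @export
pseudo_dihedral_spec <- function(structure, annotation, resno,
                                 neighbor = c("3p", "5p"), sign = 1) {
  neighbor <- match.arg(neighbor)
  atoms <- structure$atoms
  n <- annotation$n_bp
  if (!resno %in% atoms$resno) stop("no residue ", resno)
  rn <- resno + if (neighbor == "3p") 1L else -1L
  chain0 <- atoms$chain[match(resno, atoms$resno)]
  if (!rn %in% atoms$resno ||
      atoms$chain[match(rn, atoms$resno)] != chain0)
    stop("neighbor residue ", rn, " not on the same strand")
  partner <- 2L * n + 1L - rn
  base_ix <- function(r)
    which(atoms$resno == r & !atoms$name %in% c("C1'", "P") &
            atoms$element != "H")
  sugar_ix <- function(r)
    which(atoms$resno == r & grepl("'", atoms$name, fixed = TRUE))
  groups <- list(
    flipping_base = base_ix(resno),
    sugar = sugar_ix(resno),
    neighbor_sugar = sugar_ix(rn),
    neighbor_pair = c(base_ix(rn), base_ix(partner))
  )
  empty <- lengths(groups) == 0
  if (any(empty))
    stop("empty COM group(s): ", paste(names(groups)[empty], collapse = ", "))
  if (anyDuplicated(unlist(groups)))
    stop("COM groups overlap")
  structure(list(groups = groups, sign = sign, resno = resno,
                 neighbor = rn), class = "pseudo_dihedral_spec")
}

#' Pseudo-dihedral flipping angle
#'
#' Dihedral over the four group centers of mass, reported in `(-180, 180]`
#' degrees with the spec's sign convention.
#'
#' @param structure a `dna_structure`.
#' @param spec a [pseudo_dihedral_spec()], or a plain list of four atom
#'   index groups.
#' @param frame frame index.
#' @return angle in degrees.
#' @export
pseudo_dihedral <- function(structure, spec, frame = 1) {
  groups <- if (inherits(spec, "pseudo_dihedral_spec")) spec$groups else spec
  sgn <- if (inherits(spec, "pseudo_dihedral_spec")) spec$sign else 1
  crd <- frame_coords(structure, frame)
  p <- t(vapply(groups, function(ix) colMeans(crd[ix, , drop = FALSE]),
                numeric(3)))
  dihedral_points(p[1, ], p[2, ], p[3, ], p[4, ]) * sgn
}

#' Dihedral angle over four points (degrees)
#' @keywords internal
#' @noRd
dihedral_points <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("collinear consecutive centers of mass: dihedral undefined")
  ang <- atan2(sum(cr(n1, n2) * b2) / nb2, sum(n1 * n2)) * RAD2DEG
  wrap180(ang)
}

#' Opening free energy from a PMF and a closed/open partition
#'
#' `dG = -kT ln( int_open exp(-W/kT) dx / int_closed exp(-W/kT) dx )`:
#' positive when the closed state is favored.  Invariant under adding a
#' constant to `W`.
#'
#' @param pmf a `pmf_profile`.
#' @param closed logical vector along `pmf$x`, TRUE = closed (e.g. from
#'   [opening_partition()]).
#' @return dG in kcal/mol.
#' @export
delta_g_open <- function(pmf, closed) {
  if (length(closed) != length(pmf$x))
    stop("partition length does not match the profile grid")
  kT <- .KB_KCAL * pmf$temperature
  w <- pmf$W
  ok <- !is.na(w)
  if (!any(closed & ok) || !any(!closed & ok))
    stop("empty open or closed state")
  wmin <- min(w[ok])
  p <- exp(-(w - wmin) / kT)
  -kT * log(sum(p[!closed & ok]) / sum(p[closed & ok]))
}

#' Flipping barrier of a PMF
#'
#' The difference between the maximum and minimum of the profile; also
#' reported separately toward each groove (positive and negative angles
#' under the sign convention).
#'
#' @param pmf a `pmf_profile`.
#' @return list with `total`, `major` (max over x > 0 minus min),
#'   `minor` (max over x < 0 minus min), kcal/mol.
#' @export
barrier <- function(pmf) {
  w <- pmf$W
  ok <- !is.na(w)
  wmin <- min(w[ok])
  list(total = max(w[ok]) - wmin,
       major = if (any(ok & pmf$x > 0)) max(w[ok & pmf$x > 0]) - wmin else NA_real_,
       minor = if (any(ok & pmf$x < 0)) max(w[ok & pmf$x < 0]) - wmin else NA_real_)
}
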