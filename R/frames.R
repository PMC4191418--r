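## Rigid-body helical analysis: base frames, pair frames, the six base-pair
## step parameters, local helical parameters and Zp metrics.
##
## Conventions (CEHS / mid-frame):
##   * every frame is (origin o, rotation R) with columns x, y, z;
##     x points into the major groove, y along the long pair axis toward
##     strand I's backbone, z along the 5'->3' direction of strand I.
##   * the rotational step decomposition is symmetric about the mid-frame
##     (half-rotation convention); translations are expressed in mid-frame
##     axes.  The rebuild composition below is its exact inverse.
##   * angles in degrees, distances in Angstrom.

.frame <- function(R, o, rmsd = NA_real_) {
  list(R = R, o = as.numeric(o), rmsd = rmsd)
}

flip_frame <- function(f) .frame(f$R %*% diag(c(1, -1, -1)), f$o, f$rmsd)

#' Fit a base reference frame to observed base atoms
#'
#' Least-squares rigid superposition of the standard base geometry (ring
#' atoms only) onto the observed coordinates.  The returned rotation and
#' origin map standard-frame coordinates into the lab frame.
#'
#' @param base_atoms data frame with columns `name`, `x`, `y`, `z` (or a
#'   matrix with rownames = atom names) for one base.
#' @param base base letter `"A"/"T"/"G"/"C"` identifying the standard
#'   geometry to fit against.
#' @return list with `R` (3x3 rotation), `o` (origin, Angstrom) and `rmsd`
#'   of the fitted ring atoms.
#' @export
fit_base_frame <- function(base_atoms, base) {
  std <- standard_base_geometry(base, backbone = FALSE)
  std <- std[std$ring, ]
  if (is.matrix(base_atoms))
    base_atoms <- data.frame(name = rownames(base_atoms),
                             x = base_atoms[, 1], y = base_atoms[, 2],
                             z = base_atoms[, 3], stringsAsFactors = FALSE)
  m <- match(std$name, base_atoms$name)
  missing <- std$name[is.na(m)]
  have <- !is.na(m)
  if (sum(have) < 3)
    stop("too few matched ring atoms for base frame fit; missing: ",
         paste(missing, collapse = ", "))
  x <- as.matrix(std[have, c("x", "y", "z")])
  y <- as.matrix(base_atoms[m[have], c("x", "y", "z")])
  yc <- sweep(y, 2, colMeans(y))
  if (svd(yc)$d[2] < 1e-6)
    stop("observed ring atoms are collinear; base frame undefined")
  fit <- kabsch(x, y)
  assert_rotation(fit$R, what = "fitted base frame")
  .frame(fit$R, fit$t, fit$rmsd)
}

#' Base frames for all residues of one frame of a structure
#'
#' @param structure a `dna_structure`.
#' @param frame frame index.
#' @param resno residues to process (default: all).
#' @return named list of base frames (names = residue numbers).
#' @export
base_frames <- function(structure, frame = 1, resno = NULL) {
  atoms <- structure$atoms
  crd <- frame_coords(structure, frame)
  if (is.null(resno)) resno <- unique(atoms$resno)
  out <- vector("list", length(resno))
  names(out) <- as.character(resno)
  for (k in seq_along(resno)) {
    ix <- which(atoms$resno == resno[k])
    base <- resname_base(atoms$resname[ix[1]])
    df <- data.frame(name = atoms$name[ix], x = crd[ix, 1], y = crd[ix, 2],
                     z = crd[ix, 3], stringsAsFactors = FALSE)
    out[[k]] <- fit_base_frame(df, base)
  }
  out
}

## ---------------------------------------------------------------------------
## CEHS decomposition / composition

#' Decompose the rigid transform between two frames into six parameters
#'
#' Mid-frame (half-rotation) convention: the z-axes are hinged onto their
#' bisector, twist is measured about the common z, the mid-frame sits at the
#' half-twist, and roll/tilt are the bending angle resolved along the
#' mid-frame y and x axes.  Translations are components of `o2 - o1` in
#' mid-frame axes.
#'
#' @param f1,f2 frames (lists with `R`, `o`), f1 -> f2 along 5'->3'.
#' @return list with `par` (shift, slide, rise, tilt, roll, twist; Angstrom
#'   and degrees) and `mid` (the mid-frame).
#' @export
cehs_decompose <- function(f1, f2) {
  R1 <- f1$R; R2 <- f2$R
  z1 <- R1[, 3]; z2 <- R2[, 3]
  hinge <- c(z1[2] * z2[3] - z1[3] * z2[2],
             z1[3] * z2[1] - z1[1] * z2[3],
             z1[1] * z2[2] - z1[2] * z2[1])
  hn <- sqrt(sum(hinge^2))
  gamma <- atan2(hn, sum(z1 * z2))
  if (hn > 1e-12) {
    A1 <- rot_axis(hinge, gamma / 2) %*% R1
    A2 <- rot_axis(hinge, -gamma / 2) %*% R2
  } else {
    A1 <- R1; A2 <- R2
  }
  zm <- A1[, 3]
  omega <- signed_angle(A1[, 1], A2[, 1], zm)
  Rm <- rot_axis(zm, omega / 2) %*% A1
  if (hn > 1e-12) {
    phi <- signed_angle(hinge, Rm[, 2], zm)
    roll <- gamma * cos(phi)
    tilt <- gamma * sin(phi)
  } else {
    roll <- 0; tilt <- 0
  }
  d <- as.numeric(crossprod(Rm, f2$o - f1$o))
  om <- (f1$o + f2$o) / 2
  list(par = c(shift = d[1], slide = d[2], rise = d[3],
               tilt = tilt * RAD2DEG, roll = roll * RAD2DEG,
               twist = omega * RAD2DEG),
       mid = .frame(Rm, om))
}

#' Compose a frame from six parameters (exact inverse of the decomposition)
#'
#' @param f1 starting frame.
#' @param par named vector with `shift`, `slide`, `rise` (Angstrom) and
#'   `tilt`, `roll`, `twist` (degrees).
#' @return list with `f2` (the advanced frame) and `mid` (the mid-frame).
#' @export
cehs_compose <- function(f1, par) {
  tilt <- par[["tilt"]] * DEG2RAD
  roll <- par[["roll"]] * DEG2RAD
  omega <- par[["twist"]] * DEG2RAD
  gamma <- sqrt(roll^2 + tilt^2)
  phi <- atan2(tilt, roll)
  R1 <- f1$R
  R2 <- R1 %*% rot_z(omega / 2 - phi) %*% rot_y(gamma) %*%
    rot_z(omega / 2 + phi)
  Rm <- R1 %*% rot_z(omega / 2 - phi) %*% rot_y(gamma / 2) %*% rot_z(phi)
  om_t <- as.numeric(Rm %*% c(par[["shift"]], par[["slide"]], par[["rise"]]))
  o2 <- f1$o + om_t
  list(f2 = .frame(R2, o2), mid = .frame(Rm, (f1$o + o2) / 2))
}

## ---------------------------------------------------------------------------
## Pair frames and parameters

#' Pair frame and base-pair parameters from two base frames
#'
#' The complementary base's frame is flipped (y and z negated) before the
#' mid-frame decomposition, as usual for Watson-Crick geometry.  The six
#' residual parameters are reported as shear, stretch, stagger (Angstrom)
#' and buckle, propeller, opening (degrees).  Swapping the two bases negates
#' shear and buckle only.
#'
#' @param f1 frame of the leading-strand (strand I) base.
#' @param f2 frame of the complementary base.
#' @param flip flip the second frame before averaging (default TRUE; set
#'   FALSE for already co-oriented frames, e.g. a TFO base paired in trans).
#' @return list with `frame` (the pair frame) and `par` (named vector).
#' @export
pair_frame <- function(f1, f2, flip = TRUE) {
  f2f <- if (flip) flip_frame(f2) else f2
  dec <- cehs_decompose(f2f, f1)
  par <- dec$par
  names(par) <- c("shear", "stretch", "stagger", "buckle", "propeller",
                  "opening")
  list(frame = dec$mid, par = par)
}

#' Base-pair step parameters between consecutive pair frames
#'
#' @param pf1,pf2 pair frames (as returned in `$frame` by [pair_frame()]),
#'   ordered 5'->3' along strand I.
#' @return object of class `step_parameters`: list with `par`, `mid`,
#'   `f1`, `f2`, and `flag` (`"antiparallel"` when |twist| is within 5
#'   degrees of 180, `"ok"` otherwise).
#' @export
step_parameters <- function(pf1, pf2) {
  dec <- cehs_decompose(pf1, pf2)
  flag <- if (abs(dec$par[["twist"]]) > 175) "antiparallel" else "ok"
  structure(list(par = dec$par, mid = dec$mid, f1 = pf1, f2 = pf2,
                 flag = flag),
            class = "step_parameters")
}

## ---------------------------------------------------------------------------
## Local helical parameters

#' Local helical parameters of a step
#'
#' The local helical axis is the screw axis of the step's rigid rotation.
#' Helical twist and rise are the rotation about and translation along that
#' axis; x/y-displacement locate the first pair frame's origin relative to
#' the axis; inclination and tip resolve the angle between the pair normal
#' and the axis along the pair's y and x directions.
#'
#' @param step a `step_parameters` object.
#' @return named vector: `x_disp`, `y_disp` (Angstrom), `inclination`,
#'   `tip` (degrees), `h_twist`, `h_rise`; all `NA` with attribute
#'   `flag = "no_axis"` for a step with (numerically) zero net rotation.
#' @export
helical_parameters <- function(step) {
  stopifnot(inherits(step, "step_parameters"))
  R1 <- step$f1$R; o1 <- step$f1$o
  R2 <- step$f2$R; o2 <- step$f2$o
  Rot <- R2 %*% t(R1)
  aa <- rot_axis_angle(Rot)
  if (aa$angle < 1e-8) {
    out <- c(x_disp = NA_real_, y_disp = NA_real_, inclination = NA_real_,
             tip = NA_real_, h_twist = NA_real_, h_rise = NA_real_)
    attr(out, "flag") <- "no_axis"
    return(out)
  }
  u <- aa$axis; theta <- aa$angle
  if (sum(u * (R1[, 3] + R2[, 3])) < 0) {
    u <- -u; theta <- -theta
  }
  h <- sum((o2 - o1) * u)
  ## point on the screw axis: (I - Rot) p = o2 - Rot o1 - h u, solved in the
  ## plane orthogonal to u via the pseudo-inverse
  M <- diag(3) - Rot
  b <- o2 - as.numeric(Rot %*% o1) - h * u
  sv <- svd(M)
  dinv <- ifelse(sv$d > 1e-9, 1 / sv$d, 0)
  p <- as.numeric(sv$v %*% (dinv * crossprod(sv$u, b)))
  z1 <- R1[, 3]
  hinge <- c(z1[2] * u[3] - z1[3] * u[2],
             z1[3] * u[1] - z1[1] * u[3],
             z1[1] * u[2] - z1[2] * u[1])
  hn <- sqrt(sum(hinge^2))
  g1 <- atan2(hn, sum(z1 * u))
  A1 <- if (hn > 1e-12) rot_axis(hinge, g1) %*% R1 else R1
  ## inclination: tilt of the pair long axis (y) out of the plane normal to
  ## the helical axis; tip: same for the short axis (x).  Positive roll
  ## gives positive inclination, positive tilt gives positive tip.
  incl <- asin(max(-1, min(1, sum(R1[, 2] * u))))
  tip <- asin(max(-1, min(1, sum(R1[, 1] * u))))
  v <- o1 - p
  v <- v - sum(v * u) * u
  out <- c(x_disp = sum(v * A1[, 1]), y_disp = sum(v * A1[, 2]),
           inclination = incl * RAD2DEG, tip = tip * RAD2DEG,
           h_twist = theta * RAD2DEG, h_rise = h)
  attr(out, "axis") <- u
  attr(out, "axis_point") <- p
  out
}

#' Zp metrics of a step from its inter-strand phosphorus pair
#'
#' `zp` is the z-component of the phosphorus-to-phosphorus vector in the
#' middle-step frame; `zp_h` is the same vector's component along the local
#' helical axis.  Both discriminate A-, B- and TA-like conformations.
#'
#' @param step a `step_parameters` object.
#' @param p_strand1 phosphorus coordinate on strand I (the step's 3' side),
#'   or `NULL` if absent.
#' @param p_strand2 phosphorus coordinate on strand II, or `NULL`.
#' @return named vector `zp`, `zp_h` (Angstrom); `NA` with attribute
#'   `flag = "missing_P"` when either atom is absent.
#' @export
zp_metrics <- function(step, p_strand1, p_strand2) {
  stopifnot(inherits(step, "step_parameters"))
  if (is.null(p_strand1) || is.null(p_strand2) ||
      anyNA(p_strand1) || anyNA(p_strand2)) {
    out <- c(zp = NA_real_, zp_h = NA_real_)
    attr(out, "flag") <- "missing_P"
    return(out)
  }
  pp <- as.numeric(p_strand2) - as.numeric(p_strand1)
  zm <- step$mid$R[, 3]
  Rot <- step$f2$R %*% t(step$f1$R)
  aa <- rot_axis_angle(Rot)
  if (aa$angle < 1e-8) {
    zph <- NA_real_
  } else {
    u <- aa$axis
    if (sum(u * (step$f1$R[, 3] + step$f2$R[, 3])) < 0) u <- -u
    zph <- sum(pp * u)
  }
  c(zp = sum(pp * zm), zp_h = zph)
}

## ---------------------------------------------------------------------------
## Whole-structure step table

#' Per-step parameter table for a structure ensemble
#'
#' Computes, for every frame and every Watson-Crick base-pair step, the six
#' step parameters, the local helical parameters and the Zp metrics, plus a
#' region label and quality flags.  This is the long table all ensemble
#' statistics are built from.
#'
#' @param structure a `dna_structure`.
#' @param annotation a `pairing_annotation`.
#' @param frames frame indices to analyze (default: all).
#' @param hoogsteen if `TRUE`, analyze steps of the third strand (TFO base
#'   frames, no flip) instead of the Watson-Crick duplex steps.
#' @return data frame, one row per (frame, step).
#' @export
step_table <- function(structure, annotation, frames = NULL,
                       hoogsteen = FALSE) {
  stopifnot(inherits(structure, "dna_structure"),
            inherits(annotation, "pairing_annotation"))
  if (is.null(frames)) frames <- seq_len(n_frames(structure))
  n <- annotation$n_bp
  atoms <- structure$atoms
  seq1 <- resname_base(atoms$resname[match(seq_len(n), atoms$resno)])
  region_of <- function(i) {
    for (rn in names(annotation$regions)) {
      r <- annotation$regions[[rn]]
      if (i >= r[1] && i + 1 <= r[2]) return(rn)
    }
    "linker"
  }
  if (hoogsteen) {
    if (is.null(annotation$hoogsteen_pairs))
      stop("annotation has no Hoogsteen pairs")
    resnos <- sort(annotation$hoogsteen_pairs[, "tfo"])
    nsteps <- length(resnos) - 1
  } else {
    nsteps <- n - 1
  }
  rows <- vector("list", length(frames) * nsteps)
  k <- 0
  for (f in frames) {
    if (hoogsteen) {
      bf <- base_frames(structure, f, resnos)
      pfs <- bf  # single-base frames stand in for pair frames
      labels <- paste0(
        resname_base(atoms$resname[match(resnos, atoms$resno)])[-length(resnos)],
        resname_base(atoms$resname[match(resnos, atoms$resno)])[-1])
      steps_ix <- seq_len(nsteps)
      region <- rep("tfo", nsteps)
    } else {
      bf <- base_frames(structure, f, seq_len(2 * n))
      pfs <- vector("list", n)
      for (i in seq_len(n)) {
        j <- annotation$wc_pairs[i, "j"]
        pfs[[i]] <- pair_frame(bf[[as.character(i)]],
                               bf[[as.character(j)]])$frame
      }
      labels <- paste0(seq1[-n], seq1[-1])
      steps_ix <- seq_len(nsteps)
      region <- vapply(steps_ix, region_of, "")
    }
    crd <- frame_coords(structure, f)
    for (s in steps_ix) {
      st <- step_parameters(pfs[[s]], pfs[[s + 1]])
      hel <- helical_parameters(st)
      if (!hoogsteen) {
        i1 <- atom_indices(structure, resno = s + 1, name = "P")
        j2 <- annotation$wc_pairs[s, "j"]
        i2 <- atom_indices(structure, resno = j2, name = "P")
        zp <- zp_metrics(st,
                         if (length(i1)) crd[i1[1], ] else NULL,
                         if (length(i2)) crd[i2[1], ] else NULL)
      } else {
        zp <- c(zp = NA_real_, zp_h = NA_real_)
      }
      k <- k + 1
      rows[[k]] <- data.frame(
        frame = f, step = s, label = labels[s], region = region[s],
        t(st$par), t(hel[1:6]), zp = zp[["zp"]], zp_h = zp[["zp_h"]],
        flag = st$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
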