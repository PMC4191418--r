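## Synthetic helix construction: rebuild duplexes from step parameters,
## place a reverse-Hoogsteen third strand, draw Gaussian step-parameter
## ensembles, and rotate single bases out of the stack.
##
## rebuild_helix() and the frame analysis in frames.R are exact mutual
## inverses: a helix rebuilt at given step/pair parameters analyzes back to
## those parameters to numerical precision.

#' Canonical fiber step parameters
#'
#' Uniform per-step parameters for idealized A- and B-form helices.
#' Twist/roll/rise are the standard reference values (B: 36.0 deg, 0.6 deg,
#' 3.32 A; A: 31.1 deg, 8.0 deg, 3.31 A); slide uses the field-standard
#' fiber values (0 for B, -1.5 A for A).
#'
#' @param form `"B"` or `"A"`.
#' @return named vector of six step parameters.
#' @export
canonical_step_parameters <- function(form = c("B", "A")) {
  form <- match.arg(form)
  if (form == "B")
    c(shift = 0, slide = 0, rise = 3.32, tilt = 0, roll = 0.6, twist = 36.0)
  else
    c(shift = 0, slide = -1.5, rise = 3.31, tilt = 0, roll = 8.0,
      twist = 31.1)
}

.step_par_names <- c("shift", "slide", "rise", "tilt", "roll", "twist")
.pair_par_names <- c("shear", "stretch", "stagger", "buckle", "propeller",
                     "opening")

.as_step_matrix <- function(targets, nsteps, par_names = .step_par_names) {
  if (is.null(dim(targets))) {
    targets <- matrix(rep(as.numeric(targets[par_names]), each = nsteps),
                      nrow = nsteps, dimnames = list(NULL, par_names))
  } else {
    targets <- as.matrix(as.data.frame(targets)[, par_names, drop = FALSE])
    if (nrow(targets) != nsteps)
      stop("need one parameter row per step (", nsteps, "), got ",
           nrow(targets))
  }
  targets
}

## base-I and complementary-base frames of a pair, given the pair frame and
## the six pair parameters (inverse of pair_frame())
.pair_to_base_frames <- function(pframe, pair_par) {
  q <- pair_par
  names(q) <- .step_par_names
  omega <- q[["twist"]] * DEG2RAD
  gamma <- sqrt((q[["roll"]] * DEG2RAD)^2 + (q[["tilt"]] * DEG2RAD)^2)
  phi <- atan2(q[["tilt"]], q[["roll"]])
  Rg <- pframe$R %*% rot_z(-phi) %*% rot_y(-gamma / 2) %*%
    rot_z(phi - omega / 2)
  g <- .frame(Rg, pframe$o)  # origin fixed below
  adv <- cehs_compose(g, q)
  d <- as.numeric(adv$mid$R %*% q[c("shift", "slide", "rise")])
  f2f <- .frame(Rg, pframe$o - d / 2)
  f1 <- .frame(adv$f2$R, pframe$o + d / 2)
  list(f1 = f1, f2 = flip_frame(f2f))
}

.place_base <- function(base, frame, resno, chain, backbone = TRUE) {
  geo <- standard_base_geometry(base, backbone = backbone)
  crd <- as.matrix(geo[, c("x", "y", "z")]) %*% t(frame$R)
  crd <- sweep(crd, 2, frame$o, `+`)
  list(atoms = data.frame(name = geo$name, element = geo$element,
                          resno = resno, resname = base_resname(base),
                          chain = chain, stringsAsFactors = FALSE),
       xyz = crd)
}

#' Rebuild a duplex helix from step parameters
#'
#' Places standard base geometries by composing mid-frame rigid transforms,
#' so that frame analysis recovers the targets exactly.  The complementary
#' strand is antiparallel with Watson-Crick complementary bases; residues
#' are numbered 1..n (leading, chain A) and n+1..2n (complementary, chain B,
#' 5'->3', residue n+k pairing base pair n+1-k).
#'
#' @param sequence leading-strand sequence (5'->3').
#' @param step_targets named vector of six step parameters applied
#'   uniformly, or an (n-1) x 6 matrix/data frame (columns shift, slide,
#'   rise, tilt, roll, twist).
#' @param pair_targets optional base-pair parameters: named vector or n x 6
#'   matrix (columns shear, stretch, stagger, buckle, propeller, opening);
#'   default all zero (planar Watson-Crick geometry).
#' @return a single-frame `dna_structure`.
#' @export
rebuild_helix <- function(sequence, step_targets = canonical_step_parameters("B"),
                          pair_targets = NULL) {
  bases <- seq_letters(sequence)
  n <- length(bases)
  if (n < 2) stop("need at least 2 base pairs")
  steps <- .as_step_matrix(step_targets, n - 1)
  if (any(steps[, "rise"] <= 0))
    stop("non-physical step targets: rise must be > 0")
  if (is.null(pair_targets))
    pair_targets <- stats::setNames(rep(0, 6), .pair_par_names)
  pairs <- if (is.null(dim(pair_targets))) {
    pt <- as.numeric(pair_targets)
    if (!is.null(names(pair_targets)))
      pt <- as.numeric(pair_targets[.pair_par_names])
    matrix(rep(pt, each = n), nrow = n, dimnames = list(NULL, .pair_par_names))
  } else {
    .as_step_matrix(pair_targets, n, .pair_par_names)
  }
  pframes <- vector("list", n)
  pframes[[1]] <- .frame(diag(3), c(0, 0, 0))
  for (s in seq_len(n - 1)) {
    st <- steps[s, ]
    names(st) <- .step_par_names
    pframes[[s + 1]] <- cehs_compose(pframes[[s]], st)$f2
  }
  placed <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    bf <- .pair_to_base_frames(pframes[[i]], pairs[i, ])
    placed[[i]] <- .place_base(bases[i], bf$f1, i, "A")
    placed[[n + i]] <- .place_base(wc_complement(bases[i]), bf$f2,
                                   2 * n + 1 - i, "B")
  }
  ## order: chain A 1..n then chain B by increasing resno (5'->3' of II)
  ord <- c(seq_len(n), n + rev(seq_len(n)))
  placed <- placed[ord]
  atoms <- do.call(rbind, lapply(placed, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(placed, `[[`, "xyz"))
  dna_structure(atoms, xyz)
}

## ---------------------------------------------------------------------------
## Reverse-Hoogsteen third strand

## Planar rigid transform placing a TFO base against the Hoogsteen edge of
## a duplex purine, in the purine's standard frame.  Derived once per
## triplet type from idealized hydrogen-bond geometry (donor-acceptor
## distance 2.9 A) with the base plane flipped (trans pairing, antiparallel
## strand sense), and cached for the session.
.hoogsteen_cache <- new.env(parent = emptyenv())

.hoogsteen_transform <- function(base) {
  key <- toupper(base)
  if (!is.null(.hoogsteen_cache[[key]])) return(.hoogsteen_cache[[key]])
  dup <- standard_base_geometry(key, backbone = FALSE)
  tfo <- dup  # purine-motif triplets pair like with like (G-G, A-A)
  dmat <- as.matrix(dup[, c("x", "y", "z")]); rownames(dmat) <- dup$name
  tmat <- as.matrix(tfo[, c("x", "y", "z")]); rownames(tmat) <- tfo$name
  ## TFO base pairs through its Watson-Crick edge onto the duplex purine's
  ## Hoogsteen edge (trans orientation): G: N1..N7 and N2..O6; A: N6..N7
  ## and N1..N6.  Column 1 = TFO atom, column 2 = duplex atom.
  if (key == "G") {
    pairs <- rbind(c("N1", "N7"), c("N2", "O6"))
  } else if (key == "A") {
    pairs <- rbind(c("N6", "N7"), c("N1", "N6"))
  } else stop("reverse-Hoogsteen transform defined for purines only")
  flipT <- diag(c(1, -1, -1))
  target <- function(p) {
    a <- p[1] * DEG2RAD
    Rz <- rot_z(a)
    crd <- tmat %*% t(flipT) %*% t(Rz)
    crd[, 1] <- crd[, 1] + p[2]
    crd[, 2] <- crd[, 2] + p[3]
    crd
  }
  obj <- function(p) {
    crd <- target(p)
    e <- 0
    for (r in seq_len(nrow(pairs))) {
      d <- sqrt(sum((crd[pairs[r, 1], ] - dmat[pairs[r, 2], ])^2))
      e <- e + (d - 2.9)^2
    }
    ## soft steric penalty between all non-bonded heavy atoms
    dd <- sqrt(pmax(outer(rowSums(crd^2), rowSums(dmat^2), `+`) -
                      2 * crd %*% t(dmat), 0))
    for (r in seq_len(nrow(pairs))) dd[pairs[r, 1], pairs[r, 2]] <- Inf
    e + sum(pmax(0, 2.7 - dd)^2)
  }
  best <- NULL
  for (a0 in seq(0, 330, by = 30)) {
    for (t0 in list(c(6, 2), c(4, 5), c(2, 6), c(7, 0), c(5, -3))) {
      fit <- stats::optim(c(a0, t0), obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  p <- best$par
  M <- list(R = rot_z(p[1] * DEG2RAD) %*% flipT,
            t = c(p[2], p[3], 0))
  .hoogsteen_cache[[key]] <- M
  M
}

#' Add a reverse-Hoogsteen third strand to a duplex
#'
#' Each TFO base is placed by a fixed rigid transform relative to the frame
#' of its target purine on the leading strand, implementing trans
#' (reverse-Hoogsteen) pairing in the major groove with the TFO antiparallel
#' to the purine strand.  Heavy-atom donor-acceptor distances are checked to
#' lie in 2.7-3.1 A and steric clashes below 2.0 A are rejected.
#'
#' @param duplex single-frame `dna_structure` from [rebuild_helix()].
#' @param tfo_seq TFO sequence 5'->3' (`""` or `NULL` returns the duplex
#'   unchanged).
#' @param register leading-strand residue numbers targeted by the TFO, in
#'   the order of the *purine strand* 5'->3'; the TFO pairs antiparallel, so
#'   TFO residue 1 pairs `rev(register)[1]`.
#' @return a `dna_structure` with TFO residues appended (chain C, residue
#'   numbers 2n+1 ...).
#' @export
build_triplex <- function(duplex, tfo_seq, register) {
  stopifnot(inherits(duplex, "dna_structure"))
  if (is.null(tfo_seq) || identical(tfo_seq, "") || length(tfo_seq) == 0)
    return(duplex)
  tfo <- seq_letters(tfo_seq)
  n <- max(duplex$atoms$resno[duplex$atoms$chain == "A"])
  if (length(register) != length(tfo))
    stop("register length must equal TFO length")
  targets <- rev(register)  # antiparallel
  atoms <- duplex$atoms
  crd <- frame_coords(duplex, 1)
  lead_base <- resname_base(atoms$resname[match(targets, atoms$resno)])
  if (!all(is_purine(lead_base)))
    stop("target region contains pyrimidine(s) at residue(s): ",
         paste(targets[!is_purine(lead_base)], collapse = ", "))
  if (!all(tfo == lead_base))
    stop("purine-motif triplets require TFO base == purine base; mismatch ",
         "at TFO position(s): ", paste(which(tfo != lead_base),
                                       collapse = ", "))
  placed <- vector("list", length(tfo))
  for (t in seq_along(tfo)) {
    ix <- which(atoms$resno == targets[t])
    df <- data.frame(name = atoms$name[ix], x = crd[ix, 1], y = crd[ix, 2],
                     z = crd[ix, 3], stringsAsFactors = FALSE)
    pf <- fit_base_frame(df, lead_base[t])
    M <- .hoogsteen_transform(tfo[t])
    tf <- .frame(pf$R %*% M$R, pf$o + as.numeric(pf$R %*% M$t))
    placed[[t]] <- .place_base(tfo[t], tf, 2 * n + t, "C")
  }
  new_atoms <- do.call(rbind, lapply(placed, `[[`, "atoms"))
  new_xyz <- do.call(rbind, lapply(placed, `[[`, "xyz"))
  out <- dna_structure(rbind(atoms, new_atoms), rbind(crd, new_xyz))
  ## validation: H-bond ranges and steric clashes
  chk <- .triplex_checks(out, tfo, targets, 2 * n)
  if (!all(chk$hbond >= 2.7 & chk$hbond <= 3.1))
    stop("reverse-Hoogsteen H-bond distance outside 2.7-3.1 A: ",
         paste(sprintf("%.2f", chk$hbond[chk$hbond < 2.7 | chk$hbond > 3.1]),
               collapse = ", "))
  if (chk$min_contact < 2.0)
    stop(sprintf("steric clash: non-bonded heavy-atom distance %.2f A",
                 chk$min_contact))
  out
}

.triplex_checks <- function(x, tfo, targets, base_resno) {
  atoms <- x$atoms
  crd <- frame_coords(x, 1)
  hb <- c()
  for (t in seq_along(tfo)) {
    tr <- base_resno + t
    dr <- targets[t]
    pairs <- if (tfo[t] == "G") rbind(c("N1", "N7"), c("N2", "O6"))
             else rbind(c("N6", "N7"), c("N1", "N6"))
    for (r in seq_len(nrow(pairs))) {
      a <- crd[atom_indices(x, resno = tr, name = pairs[r, 1])[1], ]
      b <- crd[atom_indices(x, resno = dr, name = pairs[r, 2])[1], ]
      hb <- c(hb, sqrt(sum((a - b)^2)))
    }
  }
  tix <- which(atoms$chain == "C" & atoms$element != "H")
  oix <- which(atoms$chain != "C" & atoms$element != "H")
  d2 <- outer(rowSums(crd[tix, , drop = FALSE]^2),
              rowSums(crd[oix, , drop = FALSE]^2), `+`) -
    2 * crd[tix, , drop = FALSE] %*% t(crd[oix, , drop = FALSE])
  dmin <- sqrt(max(0, min(d2)))
  list(hbond = hb, min_contact = dmin)
}

## ---------------------------------------------------------------------------
## Gaussian step-parameter ensembles

#' Specify a Gaussian step-parameter ensemble
#'
#' @param sequence leading-strand sequence.
#' @param mean named 6-vector applied to every step, or (n-1) x 6 matrix.
#' @param cov 6x6 covariance of the step parameters (applied to every
#'   step), or a list of per-step 6x6 matrices; must be symmetric positive
#'   semi-definite.
#' @param n_frames number of frames to draw.
#' @param seed RNG seed.
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(sequence, mean, cov, n_frames, seed = 1) {
  bases <- seq_letters(sequence)
  nsteps <- length(bases) - 1
  mean <- .as_step_matrix(mean, nsteps)
  if (!is.list(cov)) cov <- rep(list(as.matrix(cov)), nsteps)
  if (length(cov) != nsteps) stop("need one covariance per step")
  roots <- lapply(cov, function(S) {
    S <- as.matrix(S)
    if (nrow(S) != 6 || ncol(S) != 6) stop("covariances must be 6x6")
    if (max(abs(S - t(S))) > 1e-8) stop("covariance not symmetric")
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values), 1))
      stop("covariance not positive semi-definite")
    e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  })
  structure(list(sequence = bases, mean = mean, roots = roots,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Draw a multi-frame ensemble from a Gaussian step-parameter spec
#'
#' Each frame is rebuilt from step parameters drawn independently per step
#' from the spec's Gaussian.  Seeded and bit-reproducible.
#'
#' @param spec an [ensemble_spec()].
#' @return a multi-frame `dna_structure`.
#' @export
sample_step_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  nsteps <- nrow(spec$mean)
  first <- NULL
  xyz <- NULL
  for (f in seq_len(spec$n_frames)) {
    par <- spec$mean
    for (s in seq_len(nsteps)) {
      par[s, ] <- spec$mean[s, ] +
        as.numeric(spec$roots[[s]] %*% stats::rnorm(6))
    }
    par[, "rise"] <- pmax(par[, "rise"], 0.1)  # keep physical
    st <- rebuild_helix(paste(spec$sequence, collapse = ""), par)
    if (is.null(first)) {
      first <- st
      xyz <- array(NA_real_, dim = c(nrow(st$atoms), 3, spec$n_frames))
    }
    xyz[, , f] <- frame_coords(st, 1)
  }
  dna_structure(first$atoms, xyz)
}

## ---------------------------------------------------------------------------
## Base flipping geometry

#' Rotate a base out of the helix about the backbone axis
#'
#' Rotates the base atoms (ring, exocyclic and H3; not C1'/P) of one
#' residue about the axis through the sugar centers of the residue and its
#' 3' neighbor on the same strand.  The pseudo-dihedral flipping coordinate
#' changes by exactly the applied angle.
#'
#' @param structure a `dna_structure`.
#' @param resno residue to flip.
#' @param angle rotation in degrees (positive = toward the major groove
#'   under the default sign convention).
#' @param frame frame index to modify.
#' @return the modified `dna_structure`.
#' @export
flip_base <- function(structure, resno, angle, frame = 1) {
  atoms <- structure$atoms
  crd <- frame_coords(structure, frame)
  nb <- resno + 1
  i_sug <- atom_indices(structure, resno = resno, name = "C1'")
  i_nb <- atom_indices(structure, resno = nb, name = "C1'")
  if (!length(i_sug) || !length(i_nb))
    stop("sugar (C1') atoms not found for residues ", resno, "/", nb)
  a <- colMeans(crd[i_sug, , drop = FALSE])
  b <- colMeans(crd[i_nb, , drop = FALSE])
  axis <- b - a
  ring <- which(atoms$resno == resno & !atoms$name %in% c("C1'", "P"))
  ## dihedral sign convention: rotating the base by -angle about the
  ## a -> b axis advances the pseudo-dihedral by +angle
  R <- rot_axis(axis, -angle * DEG2RAD)
  moved <- sweep(sweep(crd[ring, , drop = FALSE], 2, a) %*% t(R), 2, a, `+`)
  crd[ring, ] <- moved
  set_frame_coords(structure, frame, crd)
}
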