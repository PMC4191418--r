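## Ensemble-level analyses: region statistics with block-averaged errors,
## groove widths, stacking overlap areas, bend angles, Roll-Slide
## variability, covariance ellipses, and all-atom PCA.

#' Block-averaged standard error of the mean (Flyvbjerg-Petersen)
#'
#' Doubles the block size until the blocked SEM estimate plateaus (first
#' block size at which the change is below `plateau_tol`), which corrects
#' the naive SEM for serial correlation.
#'
#' @param x numeric time series.
#' @param min_blocks smallest number of blocks still used (default 4).
#' @param plateau_tol relative SEM change defining the plateau (default 0.05).
#' @return list with `sem`, `block_size`, and the full `profile` of
#'   (block_size, sem) pairs.
#' @export
block_sem <- function(x, min_blocks = 4, plateau_tol = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 * min_blocks)
    stop("series too short for block averaging: ", n, " < ", 2 * min_blocks)
  if (stats::sd(x) == 0)
    return(list(sem = 0, block_size = 1,
                profile = data.frame(block_size = 1, sem = 0)))
  bs <- 1
  prof <- NULL
  repeat {
    nb <- n %/% bs
    if (nb < min_blocks) break
    bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
    sem <- stats::sd(bm) / sqrt(nb)
    prof <- rbind(prof, data.frame(block_size = bs, sem = sem))
    bs <- bs * 2
  }
  sem <- prof$sem[nrow(prof)]
  bsz <- prof$block_size[nrow(prof)]
  if (nrow(prof) > 1) {
    rel <- abs(diff(prof$sem)) / pmax(prof$sem[-nrow(prof)], .Machine$double.eps)
    hit <- which(rel < plateau_tol)
    if (length(hit)) {
      sem <- prof$sem[hit[1] + 1]
      bsz <- prof$block_size[hit[1] + 1]
    }
  }
  list(sem = sem, block_size = bsz, profile = prof)
}

#' Region-averaged step statistics with blocked errors
#'
#' Two-stage averaging: per-step time averages first, then the region mean
#' over its steps.  The SEM is obtained by block averaging the per-frame
#' region-mean series.
#'
#' @param tab long step table from [step_table()].
#' @param parameters which parameter columns to summarize.
#' @param min_blocks passed to [block_sem()].
#' @return data frame with one row per region x parameter: `region`,
#'   `parameter`, `mean`, `sem`, `n_steps`, `n_frames`.
#' @export
region_statistics <- function(tab, parameters = c("shift", "slide", "rise",
                                                  "tilt", "roll", "twist"),
                              min_blocks = 4) {
  out <- NULL
  for (rg in unique(tab$region)) {
    sub <- tab[tab$region == rg, ]
    nfr <- length(unique(sub$frame))
    for (p in parameters) {
      per_step <- tapply(sub[[p]], sub$step, mean)
      m <- mean(per_step)
      series <- tapply(sub[[p]], sub$frame, mean)  # per-frame region mean
      sem <- if (nfr >= 2 * min_blocks)
        block_sem(as.numeric(series), min_blocks)$sem else NA_real_
      out <- rbind(out, data.frame(region = rg, parameter = p, mean = m,
                                   sem = sem,
                                   n_steps = length(per_step),
                                   n_frames = nfr,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Groove widths

#' Groove widths as inter-strand phosphorus-phosphorus distances
#'
#' Raw P-P distances (no van-der-Waals correction) with fixed cross-strand
#' index offsets: at base pair i, the minor groove spans P(i, strand I) to
#' P(i + minor_offset, strand II) and the major groove P(i, strand I) to
#' P(i + major_offset, strand II).  Base pairs whose partner index falls
#' off the helix are reported as `NA`.
#'
#' @param structure a `dna_structure`.
#' @param annotation a `pairing_annotation`.
#' @param minor_offset,major_offset cross-strand index offsets (-2, +2).
#' @param frames frame indices (default all).
#' @return data frame per base pair: mean and SD of each width over frames.
#' @export
groove_widths <- function(structure, annotation, minor_offset = -2,
                          major_offset = 2, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(structure))
  n <- annotation$n_bp
  p_index <- function(resno) {
    ix <- atom_indices(structure, resno = resno, name = "P")
    if (length(ix)) ix[1] else NA_integer_
  }
  pI <- vapply(seq_len(n), p_index, 1L)
  pII <- vapply(2L * n + 1L - seq_len(n), p_index, 1L)
  width <- function(crd, i, off) {
    j <- i + off
    if (j < 1 || j > n || is.na(pI[i]) || is.na(pII[j])) return(NA_real_)
    sqrt(sum((crd[pI[i], ] - crd[pII[j], ])^2))
  }
  minor <- matrix(NA_real_, length(frames), n)
  major <- matrix(NA_real_, length(frames), n)
  for (k in seq_along(frames)) {
    crd <- frame_coords(structure, frames[k])
    for (i in seq_len(n)) {
      minor[k, i] <- width(crd, i, minor_offset)
      major[k, i] <- width(crd, i, major_offset)
    }
  }
  data.frame(bp = seq_len(n),
             minor_mean = colMeans(minor), minor_sd = apply(minor, 2, stats::sd),
             major_mean = colMeans(major), major_sd = apply(major, 2, stats::sd))
}

## ---------------------------------------------------------------------------
## Polygon machinery (convex) and stacking overlaps

#' Shoelace area of a polygon (vertices in order)
#' @keywords internal
#' @noRd
polygon_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

#' Clip convex polygon `subj` by convex polygon `clip` (Sutherland-Hodgman)
#' @keywords internal
#' @noRd
convex_clip <- function(subj, clip) {
  ## ensure counter-clockwise clip polygon
  n <- nrow(clip)
  i2 <- c(2:n, 1)
  if (sum(clip[, 1] * clip[i2, 2] - clip[i2, 1] * clip[, 2]) < 0)
    clip <- clip[rev(seq_len(n)), , drop = FALSE]
  out <- subj
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- ex * (out[, 2] - a[2]) - ey * (out[, 1] - a[1])
    keep <- side >= -1e-12
    m <- nrow(out)
    nxt <- c(2:m, 1)
    res <- NULL
    for (v in seq_len(m)) {
      w <- nxt[v]
      if (keep[v]) res <- rbind(res, out[v, ])
      if (keep[v] != keep[w]) {
        t <- side[v] / (side[v] - side[w])
        res <- rbind(res, out[v, ] + t * (out[w, ] - out[v, ]))
      }
    }
    out <- res
  }
  out
}

#' Stacking overlap areas of a base-pair step
#'
#' Projects the base-pair polygons of two stacked pairs onto the step
#' mid-frame xy-plane and intersects them.  The endocyclic polygon is the
#' convex hull of the projected ring atoms of the two paired bases; the
#' exocyclic polygon additionally includes the exocyclic substituents.
#'
#' @param structure a `dna_structure`.
#' @param annotation a `pairing_annotation`.
#' @param step step index (between base pairs `step` and `step + 1`).
#' @param frame frame index.
#' @return named vector `endocyclic`, `exocyclic` (Angstrom^2).
#' @export
overlap_areas <- function(structure, annotation, step, frame = 1) {
  n <- annotation$n_bp
  if (step < 1 || step >= n) stop("step index out of range")
  crd <- frame_coords(structure, frame)
  atoms <- structure$atoms
  pair_poly <- function(i, mid, exo) {
    res <- c(i, annotation$wc_pairs[i, "j"])
    pts <- NULL
    for (r in res) {
      ix <- which(atoms$resno == r)
      base <- resname_base(atoms$resname[ix[1]])
      keep <- atoms$name[ix] %in% .ring_atoms[[base]]
      if (exo) keep <- keep | atoms$name[ix] %in% .exocyclic_atoms[[base]]
      pts <- rbind(pts, crd[ix[keep], , drop = FALSE])
    }
    ## project into mid-frame xy
    loc <- sweep(pts, 2, mid$o) %*% mid$R
    loc[, 1:2, drop = FALSE]
  }
  bf <- base_frames(structure, frame,
                    c(step, step + 1, annotation$wc_pairs[c(step, step + 1), "j"]))
  pf1 <- pair_frame(bf[[as.character(step)]],
                    bf[[as.character(annotation$wc_pairs[step, "j"])]])$frame
  pf2 <- pair_frame(bf[[as.character(step + 1)]],
                    bf[[as.character(annotation$wc_pairs[step + 1, "j"])]])$frame
  mid <- step_parameters(pf1, pf2)$mid
  ov <- function(exo) {
    p1 <- pair_poly(step, mid, exo)
    p2 <- pair_poly(step + 1, mid, exo)
    h1 <- p1[grDevices::chull(p1), , drop = FALSE]
    h2 <- p2[grDevices::chull(p2), , drop = FALSE]
    inter <- convex_clip(h1, h2)
    if (is.null(inter) || nrow(inter) < 3) 0 else polygon_area(inter)
  }
  c(endocyclic = ov(FALSE), exocyclic = ov(TRUE))
}

## ---------------------------------------------------------------------------
## Bend angles

#' Base-pair center-of-mass bend angles
#'
#' Angle at the vertex base pair between the centers of mass of two
#' equidistant base pairs, per frame.  The base-pair center of mass uses
#' all heavy atoms of the two Watson-Crick bases (no sugars/phosphates).
#'
#' @param structure a `dna_structure`.
#' @param annotation a `pairing_annotation`.
#' @param vertex vertex base-pair index (middle of the helix by default).
#' @param distances vector of neighbor distances d; angle(i) uses base
#'   pairs `vertex - d` and `vertex + d`.
#' @param frames frame indices (default all).
#' @return data frame with columns `distance`, `frame`, `angle` (degrees).
#' @export
bend_angles <- function(structure, annotation, vertex = NULL,
                        distances = NULL, frames = NULL) {
  n <- annotation$n_bp
  if (is.null(vertex)) vertex <- (n + 1) %/% 2
  if (is.null(distances)) distances <- seq_len(min(vertex - 1, n - vertex))
  if (any(vertex - distances < 1) || any(vertex + distances > n))
    stop("distance(s) out of range for vertex ", vertex)
  if (is.null(frames)) frames <- seq_len(n_frames(structure))
  atoms <- structure$atoms
  base_ix <- function(i) {
    res <- c(i, annotation$wc_pairs[i, "j"])
    which(atoms$resno %in% res & !atoms$name %in% c("C1'", "P") &
            atoms$element != "H")
  }
  com_ix <- lapply(seq_len(n), base_ix)
  out <- NULL
  for (f in frames) {
    crd <- frame_coords(structure, f)
    coms <- t(vapply(com_ix, function(ix) colMeans(crd[ix, , drop = FALSE]),
                     numeric(3)))
    for (d in distances) {
      v1 <- coms[vertex - d, ] - coms[vertex, ]
      v2 <- coms[vertex + d, ] - coms[vertex, ]
      cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      out <- rbind(out, data.frame(distance = d, frame = f,
                                   angle = acos(max(-1, min(1, cosv))) *
                                     RAD2DEG))
    }
  }
  out
}

## ---------------------------------------------------------------------------
## PCA of the coordinate ensemble

#' Principal component analysis of an all-atom ensemble
#'
#' Each frame is rigid-body superposed onto the first frame using the fit
#' region's atoms, then the covariance of all atomic coordinates is
#' spectrally decomposed.  Eigenvalues are reported for all 3N degrees of
#' freedom (zeros beyond the ensemble rank).
#'
#' @param structure a multi-frame `dna_structure`.
#' @param fit_resno residues used for the superposition (default: all).
#' @return list with `eigenvalues`, `eigenvectors` (3N x k, the non-trivial
#'   modes), `projections` (frames x k), `fractions`, `n_dof`.
#' @export
pca_ensemble <- function(structure, fit_resno = NULL) {
  nf <- n_frames(structure)
  if (nf < 2) stop("PCA needs at least 2 frames")
  if (is.null(fit_resno)) fit_resno <- unique(structure$atoms$resno)
  fit_ix <- which(structure$atoms$resno %in% fit_resno)
  nat <- nrow(structure$atoms)
  ref <- frame_coords(structure, 1)
  X <- matrix(NA_real_, nf, 3 * nat)
  for (f in seq_len(nf)) {
    crd <- frame_coords(structure, f)
    fit <- kabsch(crd[fit_ix, , drop = FALSE], ref[fit_ix, , drop = FALSE])
    crd <- sweep(crd %*% t(fit$R), 2, fit$t, `+`)
    X[f, ] <- as.vector(t(crd))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = min(nf, 3 * nat), nv = min(nf, 3 * nat))
  lambda <- sv$d^2 / (nf - 1)
  keep <- lambda > max(lambda) * 1e-12
  evals <- c(lambda[keep], rep(0, 3 * nat - sum(keep)))
  list(eigenvalues = evals,
       eigenvectors = sv$v[, keep, drop = FALSE],
       projections = (Xc %*% sv$v)[, keep, drop = FALSE],
       fractions = evals / sum(evals),
       n_dof = 3L * nat)
}

## ---------------------------------------------------------------------------
## Covariance ellipses and Roll-Slide variability

#' Covariance ellipse of roll-slide samples
#'
#' The ellipse `(x - mu)^T S^{-1} (x - mu) = score^2` of the sample
#' covariance `S`; at the default score 3 it is the 3-sigma harmonic
#' equi-potential contour and contains about 98.9% of a large Gaussian
#' sample.
#'
#' @param samples two-column matrix (roll, slide) or data frame.
#' @param score contour score (default 3).
#' @return list with `center`, `cov`, `semi_axes`, `angle` (degrees,
#'   orientation of the major axis), `degenerate` flag.
#' @export
covariance_ellipse <- function(samples, score = 3) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 3) stop("need at least 3 samples")
  mu <- colMeans(samples)
  S <- stats::cov(samples)
  e <- eigen(S, symmetric = TRUE)
  degen <- e$values[2] < max(e$values) * 1e-10
  list(center = mu, cov = S,
       semi_axes = score * sqrt(pmax(e$values, 0)),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]) * RAD2DEG,
       score = score, degenerate = degen)
}

#' Is a point inside a covariance ellipse?
#' @param ellipse result of [covariance_ellipse()].
#' @param points two-column matrix.
#' @return logical vector.
#' @export
in_ellipse <- function(ellipse, points) {
  points <- as.matrix(points)
  d <- sweep(points, 2, ellipse$center)
  md2 <- rowSums((d %*% solve(ellipse$cov)) * d)
  md2 <= ellipse$score^2
}

#' Per-step variability of roll and slide
#'
#' Standard deviation over frames for each unique step, grouped by the
#' pyrimidine/purine step class (YR, RR, RY, YY).
#'
#' @param tab long table from [step_table()].
#' @return data frame: `step`, `label`, `class`, `region`, `sd_roll`,
#'   `sd_slide`.
#' @export
variability_summary <- function(tab) {
  cls <- function(lab) {
    ry <- ifelse(substr(lab, 1, 1) %in% c("A", "G"), "R", "Y")
    ry2 <- ifelse(substr(lab, 2, 2) %in% c("A", "G"), "R", "Y")
    paste0(ry, ry2)
  }
  steps <- unique(tab$step)
  out <- NULL
  for (s in steps) {
    sub <- tab[tab$step == s, ]
    out <- rbind(out, data.frame(
      step = s, label = sub$label[1], class = cls(sub$label[1]),
      region = sub$region[1],
      sd_roll = stats::sd(sub$roll), sd_slide = stats::sd(sub$slide),
      stringsAsFactors = FALSE))
  }
  out
}
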