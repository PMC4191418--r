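test_that("blocked SEM matches closed forms for iid and AR(1) series", {
  set.seed(81)
  ## iid: sigma / sqrt(N)
  x <- rnorm(4096, sd = 2.5)
  got <- block_sem(x)$sem
  expect_equal(got, 2.5 / sqrt(4096), tolerance = 0.2)
  ## constant series
  expect_equal(block_sem(rep(3.2, 64))$sem, 0)
  ## AR(1): sigma_x * sqrt((1 + phi) / (1 - phi) / N)
  phi <- 0.8
  n <- 16384
  ar <- as.numeric(arima.sim(list(ar = phi), n, sd = 1))
  sem_true <- sd(ar) * sqrt((1 + phi) / (1 - phi) / n)
  expect_equal(block_sem(ar)$sem, sem_true, tolerance = 0.25)
  expect_error(block_sem(rnorm(5)), "too short")
})

test_that("region statistics follow the two-stage averaging contract", {
  spec <- ensemble_spec("GAGGGA", canonical_step_parameters("B"),
                        diag(c(.2, .2, .1, 2, 3, 3)^2), n_frames = 64,
                        seed = 12)
  ens <- sample_step_ensemble(spec)
  sysd <- system_definition("GAGGGA")
  tab <- step_table(ens, annotate_system(ens, sysd))
  rs <- region_statistics(tab)
  tw <- rs[rs$parameter == "twist", ]
  per_step <- tapply(tab$twist, tab$step, mean)
  expect_equal(tw$mean, mean(per_step), tolerance = 1e-10)
  expect_gte(tw$sem, 0)
})

test_that("groove widths are Euclidean distances with rigid-motion invariance", {
  ## two parallel straight strands 10 Angstrom apart: hand-placed P atoms
  n <- 8
  atoms <- NULL; xyz <- NULL
  for (i in 1:n) {
    atoms <- rbind(atoms,
                   data.frame(name = c("N1", "P"), element = c("N", "P"),
                              resno = i, resname = "DA", chain = "A"))
    xyz <- rbind(xyz, c(1, 0, i * 3), c(0, 0, i * 3))
  }
  for (i in 1:n) {
    atoms <- rbind(atoms,
                   data.frame(name = c("N1", "P"), element = c("N", "P"),
                              resno = 2 * n + 1 - i,
                              resname = "DT", chain = "B"))
    xyz <- rbind(xyz, c(1, 10, i * 3), c(0, 10, i * 3))
  }
  st <- dna_structure(atoms, xyz)
  ann <- structure(list(wc_pairs = cbind(i = 1:n, j = 2 * n + 1 - (1:n)),
                        hoogsteen_pairs = NULL,
                        regions = list(all = c(1L, n)), n_bp = n),
                   class = "pairing_annotation")
  gw <- groove_widths(st, ann, minor_offset = 0, major_offset = 0)
  expect_equal(gw$minor_mean, rep(10, n), tolerance = 1e-10)
  ## offset +-2: Euclidean oracle sqrt(10^2 + 6^2), terminals NA
  gw2 <- groove_widths(st, ann, minor_offset = -2, major_offset = 2)
  expect_true(all(is.na(gw2$minor_mean[1:2])))
  expect_equal(gw2$major_mean[1], sqrt(100 + 36), tolerance = 1e-10)
  ## rigid motion leaves widths unchanged
  R <- random_rotation()
  st2 <- st
  st2$xyz[, , 1] <- st$xyz[, , 1] %*% t(R) + rep(c(5, -3, 2),
                                                 each = nrow(atoms))
  gw3 <- groove_widths(st2, ann, minor_offset = 0, major_offset = 0)
  expect_equal(gw3$minor_mean, gw$minor_mean, tolerance = 1e-9)
})

test_that("triplex homo-purine major groove widens; duplex regions do not", {
  sysd <- purine_triplex_system()
  seqs <- paste(sysd$duplex_seq, collapse = "")
  dup <- rebuild_helix(seqs, example_step_targets(sysd, bound = FALSE))
  tri <- build_triplex(rebuild_helix(seqs,
                                     example_step_targets(sysd, bound = TRUE)),
                       paste(sysd$tfo_seq, collapse = ""), sysd$tfo_target)
  annD <- annotate_system(dup, purine_triplex_system(with_tfo = FALSE))
  annT <- annotate_system(tri, sysd)
  gD <- groove_widths(dup, annD)
  gT <- groove_widths(tri, annT)
  hp <- 12:19; fd <- 3:9; sd2 <- 22:28
  expect_gt(mean(gT$major_mean[hp]) - mean(gD$major_mean[hp]), 1)
  expect_lt(abs(mean(gT$major_mean[fd]) - mean(gD$major_mean[fd])), 0.5)
  expect_lt(abs(mean(gT$major_mean[sd2]) - mean(gD$major_mean[sd2])), 0.5)
})

test_that("overlap areas match trivial and Monte-Carlo oracles", {
  sq <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
  ## coincident polygons -> full area; far separation -> zero
  expect_equal(stepflip:::polygon_area(
    stepflip:::convex_clip(sq, sq)), 16, tolerance = 1e-10)
  expect_null(stepflip:::convex_clip(sq, sq + 10))
  ## real step geometry vs Monte-Carlo point-in-polygon estimate
  dup <- example_duplex()
  ann <- annotate_system(dup, purine_triplex_system(with_tfo = FALSE))
  ov <- overlap_areas(dup, ann, 15)
  expect_true(all(ov >= 0))
  expect_gte(ov[["exocyclic"]], ov[["endocyclic"]])
  set.seed(91)
  for (rep in 1:5) {
    p1 <- cbind(runif(7, -3, 3), runif(7, -3, 3))
    p2 <- cbind(runif(7, -2, 4), runif(7, -2, 4))
    h1 <- p1[grDevices::chull(p1), ]
    h2 <- p2[grDevices::chull(p2), ]
    inter <- stepflip:::convex_clip(h1, h2)
    area <- if (is.null(inter) || nrow(inter) < 3) 0
            else stepflip:::polygon_area(inter)
    expect_equal(area, mc_overlap(h1, h2, n = 2e5), tolerance = 0.03)
  }
})

test_that("bend angles satisfy collinear and inscribed-circle geometry", {
  ## untwisted vertical stack: centers of mass exactly collinear -> 180
  st <- rebuild_helix("AAAAAAAAA", c(shift = 0, slide = 0, rise = 3.3,
                                     tilt = 0, roll = 0, twist = 0))
  ann <- annotate_system(st, system_definition("AAAAAAAAA"))
  ba <- bend_angles(st, ann, vertex = 5, distances = 1:4)
  expect_equal(ba$angle, rep(180, 4), tolerance = 1e-6)
  ## hand-built planar arc: inscribed angle = 180 - d * step / 2
  n <- 9; Rc <- 40; dphi <- 10 * pi / 180
  atoms <- NULL; xyz <- NULL
  for (i in 1:n) {
    atoms <- rbind(atoms, data.frame(name = "N1", element = "N", resno = i,
                                     resname = "DA", chain = "A"))
    xyz <- rbind(xyz, c(Rc * cos(i * dphi), Rc * sin(i * dphi), 0))
  }
  for (i in 1:n) {
    atoms <- rbind(atoms, data.frame(name = "N1", element = "N",
                                     resno = 2 * n + 1 - i,
                                     resname = "DT", chain = "B"))
    xyz <- rbind(xyz, c(Rc * cos(i * dphi), Rc * sin(i * dphi), 0))
  }
  arc <- dna_structure(atoms, xyz)
  ann2 <- structure(list(wc_pairs = cbind(i = 1:n, j = 2 * n + 1 - (1:n)),
                         hoogsteen_pairs = NULL,
                         regions = list(all = c(1L, n)), n_bp = n),
                    class = "pairing_annotation")
  ba2 <- bend_angles(arc, ann2, vertex = 5, distances = 1:4)
  expect_equal(ba2$angle, 180 - (1:4) * 10, tolerance = 1e-6)
  expect_error(bend_angles(arc, ann2, vertex = 5, distances = 5), "range")
  ## rigid-motion invariance
  R <- random_rotation()
  arc2 <- arc
  arc2$xyz[, , 1] <- arc$xyz[, , 1] %*% t(R) + rep(c(1, 2, 3), each = 2 * n)
  expect_equal(bend_angles(arc2, ann2, vertex = 5, distances = 1:4)$angle,
               ba2$angle, tolerance = 1e-8)
})

test_that("PCA recovers planted modes and satisfies its invariants", {
  dup <- example_duplex()
  nat <- nrow(dup$atoms)
  ## frames displaced along one known vector -> single mode, fraction 1
  set.seed(101)
  v <- rnorm(3 * nat); v <- v / sqrt(sum(v^2))
  amp <- rnorm(12, sd = 2)
  xyz <- array(NA_real_, c(nat, 3, 12))
  base <- frame_coords(dup, 1)
  for (f in 1:12)
    xyz[, , f] <- base + matrix(amp[f] * v, ncol = 3, byrow = TRUE)
  ens1 <- dna_structure(dup$atoms, xyz)
  p1 <- pca_ensemble(ens1)
  expect_equal(p1$fractions[1], 1, tolerance = 1e-6)
  ## the fitted ensemble stays one-dimensional; the mode matches the
  ## planted vector up to its (small) rigid-body component, which the
  ## superposition legitimately removes
  expect_equal(abs(sum(p1$eigenvectors[, 1] * v)), 1, tolerance = 5e-3)
  expect_equal(p1$n_dof, 3 * nat)
  expect_length(p1$eigenvalues, 3 * nat)
  ## two planted modes with known variances 9 and 1
  v2 <- rnorm(3 * nat); v2 <- v2 - sum(v2 * v) * v
  v2 <- v2 / sqrt(sum(v2^2))
  nf <- 600
  a1 <- rnorm(nf, sd = 3); a2 <- rnorm(nf, sd = 1)
  xyz2 <- array(NA_real_, c(nat, 3, nf))
  for (f in 1:nf)
    xyz2[, , f] <- base + matrix(a1[f] * v + a2[f] * v2, ncol = 3,
                                 byrow = TRUE)
  ens2 <- dna_structure(dup$atoms, xyz2)
  p2 <- pca_ensemble(ens2)
  expect_equal(p2$eigenvalues[1], 9, tolerance = 5 * sqrt(2 / (nf - 1)))
  expect_equal(p2$eigenvalues[2], 1, tolerance = 5 * sqrt(2 / (nf - 1)))
  expect_lt(p2$eigenvalues[3] / p2$eigenvalues[1], 0.05)
  ## invariants: fractions sum to 1, projections centred
  expect_equal(sum(p2$fractions), 1, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(p2$projections))), 1e-8)
  expect_equal(sum(p2$eigenvalues), 9 + 1,
               tolerance = 10 * sqrt(2 / (nf - 1)))
  expect_error(pca_ensemble(dup), "at least 2")
})

test_that("covariance ellipses follow the chi-square geometry", {
  ## isotropic: circle of radius 3 sigma
  set.seed(111)
  iso <- matrix(rnorm(2 * 5000, sd = 2), ncol = 2)
  e <- covariance_ellipse(iso)
  expect_equal(e$semi_axes[1], 6, tolerance = 0.1)
  expect_equal(e$semi_axes[2], 6, tolerance = 0.1)
  ## diagonal (4, 1) at score 3: semi-axes 6 and 3 (eigen closed form),
  ## using samples transformed to have exactly that sample covariance
  z0 <- matrix(rnorm(2 * 200), ncol = 2)
  z0 <- scale(z0, scale = FALSE)
  ex <- z0 %*% solve(chol(cov(z0))) %*% chol(diag(c(4, 1)))
  ed <- covariance_ellipse(ex, score = 3)
  expect_equal(unname(ed$semi_axes), c(6, 3), tolerance = 1e-9)
  ## correlated Gaussian: ~98.9% inside the 3-sigma ellipse (chi^2_2)
  L <- matrix(c(2, 0.9, 0, 0.8), 2, 2)
  z <- matrix(rnorm(2 * 40000), ncol = 2) %*% t(L)
  ec <- covariance_ellipse(z)
  cover <- mean(in_ellipse(ec, z))
  expect_equal(cover, pchisq(9, df = 2), tolerance = 0.005)
  expect_error(covariance_ellipse(z[1:2, ]), "at least 3")
  ## degenerate data flagged
  degen <- cbind(1:100, (1:100) * 2)
  expect_true(covariance_ellipse(degen)$degenerate)
})

test_that("roll/slide variability reproduces the deformability ordering", {
  seqs <- paste(purine_triplex_system()$duplex_seq, collapse = "")
  spec <- ensemble_spec(seqs, canonical_step_parameters("B"),
                        deformability_covariances(seqs), n_frames = 80,
                        seed = 13)
  ens <- sample_step_ensemble(spec)
  ann <- annotate_system(ens, purine_triplex_system(with_tfo = FALSE))
  vs <- variability_summary(step_table(ens, ann))
  m <- tapply(vs$sd_roll, vs$class, mean)
  expect_gt(m[["YR"]], m[["RR"]])
  expect_gt(m[["RR"]], m[["RY"]])
  ms <- tapply(vs$sd_slide, vs$class, mean)
  expect_gt(ms[["YR"]], ms[["RR"]])
  expect_gt(ms[["RR"]], ms[["RY"]])
  ## constant ensemble -> all zero
  z <- ensemble_spec("ACGT", canonical_step_parameters("B"),
                     matrix(0, 6, 6), n_frames = 6, seed = 1)
  vz <- variability_summary(step_table(sample_step_ensemble(z),
                                       annotate_system(sample_step_ensemble(z),
                                                       system_definition("ACGT"))))
  expect_equal(vz$sd_roll, rep(0, 3), tolerance = 1e-10)
})
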