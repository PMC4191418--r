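test_that("base-frame fitting recovers exact and noisy transforms", {
  geo <- standard_base_geometry("G", backbone = FALSE)
  df <- geo[, c("name", "x", "y", "z")]
  ## exact standard placement -> identity frame
  f0 <- fit_base_frame(df, "G")
  expect_lt(max(abs(f0$R - diag(3))), 1e-10)
  expect_lt(max(abs(f0$o)), 1e-10)
  expect_lt(f0$rmsd, 1e-10)
  set.seed(11)
  for (rep in 1:20) {
    R <- random_rotation(); t <- rnorm(3, 0, 10)
    pl <- df
    pl[, 2:4] <- as.matrix(df[, 2:4]) %*% t(R) + rep(t, each = nrow(df))
    fit <- fit_base_frame(pl, "G")
    expect_lt(max(abs(fit$R - R)), 1e-8)
    expect_lt(max(abs(fit$o - t)), 1e-8)
    ## with noise: agree with the quaternion superposition oracle
    pl2 <- pl
    pl2[, 2:4] <- as.matrix(pl[, 2:4]) + rnorm(3 * nrow(pl), 0, 0.05)
    fit2 <- fit_base_frame(pl2, "G")
    std <- standard_base_geometry("G", backbone = FALSE)
    std <- std[std$ring, ]
    m <- match(std$name, pl2$name)
    oracle <- horn_superpose(as.matrix(std[, c("x", "y", "z")]),
                             as.matrix(pl2[m, 2:4]))
    expect_lt(max(abs(fit2$R - oracle$R)), 1e-8)
    expect_lt(max(abs(fit2$o - oracle$t)), 1e-8)
  }
  expect_error(fit_base_frame(df[1:2, ], "G"), "ring atoms")
})

test_that("compose and decompose are exact mutual inverses", {
  set.seed(21)
  worst <- 0
  for (i in 1:300) {
    par <- c(shift = rnorm(1, 0, 1), slide = rnorm(1, 0, 1),
             rise = runif(1, 2.5, 4.5), tilt = rnorm(1, 0, 8),
             roll = rnorm(1, 0, 10), twist = runif(1, 10, 60))
    f1 <- list(R = random_rotation(), o = rnorm(3, 0, 10))
    fwd <- cehs_compose(f1, par)
    back <- cehs_decompose(f1, fwd$f2)
    worst <- max(worst, max(abs(back$par - par)),
                 max(abs(back$mid$R - fwd$mid$R)),
                 max(abs(back$mid$o - fwd$mid$o)))
  }
  expect_lt(worst, 1e-6)
})

test_that("a pure z-rotation plus z-translation gives the canonical step", {
  f1 <- list(R = diag(3), o = c(0, 0, 0))
  f2 <- list(R = stepflip:::rot_z(36 * pi / 180), o = c(0, 0, 3.32))
  dec <- cehs_decompose(f1, f2)
  expect_equal(unname(dec$par[["twist"]]), 36, tolerance = 1e-10)
  expect_equal(unname(dec$par[["rise"]]), 3.32, tolerance = 1e-10)
  expect_lt(max(abs(dec$par[c("shift", "slide", "tilt", "roll")])), 1e-10)
  ## identity step -> all zeros
  dec0 <- cehs_decompose(f1, f1)
  expect_lt(max(abs(dec0$par)), 1e-10)
})

test_that("pair parameters have the documented swap symmetry", {
  set.seed(31)
  for (i in 1:30) {
    f1 <- list(R = random_rotation(), o = rnorm(3))
    ## a nearly-paired partner: flipped frame plus a small perturbation
    pert <- stepflip:::rot_axis(rnorm(3), runif(1, 0, 0.2))
    f2 <- list(R = pert %*% f1$R %*% diag(c(1, -1, -1)),
               o = f1$o + rnorm(3, 0, 0.5))
    a <- pair_frame(f1, f2)$par
    b <- pair_frame(f2, f1)$par
    expect_equal(unname(b[["shear"]]), -unname(a[["shear"]]), tolerance = 1e-8)
    expect_equal(unname(b[["buckle"]]), -unname(a[["buckle"]]), tolerance = 1e-8)
    expect_equal(unname(b[c("stretch", "stagger", "propeller", "opening")]),
                 unname(a[c("stretch", "stagger", "propeller", "opening")]),
                 tolerance = 1e-8)
  }
  ## coincident frames after flip -> all six parameters zero
  f1 <- list(R = random_rotation(), o = rnorm(3))
  f2 <- list(R = f1$R %*% diag(c(1, -1, -1)), o = f1$o)
  expect_lt(max(abs(pair_frame(f1, f2)$par)), 1e-10)
})

test_that("a constructed propeller twist is measured back exactly", {
  st <- rebuild_helix("ACGT", pair_targets = c(shear = 0, stretch = 0,
                                               stagger = 0, buckle = 0,
                                               propeller = -12, opening = 0))
  bf <- base_frames(st)
  pp <- pair_frame(bf[["2"]], bf[["7"]])$par
  expect_equal(unname(pp[["propeller"]]), -12, tolerance = 1e-6)
  expect_lt(max(abs(pp[c("shear", "stretch", "stagger", "buckle",
                         "opening")])), 1e-6)
})

test_that("strand-direction reversal negates shift and tilt only", {
  set.seed(41)
  flipx <- function(f) list(R = f$R %*% diag(c(1, -1, -1)), o = f$o)
  for (i in 1:30) {
    par <- c(shift = rnorm(1), slide = rnorm(1), rise = runif(1, 3, 4),
             tilt = rnorm(1, 0, 6), roll = rnorm(1, 0, 8),
             twist = runif(1, 20, 50))
    f1 <- list(R = random_rotation(), o = rnorm(3))
    f2 <- cehs_compose(f1, par)$f2
    rev_par <- cehs_decompose(flipx(f2), flipx(f1))$par
    expect_equal(unname(rev_par[c("shift", "tilt")]),
                 -unname(par[c("shift", "tilt")]), tolerance = 1e-8)
    expect_equal(unname(rev_par[c("slide", "rise", "roll", "twist")]),
                 unname(par[c("slide", "rise", "roll", "twist")]),
                 tolerance = 1e-8)
  }
})

test_that("helical parameters match screw-decomposition oracles", {
  f1 <- list(R = diag(3), o = c(0, 0, 0))
  ## pure twist: axis through the origin, no displacement or inclination
  st <- step_parameters(f1, cehs_compose(
    f1, c(shift = 0, slide = 0, rise = 3.32, tilt = 0, roll = 0,
          twist = 36))$f2)
  hp <- helical_parameters(st)
  expect_lt(max(abs(hp[c("x_disp", "y_disp", "inclination", "tip")])), 1e-9)
  expect_equal(unname(hp[["h_twist"]]), 36, tolerance = 1e-9)
  expect_equal(unname(hp[["h_rise"]]), 3.32, tolerance = 1e-9)
  ## negative slide -> negative x-displacement
  stn <- step_parameters(f1, cehs_compose(
    f1, c(shift = 0, slide = -1.5, rise = 3.3, tilt = 0, roll = 0,
          twist = 34))$f2)
  expect_lt(helical_parameters(stn)[["x_disp"]], 0)
  stp <- step_parameters(f1, cehs_compose(
    f1, c(shift = 0, slide = 1.5, rise = 3.3, tilt = 0, roll = 0,
          twist = 34))$f2)
  expect_gt(helical_parameters(stp)[["x_disp"]], 0)
  ## random steps: rotation angle/axis and the screw-fixed-line property
  set.seed(51)
  for (i in 1:40) {
    par <- c(shift = rnorm(1), slide = rnorm(1), rise = runif(1, 3, 4),
             tilt = rnorm(1, 0, 6), roll = rnorm(1, 0, 8),
             twist = runif(1, 15, 55))
    g1 <- list(R = random_rotation(), o = rnorm(3, 0, 5))
    g2 <- cehs_compose(g1, par)$f2
    st <- step_parameters(g1, g2)
    hp <- helical_parameters(st)
    Rot <- g2$R %*% t(g1$R)
    ang <- acos((sum(diag(Rot)) - 1) / 2) * 180 / pi
    expect_equal(abs(unname(hp[["h_twist"]])), ang, tolerance = 1e-8)
    u <- attr(hp, "axis"); p <- attr(hp, "axis_point")
    ## points on the axis advance by exactly h_rise along the axis
    img <- as.numeric(Rot %*% (p - g1$o)) + g2$o
    expect_lt(max(abs(img - (p + hp[["h_rise"]] * u))), 1e-6)
    ## x/y displacement reconstructs the perpendicular offset of o1
    v <- g1$o - p
    v <- v - sum(v * u) * u
    expect_equal(sqrt(sum(v^2)),
                 sqrt(hp[["x_disp"]]^2 + hp[["y_disp"]]^2),
                 tolerance = 1e-6)
  }
  ## degenerate continuity: tiny bend, helical ~ plain parameters
  std <- step_parameters(f1, cehs_compose(
    f1, c(shift = 0, slide = 0, rise = 3.32, tilt = 1e-5, roll = 1e-5,
          twist = 36))$f2)
  hpd <- helical_parameters(std)
  expect_equal(unname(hpd[["h_rise"]]), 3.32, tolerance = 1e-4)
  expect_equal(unname(hpd[["h_twist"]]), 36, tolerance = 1e-4)
  ## zero net rotation is flagged, not invented
  st0 <- step_parameters(f1, list(R = diag(3), o = c(0, 0, 3.3)))
  expect_identical(attr(helical_parameters(st0), "flag"), "no_axis")
})

test_that("Zp metrics are exact projections and flag missing phosphates", {
  f1 <- list(R = diag(3), o = c(0, 0, 0))
  st <- step_parameters(f1, cehs_compose(
    f1, c(shift = 0, slide = 0, rise = 3.32, tilt = 0, roll = 0,
          twist = 36))$f2)
  ## vector orthogonal to the mid-frame z and the helical axis -> both zero
  zm <- st$mid$R[, 3]
  perp <- c(zm[2], -zm[1], 0)
  z0 <- zp_metrics(st, c(0, 0, 0), perp)
  expect_lt(max(abs(z0)), 1e-9)
  ## constructed vector with known components
  v <- 1.7 * zm + 0.4 * st$mid$R[, 1]
  z1 <- zp_metrics(st, c(1, 2, 3), c(1, 2, 3) + v)
  expect_equal(unname(z1[["zp"]]), 1.7, tolerance = 1e-9)
  expect_equal(unname(z1[["zp_h"]]), 1.7, tolerance = 1e-9)  # axis = z here
  miss <- zp_metrics(st, NULL, c(0, 0, 0))
  expect_true(all(is.na(miss)))
  expect_identical(attr(miss, "flag"), "missing_P")
})

test_that("step quality flag marks near-antiparallel twists", {
  f1 <- list(R = diag(3), o = c(0, 0, 0))
  f2 <- cehs_compose(f1, c(shift = 0, slide = 0, rise = 3.3, tilt = 0,
                           roll = 0, twist = 178))$f2
  expect_identical(step_parameters(f1, f2)$flag, "antiparallel")
})
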