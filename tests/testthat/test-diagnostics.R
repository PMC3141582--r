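test_that("z-vorticity matches analytic curls", {
  g <- small_grid()
  m <- mesh_xy(g)
  # uniform flow
  expect_equal(max(abs(vorticity_z(list(array(2, g$n), array(-1, g$n)), g))), 0)
  # solid-body rotation about the domain center: omega = 2*Omega
  Om <- 0.7
  ctr <- g$extent / 2
  u <- list(-Om * (m$y - ctr[2]), Om * (m$x - ctr[1]))
  om <- vorticity_z(u, g)
  interior <- om[8:24, 8:24]  # away from the periodic seam
  expect_equal(interior, array(2 * Om, dim(interior)), tolerance = 1e-10)
  # simple shear u = (gamma*y, 0): omega = -gamma
  sh <- vorticity_z(list(0.4 * m$y, array(0, g$n)), g)
  expect_equal(sh[8:24, 8:24], array(-0.4, c(17, 17)), tolerance = 1e-10)
})

test_that("vorticity of a projected field integrates to zero", {
  g <- small_grid()
  pp <- fluid_params(dt = 1e-3)
  set.seed(21)
  u <- solenoidal_velocity(g, pp)
  expect_lt(abs(sum(vorticity_z(u, g)) * g$h^2), 1e-10)
})

test_that("slice kinetic energy reduces correctly in both modes", {
  g <- small_grid()
  expect_equal(kinetic_energy_slice(list(array(0, g$n), array(0, g$n)), 1, g), 0)
  uni <- list(array(1, g$n), array(0, g$n))
  expect_equal(kinetic_energy_slice(uni, 1, g, "max"), 0.5)
  expect_equal(kinetic_energy_slice(uni, 1, g, "total"), 0.5 * prod(g$extent))
  expect_equal(kinetic_energy_slice(uni, 2, g, "max"), 1)
  # floor masks sub-threshold energy
  expect_equal(kinetic_energy_slice(uni, 1, g, "total", floor = 0.6), 0)
  # a normalized series has maximum exactly one
  ke <- c(0.2, 1.4, 0.7)
  expect_equal(max(ke / max(ke)), 1)
})

test_that("chamber area uses the shoelace rule with safety checks", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  mod <- fiber_model(sq, NULL, ds = 1)
  expect_equal(chamber_volume(boundary_state(mod), 1:4), 1)
  # orientation reversal gives the same magnitude
  expect_equal(chamber_volume(boundary_state(mod), 4:1), 1)
  # polygon area converges to the circle area at O(n^-2)
  areas <- vapply(c(16, 32, 64), function(n) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    modc <- fiber_model(cbind(cos(th), sin(th)), NULL, ds = 1)
    chamber_volume(boundary_state(modc), seq_len(n))
  }, 0)
  errs <- pi - areas
  expect_true(all(errs > 0))
  expect_equal(errs[1] / errs[2], 4, tolerance = 0.1)
  expect_equal(errs[2] / errs[3], 4, tolerance = 0.1)
  # bow-tie raises
  bow <- fiber_model(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)), NULL, ds = 1)
  expect_error(chamber_volume(boundary_state(bow), 1:4), "self-intersecting")
})

test_that("flow-rate non-dimensionalization scales by stroke volume and period", {
  expect_equal(nondimensionalize_flow(5 / 0.8, T = 0.8, stroke_volume = 5), 1)
  expect_equal(nondimensionalize_flow(0, 0.8, 5), 0)
  q <- c(-3, 0, 7)
  expect_equal(sign(nondimensionalize_flow(q, 0.8, 5)), sign(q))
  expect_error(nondimensionalize_flow(1, 0.8, 0), "stroke volume")
})

test_that("vortex-core counting resolves sign, size and threshold structure", {
  g <- small_grid()
  m <- mesh_xy(g)
  expect_equal(unname(count_vortex_cores(array(0, g$n))), c(0L, 0L))
  # solid-body rotation: one positive core (masked to the rotation core;
  # on a periodic domain the seam carries compensating shear)
  Om <- 1
  ctr <- g$extent / 2
  om_sb <- vorticity_z(list(-Om * (m$y - ctr[2]), Om * (m$x - ctr[1])), g)
  core_mask <- (m$x - ctr[1])^2 + (m$y - ctr[2])^2 < 1
  cc <- count_vortex_cores(om_sb, threshold_frac = 0.5, mask = core_mask)
  expect_equal(unname(cc), c(1L, 0L))
  # ideal dipole: two opposite Gaussian vortices
  gauss <- function(cx, cy, s) exp(-((m$x - cx)^2 + (m$y - cy)^2) / (2 * s^2))
  om_di <- gauss(1.1, 1.6, 0.2) - gauss(2.1, 1.6, 0.2)
  expect_equal(unname(count_vortex_cores(om_di, 0.2)), c(1L, 1L))
  # a core smaller than min_cells is discarded
  om_small <- array(0, g$n)
  om_small[5, 5] <- 1
  om_small[20:23, 20:23] <- -1
  expect_equal(unname(count_vortex_cores(om_small, 0.2, min_cells = 4L)), c(0L, 1L))
  # periodic wrapping joins a core split across the seam
  om_seam <- gauss(0.05, 1.6, 0.25) + gauss(g$extent[1] - 0.05, 1.6, 0.25)
  expect_equal(unname(count_vortex_cores(om_seam, 0.2)), c(1L, 0L))
})

test_that("kinetic-energy peak detection finds separated maxima in time order", {
  t <- seq(0, 1, length.out = 400)
  # single sine period peaks at its analytic maximum
  p1 <- detect_ke_peaks(sin(2 * pi * t), t)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$t, 0.25, tolerance = 0.01)
  # three separated Gaussians, with the E > A height ordering preserved
  ke <- 1.0 * exp(-(t - 0.13)^2 / 5e-4) + 0.6 * exp(-(t - 0.44)^2 / 5e-4) +
        0.9 * exp(-(t - 0.83)^2 / 5e-4)
  pk <- detect_ke_peaks(ke, t)
  expect_equal(nrow(pk), 3)
  expect_equal(pk$t, c(0.13, 0.44, 0.83), tolerance = 0.01)
  expect_gt(pk$ke[1], pk$ke[2])
  # flat series yields nothing
  expect_equal(nrow(detect_ke_peaks(rep(2, 100), seq_len(100))), 0)
  # sub-prominence ripples are ignored
  ripple <- sin(2 * pi * t) + 0.02 * sin(40 * pi * t)
  expect_equal(nrow(detect_ke_peaks(ripple, t, prominence_frac = 0.1)), 1)
})

test_that("peak detection agrees with an independent detector on a clean series", {
  skip_if_not_installed("pracma")
  t <- seq(0, 1, length.out = 500)
  ke <- exp(-(t - 0.2)^2 / 1e-3) + 0.5 * exp(-(t - 0.7)^2 / 1e-3)
  ours <- detect_ke_peaks(ke, t)
  theirs <- pracma::findpeaks(ke, minpeakheight = 0.1)
  expect_equal(nrow(ours), nrow(theirs))
  expect_equal(sort(t[theirs[, 2]]), ours$t, tolerance = 1e-8)
})
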