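test_that("activation schedules validate their phase structure", {
  sch <- activation_schedule()
  expect_equal(sch$T, 0.8)
  expect_equal(sch$diastole_span, c(0, 0.75))
  expect_equal(sch$systole_span, c(0.75, 1))
  expect_error(activation_schedule(diastole_span = c(0, 0.9),
                                   systole_span = c(0.75, 1)), "overlap")
  expect_error(activation_schedule(e_wave_span = c(0.3, 0.1)), "ordered")
})

test_that("activation multipliers are baseline in mid-diastole and peak as configured", {
  sch <- activation_schedule()
  expect_equal(activation_value(sch, 0.4, "ventricle"), c(k = 1, L0 = 1))
  expect_equal(activation_value(sch, 0.4, "unknown_group"), c(k = 1, L0 = 1))
  # mid-systole: full contraction multipliers from the schedule
  mid_sys <- 0.9
  av <- activation_value(sch, mid_sys, "ventricle")
  expect_equal(unname(av["k"]), sch$groups$ventricle$k)
  expect_equal(unname(av["L0"]), sch$groups$ventricle$L0)
  # atrial kick peaks at the A-wave center
  aa <- activation_value(sch, sch$a_wave_center, "atrium")
  expect_equal(unname(aa["k"]), sch$groups$atrium$k)
  # periodic in t_norm
  expect_equal(activation_value(sch, 0.98, "ventricle"),
               activation_value(sch, 1.98, "ventricle"))
})

test_that("activation shapes are C1 and integrate to their closed forms", {
  sch <- activation_schedule()
  tt <- seq(0, 1, length.out = 20001)
  for (grp in c("ventricle", "atrium")) {
    m <- vapply(tt, function(t) unname(activation_value(sch, t, grp)["k"]), 0)
    # continuity and bounded slope change (C1 up to quadrature resolution)
    d1 <- diff(m) / diff(tt)[1]
    expect_lt(max(abs(diff(d1))) * 1, max(abs(d1)) * 0.05 + 1e-9)
  }
  # quadrature of the raw shape vs closed form: cosine ramps contribute
  # half their span, the plateau contributes its full length
  m_v <- vapply(tt, function(t) {
    (unname(activation_value(sch, t, "ventricle")["k"]) - 1) /
      (sch$groups$ventricle$k - 1)
  }, 0)
  plateau <- (1 - (sch$systole_span[1] + sch$sys_ramp)) + sch$release_span[1]
  closed <- sch$sys_ramp / 2 + plateau + diff(sch$release_span) / 2
  expect_equal(mean(m_v), closed, tolerance = 1e-3)
  m_a <- vapply(tt, function(t) {
    (unname(activation_value(sch, t, "atrium")["k"]) - 1) / (sch$groups$atrium$k - 1)
  }, 0)
  expect_equal(mean(m_a), sch$a_wave_width, tolerance = 1e-4)
})

test_that("ellipse membranes satisfy the anti-leakage spacing rule", {
  g <- grid_spec(64, 6.4)
  fix <- make_ellipse_membrane(1.4, 0.9, g)
  X <- fix$model$points
  n <- nrow(X)
  seg <- sqrt(rowSums((X[c(2:n, 1), ] - X)^2))
  expect_lt(max(seg), g$h / 2 + 1e-12)
  expect_warning(make_ellipse_membrane(1.4, 0.9, g, n_points = 40), "under-resolved")
  expect_error(make_ellipse_membrane(4, 1, g), "fit")
  # circle at rest length is an equilibrium input (up to the arclength
  # resampling residual, tiny relative to the working tension scale)
  circ <- make_ellipse_membrane(1.0, 1.0, g)
  Fd <- fiber_force(circ$bstate, circ$model)
  expect_lt(max(abs(Fd)), 1e-6 * 1e4)  # strain residual below 1e-6
})

test_that("fixtures are deterministic functions of their configuration", {
  g <- grid_spec(64, 6.4)
  a <- make_ventricle_2d(g)
  b <- make_ventricle_2d(g)
  expect_identical(a$model$points, b$model$points)
  expect_identical(a$model$springs, b$model$springs)
  c1 <- make_cylinder_ring(c(2.2, 3.2), 0.6, grid_spec(c(128, 64), c(12.8, 6.4)))
  c2 <- make_cylinder_ring(c(2.2, 3.2), 0.6, grid_spec(c(128, 64), c(12.8, 6.4)))
  expect_identical(c1$model$points, c2$model$points)
})

test_that("cylinder ring enforces its resolution precondition and is tethered", {
  g <- grid_spec(64, 6.4)
  expect_error(make_cylinder_ring(c(3.2, 3.2), 0.3, g), "at least 4h")
  fix <- make_cylinder_ring(c(3.2, 3.2), 0.6, g)
  expect_equal(nrow(fix$model$tethers), nrow(fix$model$points))
  # tethered at rest in still fluid: no force, no drag
  expect_lt(max(abs(fiber_force(fix$bstate, fix$model))), 1e-9)
})

test_that("the two-chamber ventricle fixture is well-formed", {
  g <- grid_spec(64, 6.4)
  expect_error(make_ventricle_2d(grid_spec(32, 3.2)), "48")
  fix <- make_ventricle_2d(g)
  # anti-leakage spacing along every spring
  sp <- fix$model$springs
  wall <- sp[sp$group %in% c("atrium", "ventricle", "conduit"), ]
  expect_lt(max(wall$L0), g$h / 2 + 1e-12)
  # ports clear of walls
  for (p in fix$ports) {
    d <- sqrt(min(rowSums(sweep(fix$model$points, 2, p$center)^2)))
    expect_gt(d, p$radius)
  }
  # chamber loops are valid polygons
  expect_gt(chamber_volume(fix$bstate, fix$chambers$ventricle), 3)
  expect_gt(chamber_volume(fix$bstate, fix$chambers$atrium), 2)
  # reservoirs at the reference pressures
  expect_equal(fix$ports[[1]]$pressure_mmhg, 15)
  expect_equal(fix$ports[[2]]$pressure_mmhg, 80)
  # the same physical geometry emerges on a finer grid
  fix2 <- make_ventricle_2d(grid_spec(128, 6.4))
  expect_gt(nrow(fix2$model$points), nrow(fix$model$points))
  expect_equal(chamber_volume(fix2$bstate, fix2$chambers$ventricle),
               chamber_volume(fix$bstate, fix$chambers$ventricle), tolerance = 0.02)
})

test_that("the 3-D ellipsoid shell exercises the 3-D path", {
  g <- grid_spec(16, 1.6, ndim = 3)
  fix <- make_ellipsoid_shell(c(0.4, 0.4, 0.5), g, stiffness = 100)
  pp <- fluid_params(dt = 1e-3)
  st <- fluid_state(g)
  bs <- fix$bstate
  for (i in 1:5) {
    r <- step_fsi(st, bs, fix$model, NULL, pp, g)
    st <- r$state; bs <- r$bstate
  }
  expect_true(all(is.finite(bs$X)))
  expect_true(all(vapply(st$u, function(a) all(is.finite(a)), TRUE)))
  # 3-D spreading conserves total force too
  bs$F <- matrix(rnorm(3 * nrow(bs$X)), ncol = 3)
  f <- spread_force(bs, fix$model, g)
  for (d in 1:3) {
    expect_equal(sum(f[[d]]) * g$h^3, sum(bs$F[, d] * fix$model$ds), tolerance = 1e-12)
  }
})
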