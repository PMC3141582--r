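test_that("grid construction validates its invariants", {
  g <- grid_spec(64, 6.4)
  expect_equal(g$h, 0.1)
  expect_equal(g$coords[[1]][1], 0.05)
  expect_error(grid_spec(48, 4.8), "power of two")
  expect_error(grid_spec(4, 1), "at least 8")
  expect_error(grid_spec(c(32, 64), c(3.2, 3.2)), "meshwidth")
  g2 <- grid_spec(c(64, 32), c(6.4, 3.2))
  expect_equal(g2$h, 0.1)
})

test_that("predictor fixes the null state and uniform translation", {
  g <- small_grid()
  pp <- fluid_params(dt = 1e-3)
  st <- fluid_state(g)
  u <- advect_diffuse_predictor(st, NULL, pp, g, pp$dt)
  expect_equal(max(abs(u[[1]])), 0)
  # a spatially uniform field is untouched by advection and diffusion
  st2 <- fluid_state(g, u = list(array(1.7, g$n), array(-0.4, g$n)))
  u2 <- advect_diffuse_predictor(st2, NULL, pp, g, pp$dt)
  expect_equal(u2[[1]], array(1.7, g$n), tolerance = 1e-13)
  expect_equal(u2[[2]], array(-0.4, g$n), tolerance = 1e-13)
})

test_that("predictor refuses a CFL-violating step", {
  g <- small_grid()
  pp <- fluid_params(dt = 0.2)
  st <- fluid_state(g, u = list(array(1, g$n), array(0, g$n)))
  expect_error(advect_diffuse_predictor(st, NULL, pp, g, pp$dt), "Courant number")
})

test_that("pressure solve recovers a constructed mode and fixes the gauge", {
  g <- small_grid()
  pp <- fluid_params(dt = 1e-3)
  m <- mesh_xy(g)
  p_true <- cos(2 * pi * m$x / g$extent[1]) * sin(2 * pi * 2 * m$y / g$extent[2])
  p_true <- p_true - mean(p_true)
  # provisional = (dt/rho) * grad(p_true): solver must invert to p_true
  gr <- gradient(p_true, g)
  prov <- lapply(gr, function(a) (pp$dt / pp$rho) * a)
  p <- solve_pressure_poisson(NULL, prov, pp, g, pp$dt)
  expect_equal(p, p_true, tolerance = 1e-10)
  # already divergence-free input gives p = 0
  set.seed(4)
  u0 <- solenoidal_velocity(g, pp)
  p0 <- solve_pressure_poisson(NULL, u0, pp, g, pp$dt)
  expect_lt(max(abs(p0)), 1e-9 * max(abs(unlist(u0))) * pp$rho / pp$dt)
})

test_that("pressure solve raises on an unbalanced source field", {
  g <- small_grid()
  pp <- fluid_params(dt = 1e-3)
  set.seed(5)
  u <- rand_velocity(g)
  q <- array(1e-3, g$n)  # nonzero mean divergence target
  expect_error(solve_pressure_poisson(q, u, pp, g, pp$dt), "nonzero mean")
})

test_that("projection is exact, gauge-invariant and idempotent", {
  g <- small_grid()
  pp <- fluid_params(dt = 1e-3)
  set.seed(6)
  u <- rand_velocity(g)
  expect_identical(project(u, array(0, g$n), pp, g, pp$dt), u)
  pc <- project(u, array(3.14, g$n), pp, g, pp$dt)
  expect_equal(pc, u, tolerance = 1e-14)
  for (rep in 1:5) {
    u <- rand_velocity(g)
    pr <- ibcms:::project_velocity(u, NULL, pp, g, pp$dt)
    dv <- divergence(pr$u, g)
    uscale <- max(abs(unlist(pr$u))) / g$h
    expect_lt(max(abs(dv)), 1e-10 * uscale)
    pr2 <- ibcms:::project_velocity(pr$u, NULL, pp, g, pp$dt)
    expect_lt(max(abs(pr2$u[[1]] - pr$u[[1]])), 1e-12 * max(abs(pr$u[[1]])))
  }
})

test_that("projection drives divergence to a prescribed source field", {
  g <- small_grid()
  pp <- fluid_params(dt = 1e-3)
  ports <- ibcms:::prepare_ports(list(
    reservoir_port("IN", c(0.8, 0.8), 0.3, 10, 1),
    reservoir_port("OUT", c(2.4, 2.4), 0.3, -10, 1)), g)
  q <- build_source_field(ports, c(2, -2), g)$q
  expect_lt(abs(sum(q)) * g$h^2, 1e-12)
  set.seed(7)
  u <- rand_velocity(g)
  p <- solve_pressure_poisson(q, u, pp, g, pp$dt)
  un <- project(u, p, pp, g, pp$dt)
  expect_equal(divergence(un, g), q, tolerance = 1e-9)
  # discrete Gauss: net flux balance means domain integral of div is 0
  expect_lt(abs(sum(divergence(un, g))) * g$h^2, 1e-10)
})

test_that("Taylor-Green vortex decays at 2*nu*k^2 with second-order dt error", {
  nu <- 0.5
  r1 <- tg_decay_rate(nu, dt = 0.02, n_steps = 60)
  expect_lt(abs(r1 - 2 * nu) / (2 * nu), 0.01)
  # halving dt reduces the decay-rate error about fourfold
  r2 <- tg_decay_rate(nu, dt = 0.01, n_steps = 120)
  e1 <- abs(r1 - 2 * nu)
  e2 <- abs(r2 - 2 * nu)
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5.5)
})

test_that("domain-mean momentum is conserved without forces or sources", {
  g <- small_grid()
  pp <- fluid_params(nu = 0.02, dt = 2e-3)
  set.seed(8)
  st <- fluid_state(g, u = solenoidal_velocity(g, pp, sd = 0.3))
  mom0 <- vapply(st$u, mean, 0)
  for (i in 1:30) {
    us <- advect_diffuse_predictor(st, NULL, pp, g, pp$dt)
    pr <- ibcms:::project_velocity(us, NULL, pp, g, pp$dt)
    st <- fluid_state(g, u = pr$u, p = pr$p, t = st$t + pp$dt)
  }
  expect_equal(vapply(st$u, mean, 0), mom0, tolerance = 1e-12)
})

test_that("the fused spectral stage matches the composed reference operators", {
  g <- small_grid()
  pp <- fluid_params(nu = 0.05, dt = 1e-3)
  set.seed(9)
  st <- fluid_state(g, u = solenoidal_velocity(g, pp, sd = 0.5))
  f <- rand_velocity(g)
  ports <- ibcms:::prepare_ports(list(
    reservoir_port("A", c(0.8, 0.8), 0.3, 20, 1),
    reservoir_port("B", c(2.4, 2.4), 0.3, -10, 2)), g)
  us <- advect_diffuse_predictor(st, f, pp, g, pp$dt)
  ref <- ibcms:::project_with_ports(us, ports, pp, g, pp$dt)
  zb <- ibcms:::fftn(st$u[[1]] + 1i * st$u[[2]])
  fu <- ibcms:::fluid_stage_2d(zb, st$u, st$u, f, ports, pp, g, pp$dt, want_p = TRUE)
  expect_equal(fu$u, ref$u, tolerance = 1e-12)
  expect_equal(fu$p, ref$p, tolerance = 1e-9)
  expect_equal(fu$Q, ref$Q, tolerance = 1e-12)
})
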