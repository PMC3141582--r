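test_that("the four-point kernel has the right values, support and moments", {
  expect_equal(delta_weight(0), 0.5)
  expect_equal(delta_weight(c(1, -1)), c(0.25, 0.25))
  expect_equal(delta_weight(c(2, -2, 3.7)), c(0, 0, 0))
  expect_true(all(delta_weight(seq(-3, 3, 0.01)) >= 0))
  # partition of unity and zero first moment, swept over the unit cell
  for (r in seq(-0.5, 0.5, length.out = 101)) {
    offs <- r - (-3:3)
    w <- delta_weight(offs)
    expect_equal(sum(w), 1, tolerance = 1e-14)
    expect_equal(sum(offs * w), 0, tolerance = 1e-14)
  }
})

test_that("force spreading conserves total force and localizes on the stencil", {
  g <- small_grid()
  set.seed(11)
  M <- 23
  mod <- fiber_model(cbind(runif(M, 0, 3.2), runif(M, 0, 3.2)), NULL,
                     ds = runif(M, 0.5, 1.5))
  bs <- boundary_state(mod)
  f0 <- spread_force(bs, mod, g)  # F = 0
  expect_equal(max(abs(f0[[1]])), 0)
  bs$F <- matrix(rnorm(2 * M), M, 2)
  f <- spread_force(bs, mod, g)
  for (d in 1:2) {
    expect_equal(sum(f[[d]]) * g$h^2, sum(bs$F[, d] * mod$ds), tolerance = 1e-12)
  }
  # point exactly on a node: center weight 0.5^2, support within the
  # 4x4 stencil (the on-node edge weight phi(2) vanishes, leaving 3x3)
  mod1 <- fiber_model(matrix(g$h * c(10.5, 10.5), 1, 2), NULL, ds = 1)
  bs1 <- boundary_state(mod1)
  bs1$F <- matrix(c(1, 0), 1, 2)
  f1 <- spread_force(bs1, mod1, g)
  expect_equal(f1[[1]][11, 11] * g$h^2, 0.25)
  expect_equal(f1[[1]][10, 11] * g$h^2, 0.25 * 0.5)
  expect_equal(sum(f1[[1]] != 0), 9)
  nz <- which(f1[[1]] != 0, arr.ind = TRUE)
  expect_true(all(abs(nz[, 1] - 11) <= 2) && all(abs(nz[, 2] - 11) <= 2))
})

test_that("velocity interpolation reproduces uniform and linear fields", {
  g <- small_grid()
  set.seed(12)
  M <- 17
  mod <- fiber_model(cbind(runif(M, 0, 3.2), runif(M, 0, 3.2)), NULL, ds = 1)
  bs <- boundary_state(mod)
  uni <- list(array(2.5, g$n), array(-1.2, g$n))
  U <- interpolate_velocity(uni, bs, g)
  expect_equal(U[, 1], rep(2.5, M), tolerance = 1e-14)
  expect_equal(U[, 2], rep(-1.2, M), tolerance = 1e-14)
  # linear field, points away from the periodic seam
  m <- mesh_xy(g)
  lin <- list(0.3 + 0.7 * m$x - 0.2 * m$y, 1.1 * m$y)
  mod2 <- fiber_model(cbind(runif(M, 0.5, 2.7), runif(M, 0.5, 2.7)), NULL, ds = 1)
  bs2 <- boundary_state(mod2)
  U2 <- interpolate_velocity(lin, bs2, g)
  expect_equal(U2[, 1], 0.3 + 0.7 * mod2$points[, 1] - 0.2 * mod2$points[, 2],
               tolerance = 1e-12)
  expect_equal(U2[, 2], 1.1 * mod2$points[, 2], tolerance = 1e-12)
})

test_that("spreading and interpolation are adjoint", {
  g <- small_grid()
  set.seed(13)
  for (rep in 1:5) {
    M <- sample(5:40, 1)
    mod <- fiber_model(cbind(runif(M, 0, 3.2), runif(M, 0, 3.2)), NULL,
                       ds = runif(M, 0.2, 2))
    bs <- boundary_state(mod)
    bs$F <- matrix(rnorm(2 * M), M, 2)
    u <- rand_velocity(g)
    f <- spread_force(bs, mod, g)
    U <- interpolate_velocity(u, bs, g)
    lhs <- sum(bs$F * U * mod$ds)
    rhs <- sum(f[[1]] * u[[1]] + f[[2]] * u[[2]]) * g$h^2
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("fiber forces follow the Hooke law with defined degenerate limits", {
  # two points joined by one spring: equal and opposite along the connector
  X <- rbind(c(1, 1), c(1 + 0.8, 1))
  mod <- fiber_model(X, data.frame(i = 1, j = 2, k = 50, L0 = 0.5), ds = 1)
  bs <- boundary_state(mod)
  Fd <- fiber_force(bs, mod)
  expect_equal(Fd[1, ], c(50 * 0.3, 0))
  expect_equal(Fd[2, ], c(-50 * 0.3, 0))
  # at rest length the network is in equilibrium
  mod0 <- fiber_model(X, data.frame(i = 1, j = 2, k = 50, L0 = 0.8), ds = 1)
  expect_equal(max(abs(fiber_force(boundary_state(mod0), mod0))), 0)
  # coincident endpoints: zero contribution, flagged
  modc <- fiber_model(rbind(c(1, 1), c(1, 1) + 1e-300),
                      data.frame(i = 1, j = 2, k = 50, L0 = 0.5), ds = 1)
  bsc <- boundary_state(modc)
  bsc$X[2, ] <- bsc$X[1, ]
  expect_warning(Fc <- fiber_force(bsc, modc), "coincident")
  expect_equal(max(abs(Fc)), 0)
  # tension-only springs carry no compression
  modt <- fiber_model(X, data.frame(i = 1, j = 2, k = 50, L0 = 2,
                                    tension_only = TRUE), ds = 1)
  expect_equal(max(abs(fiber_force(boundary_state(modt), modt))), 0)
})

test_that("a uniformly stretched ring pulls radially inward with zero net force", {
  g <- small_grid()
  n <- 40
  th <- 2 * pi * (seq_len(n) - 1) / n
  r0 <- 0.9
  X <- cbind(1.6 + r0 * cos(th), 1.6 + r0 * sin(th))
  chord <- 2 * r0 * sin(pi / n)
  mod <- fiber_model(X, data.frame(i = seq_len(n), j = c(2:n, 1), k = 100,
                                   L0 = 0.8 * chord), ds = 1)
  Fd <- fiber_force(boundary_state(mod), mod)
  expect_equal(colSums(Fd), c(0, 0), tolerance = 1e-12)
  radial <- rowSums(Fd * cbind(cos(th), sin(th)))
  expect_true(all(radial < 0))
  tangential <- rowSums(Fd * cbind(-sin(th), cos(th)))
  expect_lt(max(abs(tangential)), 1e-12 * max(abs(radial)))
})

test_that("a membrane at rest is an equilibrium of the FSI step", {
  g <- grid_spec(32, 3.2)
  pp <- fluid_params(dt = 5e-4)
  # exact equilibrium: regular polygon with rest lengths at the chords
  n <- 64
  th <- 2 * pi * (seq_len(n) - 1) / n
  X <- cbind(1.6 + 0.8 * cos(th), 1.6 + 0.8 * sin(th))
  chord <- sqrt(sum((X[2, ] - X[1, ])^2))
  mod <- fiber_model(X, data.frame(i = seq_len(n), j = c(2:n, 1), k = 1e3,
                                   L0 = chord), ds = 2 * pi * 0.8 / n)
  st <- fluid_state(g)
  bs <- boundary_state(mod)
  for (i in 1:100) {
    r <- step_fsi(st, bs, mod, NULL, pp, g)
    st <- r$state; bs <- r$bstate
  }
  expect_lt(max(abs(st$u[[1]])), 1e-11)
  expect_lt(max(abs(bs$X - X)), 1e-11)
})

test_that("the FSI step is bitwise deterministic", {
  g <- grid_spec(32, 3.2)
  pp <- fluid_params(dt = 5e-4)
  run_once <- function() {
    fix <- make_ellipse_membrane(1.0, 0.6, g, stiffness = 2e3)
    st <- fluid_state(g)
    bs <- fix$bstate
    for (i in 1:50) {
      r <- step_fsi(st, bs, fix$model, NULL, pp, g)
      st <- r$state; bs <- r$bstate
    }
    list(u = st$u, X = bs$X)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$u, b$u)
  expect_identical(a$X, b$X)
})

test_that("fluid plus elastic energy decays for a free elastic ring", {
  g <- grid_spec(32, 3.2)
  pp <- fluid_params(nu = 0.05, dt = 5e-4)
  fix <- make_ellipse_membrane(1.0, 0.6, g, stiffness = 2e3)
  st <- fluid_state(g)
  bs <- fix$bstate
  energy <- function(st, bs) {
    ke <- 0.5 * pp$rho * sum(st$u[[1]]^2 + st$u[[2]]^2) * g$h^2
    ke + fiber_energy(bs, fix$model)
  }
  e_prev <- energy(st, bs)
  for (i in 1:300) {
    r <- step_fsi(st, bs, fix$model, NULL, pp, g)
    st <- r$state; bs <- r$bstate
    e <- energy(st, bs)
    expect_lt(e, e_prev + 1e-6 * max(e_prev, 1))
    e_prev <- e
  }
  # and it must actually have dissipated something
  expect_lt(e_prev, energy(fluid_state(g), fix$bstate))
})
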