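# shared builders for the test suite (all fixtures generated in code)

small_grid <- function(n = 32, extent = 3.2) grid_spec(n, extent)

rand_field <- function(grid, sd = 1) {
  array(stats::rnorm(prod(grid$n), sd = sd), dim = grid$n)
}

rand_velocity <- function(grid, sd = 1) {
  replicate(grid$ndim, rand_field(grid, sd), simplify = FALSE)
}

# divergence-free random velocity (projected)
solenoidal_velocity <- function(grid, params, sd = 1) {
  u <- rand_velocity(grid, sd)
  ibcms:::project_velocity(u, NULL, params, grid, params$dt)$u
}

mesh_xy <- function(grid) {
  X <- outer(grid$coords[[1]], rep(1, grid$n[2]))
  list(x = X, y = t(outer(grid$coords[[2]], rep(1, grid$n[1]))))
}

taylor_green_state <- function(grid) {
  m <- mesh_xy(grid)
  fluid_state(grid, u = list(sin(m$x) * cos(m$y), -cos(m$x) * sin(m$y)))
}

# observed Taylor-Green decay rate over n steps
tg_decay_rate <- function(nu, dt, n_steps, n_cells = 32) {
  g <- grid_spec(n_cells, 2 * pi)
  pp <- fluid_params(rho = 1, nu = nu, dt = dt)
  st <- taylor_green_state(g)
  amp0 <- max(abs(st$u[[1]]))
  for (i in seq_len(n_steps)) {
    us <- advect_diffuse_predictor(st, NULL, pp, g, dt)
    pr <- ibcms:::project_velocity(us, NULL, pp, g, dt)
    st <- fluid_state(g, u = pr$u, p = pr$p, t = st$t + dt)
  }
  -log(max(abs(st$u[[1]])) / amp0) / st$t
}
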