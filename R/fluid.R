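#' Advection--diffusion predictor step
#'
#' Advances the momentum equation without the pressure gradient over a
#' span `dt_frac`, producing the provisional velocity `u*` of the
#' fractional-step method. Advection is explicit, centered and in
#' skew-symmetric form (the mean of advective and divergence forms,
#' which conserves discrete kinetic energy); the viscous term is
#' time-centered (Crank--Nicolson) and solved exactly in spectral space,
#' so diffusion is unconditionally stable. The body force enters as
#' `f / rho`.
#'
#' For the time-centered full step of the FSI cycle the advecting
#' velocity may differ from the base state being advanced: pass the
#' midpoint field as `adv`.
#'
#' @param state an [fluid_state()]; its `u` is the base field advanced.
#' @param force list of body-force component arrays, dyn/cm^3 (or NULL).
#' @param params an [fluid_params()].
#' @param grid an [grid_spec()].
#' @param dt_frac time span, s (the half or the full step).
#' @param adv optional list of component arrays used to evaluate the
#'   advection term (defaults to `state$u`).
#' @return list of provisional velocity component arrays.
#' @export
advect_diffuse_predictor <- function(state, force, params, grid, dt_frac,
                                     adv = NULL) {
  u <- state$u
  if (is.null(adv)) adv <- u
  co <- courant_number(adv, grid, dt_frac)
  if (co > params$cfl_limit) {
    stop(sprintf("CFL violation: Courant number %.3f exceeds limit %.3f", co, params$cfl_limit))
  }
  nd <- grid$ndim
  h <- grid$h
  visc <- params$nu * dt_frac / 2
  # cache the Crank-Nicolson spectral factors per dt_frac
  key <- paste0("cn_", format(visc, digits = 17))
  cn <- grid$cache[[key]]
  if (is.null(cn)) {
    cn <- list(num = visc * grid$lap_spec, den = 1 / (1 - visc * grid$lap_spec))
    grid$cache[[key]] <- cn
  }
  rhs <- vector("list", nd)
  for (d in seq_len(nd)) {
    # skew-symmetric advection: 0.5 * (u.grad u_d + div(u u_d)), centered
    advec <- 0
    for (j in seq_len(nd)) {
      advec <- advec + 0.5 * (adv[[j]] * cdiff(adv[[d]], j, h) +
                              cdiff(adv[[j]] * adv[[d]], j, h))
    }
    rhs[[d]] <- u[[d]] + dt_frac * (-advec)
    if (!is.null(force)) rhs[[d]] <- rhs[[d]] + dt_frac * force[[d]] / params$rho
  }
  out <- vector("list", nd)
  if (nd == 2L) {
    # the spectral factors are real, so two real solves share one
    # complex transform
    zhat <- fftn(rhs[[1]] + 1i * rhs[[2]]) + cn$num * fftn(u[[1]] + 1i * u[[2]])
    z <- stats::fft(zhat * cn$den, inverse = TRUE) / length(zhat)
    out[[1]] <- Re(z)
    out[[2]] <- Im(z)
  } else {
    for (d in seq_len(nd)) {
      rhat <- fftn(rhs[[d]]) + cn$num * fftn(u[[d]])
      out[[d]] <- ifftn(rhat * cn$den)
    }
  }
  out
}

#' Courant number of a velocity field
#'
#' @param u list of velocity component arrays, cm/s.
#' @param grid an [grid_spec()].
#' @param dt time span, s.
#' @return max over axes of `max|u_d| * dt / h`.
#' @export
courant_number <- function(u, grid, dt) {
  max(vapply(u, function(a) max(abs(a)), 0)) * dt / grid$h
}

#' Pressure Poisson solve
#'
#' Solves the discrete Poisson equation whose solution, used in
#' [project()], drives the discrete divergence of the provisional field
#' to `div_target`. The Laplacian symbol is the one obtained by composing
#' the centered discrete divergence with the centered discrete gradient,
#' so the projection is exact in the discrete sense on the periodic
#' domain. The pressure gauge is fixed by a zero spatial mean.
#'
#' Modes on which the composed symbol vanishes (the constant mode and the
#' per-axis Nyquist combinations) carry no discrete divergence at all; a
#' right-hand side with content there is unreachable, which for the mean
#' mode signals unbalanced sources and raises.
#'
#' @param div_target prescribed divergence field, 1/s (NULL means zero).
#' @param provisional list of provisional velocity component arrays.
#' @param params an [fluid_params()].
#' @param grid an [grid_spec()].
#' @param dt_frac the time span the projection will use, s.
#' @param tol relative tolerance on the mean of the right-hand side.
#' @return pressure array, dyn/cm^2, zero mean.
#' @export
solve_pressure_poisson <- function(div_target, provisional, params, grid,
                                   dt_frac, tol = 1e-10) {
  div_u <- divergence(provisional, grid)
  rhs <- if (is.null(div_target)) div_u else div_u - div_target
  # scale against the velocity field, not the (possibly tiny) residual
  scale <- max(vapply(provisional, function(a) max(abs(a)), 0)) / grid$h
  if (!is.null(div_target)) scale <- max(scale, max(abs(div_target)))
  if (scale > 0 && abs(mean(rhs)) > tol * scale) {
    stop(sprintf("pressure solve: right-hand side has nonzero mean %.3e (unbalanced sources?)",
                 mean(rhs)))
  }
  rhat <- (params$rho / dt_frac) * fftn(rhs)
  ifftn(rhat * grid$inv_poisson)
}

#' Pressure-correction projection
#'
#' Subtracts `(dt_frac / rho) * grad p` from the provisional velocity.
#' With `p` from [solve_pressure_poisson()] the result has discrete
#' divergence equal to the prescribed source field to solver tolerance.
#'
#' @param provisional list of provisional velocity component arrays.
#' @param p pressure array (gauge-fixed).
#' @param params an [fluid_params()].
#' @param grid an [grid_spec()].
#' @param dt_frac time span, s.
#' @return list of projected velocity component arrays.
#' @export
project <- function(provisional, p, params, grid, dt_frac) {
  g <- gradient(p, grid)
  lapply(seq_len(grid$ndim), function(d) provisional[[d]] - (dt_frac / params$rho) * g[[d]])
}

# poisson solve + projection in one call; q may be NULL (divergence-free)
project_velocity <- function(provisional, q, params, grid, dt_frac) {
  p <- solve_pressure_poisson(q, provisional, params, grid, dt_frac)
  list(u = project(provisional, p, params, grid, dt_frac), p = p)
}

# fused spectral stage (2-D fast path): momentum predictor, pressure
# solve, implicit reservoir ports and projection in one spectral pass.
# Mathematically identical to advect_diffuse_predictor +
# project_with_ports (asserted in the test suite); it exists because the
# FSI loop spends most of its time in transforms.
fluid_stage_2d <- function(zhat_base, u_base, adv, force, ports, params, grid,
                           dt_frac, want_p = FALSE) {
  visc <- params$nu * dt_frac / 2
  key <- paste0("cn_", format(visc, digits = 17))
  cn <- grid$cache[[key]]
  if (is.null(cn)) {
    cn <- list(num = visc * grid$lap_spec, den = 1 / (1 - visc * grid$lap_spec))
    grid$cache[[key]] <- cn
  }
  np <- if (is.null(ports)) 0L else length(ports)
  res <- fluid_stage_cpp(
    zhat_base, u_base[[1]], u_base[[2]], adv[[1]], adv[[2]],
    if (is.null(force)) NULL else force[[1]],
    if (is.null(force)) NULL else force[[2]],
    dt_frac, params$rho, grid$h, params$cfl_limit,
    cn$num, cn$den, grid$sym_full[[1]], grid$sym_full[[2]], grid$inv_poisson,
    if (np) lapply(ports, `[[`, "what_conj") else list(),
    if (np) lapply(ports, `[[`, "ghat") else list(),
    if (np) attr(ports, "response") else matrix(0, 0, 0),
    if (np) attr(ports, "Pres") else numeric(0),
    if (np) attr(ports, "Rres") else numeric(0),
    want_p)
  Q <- as.numeric(res$Q)
  if (np) names(Q) <- vapply(ports, `[[`, "", "name")
  list(u = res$u, Q = Q, p = res$p)
}
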