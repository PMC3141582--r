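#' Lagrangian fiber model
#'
#' A fiber model is a network of boundary points joined by linear springs
#' (a discrete realization of a generalized Hooke's law for the elastic
#' boundary), plus optional tether points anchored to fixed targets.
#' Springs carry a reference stiffness `k` (dyn/cm) and rest length `L0`
#' (cm); time-dependent activation multiplies both through an
#' [activation_schedule()], which is how contraction and relaxation of
#' chamber walls are driven. The Lagrangian weight `ds` (cm of boundary
#' per point) converts point forces to the force densities the spreading
#' operator expects.
#'
#' @param points M x ndim matrix of rest coordinates, cm.
#' @param springs data frame with columns `i`, `j` (1-based point
#'   indices), `k` (dyn/cm), `L0` (cm) and optionally `group` (character,
#'   used by the activation schedule; default `"none"`).
#' @param ds Lagrangian increment per point, cm (scalar or length M).
#' @param tethers optional data frame with columns `point`, target
#'   coordinates `tx`, `ty` (and `tz` in 3-D) and stiffness `k`.
#' @param groups optional character vector naming the fiber group of each
#'   point (bookkeeping only; activation acts on spring groups).
#' @return An object of class `ib_fiber_model`.
#' @export
fiber_model <- function(points, springs, ds, tethers = NULL, groups = NULL) {
  points <- as.matrix(points)
  M <- nrow(points)
  nd <- ncol(points)
  stopifnot(nd %in% c(2L, 3L), M >= 1L)
  if (is.null(springs)) {
    springs <- data.frame(i = integer(), j = integer(), k = numeric(), L0 = numeric(),
                          group = character())
  }
  springs <- as.data.frame(springs)
  if (is.null(springs$group)) springs$group <- rep("none", nrow(springs))
  if (is.null(springs$tension_only)) springs$tension_only <- rep(FALSE, nrow(springs))
  if (nrow(springs) > 0) {
    if (any(springs$i < 1 | springs$i > M | springs$j < 1 | springs$j > M))
      stop("spring index out of range")
    if (any(springs$i == springs$j)) stop("spring connects a point to itself")
    key <- paste(pmin(springs$i, springs$j), pmax(springs$i, springs$j))
    if (anyDuplicated(key)) stop("duplicate spring")
    if (any(springs$k < 0) || any(springs$L0 < 0)) stop("spring k and L0 must be >= 0")
  }
  ds <- rep_len(as.numeric(ds), M)
  if (!is.null(tethers)) {
    tethers <- as.data.frame(tethers)
    need <- c("point", c("tx", "ty", "tz")[seq_len(nd)], "k")
    if (!all(need %in% names(tethers))) stop("tethers need columns: ", paste(need, collapse = ", "))
    if (any(tethers$k < 0)) stop("tether stiffness must be >= 0")
    if (any(tethers$point < 1 | tethers$point > M)) stop("tether point index out of range")
  }
  structure(list(points = points, springs = springs, ds = ds,
                 tethers = tethers, groups = groups, ndim = nd),
            class = "ib_fiber_model")
}

#' @export
print.ib_fiber_model <- function(x, ...) {
  cat(sprintf("<ib_fiber_model> %d points, %d springs, %d tethers (%d-D)\n",
              nrow(x$points), nrow(x$springs),
              if (is.null(x$tethers)) 0L else nrow(x$tethers), x$ndim))
  invisible(x)
}

#' Boundary state
#'
#' Current positions and force densities of the Lagrangian boundary
#' points. Positions are stored unwrapped (periodic wrapping is applied
#' only inside the kernel evaluation) so spring lengths stay well defined
#' across the periodic seam.
#'
#' @param model an [fiber_model()].
#' @param X optional M x ndim matrix of current positions, cm (defaults
#'   to the model rest coordinates).
#' @param t time, s.
#' @return An object of class `ib_boundary_state` with fields `X`, `F`
#'   (force densities, dyn per unit ds), `t`.
#' @export
boundary_state <- function(model, X = NULL, t = 0) {
  if (is.null(X)) X <- model$points
  X <- as.matrix(X)
  stopifnot(identical(dim(X), dim(model$points)))
  if (!all(is.finite(X))) stop("non-finite boundary position")
  structure(list(X = X, F = matrix(0, nrow(X), ncol(X)), t = t),
            class = "ib_boundary_state")
}

#' @export
print.ib_boundary_state <- function(x, ...) {
  cat(sprintf("<ib_boundary_state> %d points, t = %g s\n", nrow(x$X), x$t))
  invisible(x)
}

#' Four-point regularized delta kernel
#'
#' The one-dimensional factor of the regularized delta function used for
#' both force spreading and velocity interpolation. It has support
#' `|r| < 2` (grid units), is non-negative, and satisfies the discrete
#' partition of unity `sum_j phi(r - j) = 1` and the zero first-moment
#' condition `sum_j (r - j) phi(r - j) = 0` for every real `r`, which is
#' what makes the spreading/interpolation pair conserve total force and
#' reproduce linear velocity fields exactly.
#'
#' @param r dimensionless offset(s) in grid units.
#' @return kernel value(s); `phi(0) = 0.5`, `phi(+-1) = 0.25`.
#' @export
delta_weight <- function(r) {
  phi4_cpp(as.numeric(r))
}

#' Spread boundary forces to the grid
#'
#' Realizes the delta-function integral carrying Lagrangian force
#' densities onto the Eulerian grid:
#' `f(x) = sum_m F_m delta_h(x - X_m) ds_m`, with `delta_h` the
#' tensor-product four-point kernel scaled by `h^-ndim` and periodic
#' wrapping of the stencil. Total force is conserved:
#' `sum_x f h^ndim = sum_m F_m ds_m`.
#'
#' @param bstate an [boundary_state()] with `F` populated.
#' @param model an [fiber_model()] (provides `ds`).
#' @param grid an [grid_spec()].
#' @return list of `ndim` force-density component arrays, dyn/cm^3
#'   (dyn/cm^2 in 2-D).
#' @export
spread_force <- function(bstate, model, grid) {
  if (grid$ndim == 2L) {
    f <- spread_2d(bstate$X, bstate$F, model$ds, grid$n, grid$h)
  } else {
    f <- spread_3d(bstate$X, bstate$F, model$ds, grid$n, grid$h)
  }
  f
}

#' Interpolate grid velocity to boundary points
#'
#' The adjoint of [spread_force()] with the identical kernel:
#' `U_m = sum_x u(x) delta_h(x - X_m) h^ndim`. Uniform fields are
#' reproduced exactly (partition of unity) and linear fields exactly
#' (first-moment condition).
#'
#' @param u list of velocity component arrays.
#' @param bstate an [boundary_state()].
#' @param grid an [grid_spec()].
#' @return M x ndim matrix of boundary-point velocities, cm/s.
#' @export
interpolate_velocity <- function(u, bstate, grid) {
  if (grid$ndim == 2L) {
    interp_2d(u[[1]], u[[2]], bstate$X, grid$n, grid$h)
  } else {
    interp_3d(u[[1]], u[[2]], u[[3]], bstate$X, grid$n, grid$h)
  }
}

# accumulate val (vector) into a length-M vector at positions idx
acc_at <- function(idx, val, M) {
  acc_add_cpp(as.integer(idx), val, M)
}

#' Evaluate fiber forces
#'
#' Hooke-law spring tensions plus tether restoring forces, returned as
#' force densities (point force divided by `ds`). For each spring (i, j)
#' the tension is `T = k * (|X_j - X_i| - L0)` directed along the
#' connector; stretched springs pull their endpoints together. With an
#' activation schedule, `k` and `L0` are multiplied by the group's
#' activation values at the normalized cycle time `t_norm`, which is how
#' systolic stiffening/shortening and the atrial kick enter. Coincident
#' endpoints contribute zero force (the defined limit of the direction
#' vector).
#'
#' @param bstate an [boundary_state()].
#' @param model an [fiber_model()].
#' @param t_norm normalized cycle time in `[0, 1]`.
#' @param schedule optional [activation_schedule()].
#' @return M x ndim matrix of force densities, dyn per unit ds.
#' @export
fiber_force <- function(bstate, model, t_norm = 0, schedule = NULL) {
  X <- bstate$X
  M <- nrow(X)
  nd <- ncol(X)
  Fp <- matrix(0, M, nd)
  sp <- model$springs
  if (nrow(sp) > 0) {
    k <- sp$k
    L0 <- sp$L0
    if (!is.null(schedule)) {
      for (g in unique(sp$group)) {
        sel <- sp$group == g
        av <- activation_value(schedule, t_norm, g)
        k[sel] <- k[sel] * av[["k"]]
        L0[sel] <- L0[sel] * av[["L0"]]
      }
    }
    d <- X[sp$j, , drop = FALSE] - X[sp$i, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    degen <- len == 0
    if (any(degen)) warning(sum(degen), " spring(s) with coincident endpoints; zero direction used")
    tension <- k * (len - L0)
    # tension-only elements (chordae) carry no compressive load
    slack <- sp$tension_only & tension < 0
    tension[slack] <- 0
    dir <- d / ifelse(len > 0, len, 1)
    dir[degen, ] <- 0
    ff <- dir * tension
    for (dd in seq_len(nd)) {
      Fp[, dd] <- Fp[, dd] + acc_at(sp$i, ff[, dd], M) - acc_at(sp$j, ff[, dd], M)
    }
  }
  te <- model$tethers
  if (!is.null(te) && nrow(te) > 0) {
    tgt <- as.matrix(te[, c("tx", "ty", "tz")[seq_len(nd)], drop = FALSE])
    Fp[te$point, ] <- Fp[te$point, ] + te$k * (tgt - X[te$point, , drop = FALSE])
  }
  Fp / model$ds
}

#' Cells within kernel reach of the boundary
#'
#' Marks grid cells lying inside the spreading-kernel support of any
#' boundary point (by spreading a unit marker). Diagnostics use this to
#' separate interior flow from the wall-adjacent layer, where fields mix
#' fluid and boundary dynamics.
#'
#' @param bstate an [boundary_state()].
#' @param grid an [grid_spec()] (2-D).
#' @return logical array, TRUE within two meshwidths of a fiber.
#' @export
near_boundary_mask <- function(bstate, grid) {
  stopifnot(grid$ndim == 2L)
  M <- nrow(bstate$X)
  marker <- spread_2d(bstate$X, matrix(1, M, 2), rep(1, M), grid$n, grid$h)
  marker[[1]] > 1e-12
}

#' Elastic potential energy of the fiber network
#'
#' `sum 0.5 k (len - L0)^2` over springs plus the tether terms; used by
#' the energy-budget checks (viscous dissipation makes fluid + elastic
#' energy non-increasing for a free membrane).
#'
#' @inheritParams fiber_force
#' @return energy, erg (erg/cm in 2-D).
#' @export
fiber_energy <- function(bstate, model, t_norm = 0, schedule = NULL) {
  X <- bstate$X
  nd <- ncol(X)
  e <- 0
  sp <- model$springs
  if (nrow(sp) > 0) {
    k <- sp$k
    L0 <- sp$L0
    if (!is.null(schedule)) {
      for (g in unique(sp$group)) {
        sel <- sp$group == g
        av <- activation_value(schedule, t_norm, g)
        k[sel] <- k[sel] * av[["k"]]
        L0[sel] <- L0[sel] * av[["L0"]]
      }
    }
    len <- sqrt(rowSums((X[sp$j, , drop = FALSE] - X[sp$i, , drop = FALSE])^2))
    ext <- len - L0
    ext[sp$tension_only & ext < 0] <- 0
    e <- e + sum(0.5 * k * ext^2)
  }
  te <- model$tethers
  if (!is.null(te) && nrow(te) > 0) {
    tgt <- as.matrix(te[, c("tx", "ty", "tz")[seq_len(nd)], drop = FALSE])
    e <- e + sum(0.5 * te$k * rowSums((tgt - X[te$point, , drop = FALSE])^2))
  }
  e
}
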