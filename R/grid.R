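#' Periodic Cartesian grid specification
#'
#' Defines the uniform, periodic, cell-centered Eulerian grid the fluid
#' solver works on. Nodes sit at `(i + 0.5) * h` along every axis
#' (0-based `i`), the domain wraps periodically, and the meshwidth `h`
#' must be identical along all axes (the immersed-boundary kernel assumes
#' an isotropic stencil).
#'
#' @param n integer vector of cells per axis (length 1 is recycled to
#'   `ndim`); every entry must be a power of two and at least 8.
#' @param extent physical domain width per axis in cm (recycled like `n`);
#'   `extent / n` must give the same meshwidth on every axis.
#' @param ndim number of spatial dimensions, 2 or 3.
#' @return An object of class `ib_grid` with fields `ndim`, `n`,
#'   `extent`, `h`, per-axis cell-center coordinates `coords`, and
#'   precomputed spectral symbols for the viscous and pressure solves.
#' @examples
#' g <- grid_spec(64, extent = 6.4)
#' g$h  # 0.1 cm
#' @export
grid_spec <- function(n, extent, ndim = max(length(n), length(extent), 2L)) {
  if (!ndim %in% c(2L, 3L)) stop("ndim must be 2 or 3")
  n <- as.integer(rep_len(n, ndim))
  extent <- rep_len(as.numeric(extent), ndim)
  if (any(n < 8L)) stop("need at least 8 cells per axis")
  if (any(bitwAnd(n, n - 1L) != 0L)) stop("cells per axis must be a power of two")
  if (any(extent <= 0)) stop("extent must be positive")
  h <- extent / n
  if (diff(range(h)) > 1e-12 * h[1]) {
    stop("meshwidth must be identical on every axis (got ", paste(signif(h, 6), collapse = ", "), ")")
  }
  h <- h[1]
  coords <- lapply(seq_len(ndim), function(d) (seq_len(n[d]) - 0.5) * h)

  # integer wavenumbers -> physical k = 2*pi*m/L; centered-difference
  # first-derivative symbol is sin(k h)/h (imaginary part)
  kphys <- lapply(seq_len(ndim), function(d) {
    m <- c(0:(n[d] %/% 2), -((n[d] %/% 2 - 1):1))
    2 * pi * m / extent[d]
  })
  # sinpi keeps the Nyquist symbol exactly zero
  sym1 <- lapply(seq_len(ndim), function(d) {
    m <- c(0:(n[d] %/% 2), -((n[d] %/% 2 - 1):1))
    sinpi(2 * m / n[d]) / h
  })

  expand_axis <- function(v, d) {
    # broadcast per-axis vector v (length n[d]) to a full ndim array
    perm <- seq_len(ndim)
    perm[c(1L, d)] <- perm[c(d, 1L)]
    aperm(array(v, dim = n[perm]), perm)
  }
  # exact spectral Laplacian (viscous term); composed div.grad symbol (pressure)
  lap_spec <- 0
  lap_cd2 <- 0
  for (d in seq_len(ndim)) {
    lap_spec <- lap_spec - expand_axis(kphys[[d]]^2, d)
    lap_cd2 <- lap_cd2 - expand_axis(sym1[[d]]^2, d)
  }
  inv_poisson <- ifelse(lap_cd2 == 0, 0, 1 / lap_cd2)
  sym_full <- lapply(seq_len(ndim), function(d) expand_axis(sym1[[d]], d))
  structure(list(
    sym_full = sym_full,
    ndim = ndim, n = n, extent = extent, h = h, coords = coords,
    kphys = kphys, sym1 = sym1,
    lap_spec = lap_spec, poisson_sym = lap_cd2,
    inv_poisson = inv_poisson,
    null_modes = lap_cd2 == 0,
    cache = new.env(parent = emptyenv())
  ), class = "ib_grid")
}

#' @export
print.ib_grid <- function(x, ...) {
  cat(sprintf("<ib_grid> %d-D periodic, %s cells, extent %s cm, h = %g cm\n",
              x$ndim, paste(x$n, collapse = " x "),
              paste(signif(x$extent, 6), collapse = " x "), x$h))
  invisible(x)
}

#' Fluid parameters
#'
#' Physical fluid constants and the integration time step, in CGS units.
#' Blood is modeled as a Newtonian fluid; the reference values are
#' density 1.0 g/cm^3 and kinematic viscosity 0.03125 cm^2/s.
#'
#' @param rho density, g/cm^3.
#' @param nu kinematic viscosity, cm^2/s.
#' @param dt time step, s.
#' @param cfl_limit maximum admissible Courant number before the
#'   advection predictor refuses to step (explicit advection).
#' @return An object of class `ib_fluid_params`; `mu = rho * nu` is the
#'   dynamic viscosity in poise.
#' @export
fluid_params <- function(rho = 1.0, nu = 0.03125, dt = 2.44e-5, cfl_limit = 0.9) {
  stopifnot(rho > 0, nu >= 0, dt > 0, cfl_limit > 0)
  structure(list(rho = rho, nu = nu, mu = rho * nu, dt = dt, cfl_limit = cfl_limit),
            class = "ib_fluid_params")
}

#' @export
print.ib_fluid_params <- function(x, ...) {
  cat(sprintf("<ib_fluid_params> rho = %g g/cm^3, nu = %g cm^2/s, dt = %g s\n",
              x$rho, x$nu, x$dt))
  invisible(x)
}

#' Fluid state at one time level
#'
#' Velocity components (cell-centered, cm/s) plus pressure (dyn/cm^2) and
#' the current time. A freshly constructed state is quiescent.
#'
#' @param grid an [grid_spec()] object.
#' @param u optional list of `ndim` velocity component arrays.
#' @param p optional pressure array.
#' @param t time, s.
#' @return An object of class `ib_fluid_state` with fields `u`, `p`, `t`.
#' @export
fluid_state <- function(grid, u = NULL, p = NULL, t = 0) {
  zero <- array(0, dim = grid$n)
  if (is.null(u)) u <- replicate(grid$ndim, zero, simplify = FALSE)
  if (is.null(p)) p <- zero
  stopifnot(length(u) == grid$ndim)
  for (d in seq_len(grid$ndim)) {
    if (!identical(dim(u[[d]]), grid$n)) stop("velocity component ", d, " has wrong shape")
  }
  if (!identical(dim(p), grid$n)) stop("pressure has wrong shape")
  structure(list(u = u, p = p, t = t), class = "ib_fluid_state")
}

#' @export
print.ib_fluid_state <- function(x, ...) {
  sp <- vapply(x$u, function(a) max(abs(a)), 0)
  cat(sprintf("<ib_fluid_state> t = %g s, max|u| = %g cm/s, pressure range [%g, %g]\n",
              x$t, max(sp), min(x$p), max(x$p)))
  invisible(x)
}

# circular shift of array a by +1 or -1 cells along axis d
axis_shift <- function(a, d, by) {
  n <- dim(a)
  ix <- if (by > 0) c(2:n[d], 1L) else c(n[d], 1:(n[d] - 1L))
  if (length(n) == 2L) {
    if (d == 1L) a[ix, , drop = FALSE] else a[, ix, drop = FALSE]
  } else {
    if (d == 1L) a[ix, , , drop = FALSE]
    else if (d == 2L) a[, ix, , drop = FALSE]
    else a[, , ix, drop = FALSE]
  }
}

# centered first difference along axis d
cdiff <- function(a, d, h) (axis_shift(a, d, +1) - axis_shift(a, d, -1)) / (2 * h)

#' Discrete divergence of a cell-centered vector field
#'
#' Centered second-order periodic differences; this is the divergence
#' operator the projection step drives to the prescribed source field.
#'
#' @param u list of velocity component arrays.
#' @param grid an [grid_spec()] object.
#' @return scalar array, 1/s.
#' @export
divergence <- function(u, grid) {
  out <- cdiff(u[[1]], 1L, grid$h)
  for (d in 2:grid$ndim) out <- out + cdiff(u[[d]], d, grid$h)
  out
}

#' Discrete gradient of a cell-centered scalar field
#'
#' @param p scalar array.
#' @param grid an [grid_spec()] object.
#' @return list of `ndim` component arrays.
#' @export
gradient <- function(p, grid) {
  lapply(seq_len(grid$ndim), function(d) cdiff(p, d, grid$h))
}

fftn <- function(a) {
  if (length(dim(a)) == 2L) fft2_cpp(a) else stats::fft(a)
}
ifftn <- function(a) {
  if (length(dim(a)) == 2L) Re(ifft2_cpp(a))
  else Re(stats::fft(a, inverse = TRUE)) / length(a)
}
ifftn_cx <- function(a) {
  if (length(dim(a)) == 2L) ifft2_cpp(a)
  else stats::fft(a, inverse = TRUE) / length(a)
}

# separable (1/4, 1/2, 1/4) low-pass passes: each pass adds variance
# h^2/2 per axis and removes the Nyquist (checkerboard) mode exactly
smooth_field2 <- function(a, n_pass = 1L) {
  for (i in seq_len(n_pass)) {
    a <- 0.25 * axis_shift(a, 1L, -1) + 0.5 * a + 0.25 * axis_shift(a, 1L, 1)
    a <- 0.25 * axis_shift(a, 2L, -1) + 0.5 * a + 0.25 * axis_shift(a, 2L, 1)
  }
  a
}

dilate_mask <- function(m, n = 1L) {
  for (i in seq_len(n)) {
    m <- m | axis_shift(m, 1L, 1) | axis_shift(m, 1L, -1) |
      axis_shift(m, 2L, 1) | axis_shift(m, 2L, -1)
  }
  m
}
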