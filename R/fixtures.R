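#' Cardiac activation schedule
#'
#' Phase timings within the normalized cardiac cycle and the modulation
#' depths that drive fiber stiffness `k(t)` and rest length `L0(t)` per
#' fiber group. The default convention is diastole 0--0.75 T (containing
#' the E- and A-waves) and systole 0.75--1.0 T (the S-wave), with a cycle
#' period of 0.8 s.
#'
#' Two modulation shapes are provided, both C1 piecewise-cosine and
#' periodic in the cycle:
#' * `"systolic"`: ramps up at the start of systole, holds a contracted
#'   plateau across the cycle wrap, and releases in early diastole --
#'   the release is what drives the E-wave recoil jet;
#' * `"bump"`: a single cosine pulse (the atrial kick at the A-wave
#'   center).
#'
#' @param T cycle period, s.
#' @param diastole_span,systole_span normalized phase spans.
#' @param e_wave_span normalized span of early filling (bookkeeping for
#'   diagnostics; the E-wave itself emerges from the release ramp).
#' @param a_wave_center,a_wave_width center and half-width of the atrial
#'   pulse, normalized.
#' @param sys_ramp duration of the contraction ramp at systole onset,
#'   normalized.
#' @param release_span normalized span over which the ventricle releases
#'   its contraction in early diastole.
#' @param groups named list of per-group modulation entries, each a list
#'   with `type` (`"systolic"`, `"bump"` or `"none"`), and peak
#'   multipliers `k` and `L0`.
#' @return An object of class `ib_activation_schedule`.
#' @export
activation_schedule <- function(T = 0.8,
                                diastole_span = c(0, 0.75),
                                e_wave_span = c(0, 0.25),
                                a_wave_center = 0.5,
                                a_wave_width = 0.12,
                                systole_span = c(0.75, 1),
                                sys_ramp = 0.10,
                                release_span = c(0.03, 0.10),
                                groups = list(
                                  ventricle = list(type = "systolic", k = 1.3, L0 = 0.26),
                                  atrium = list(type = "bump", k = 2.0, L0 = 0.62)
                                )) {
  stopifnot(T > 0)
  chk <- function(s) all(s >= 0 & s <= 1) && s[2] > s[1]
  if (!chk(diastole_span) || !chk(systole_span) || !chk(e_wave_span) || !chk(release_span))
    stop("phase spans must lie in [0,1] and be ordered")
  if (diastole_span[2] > systole_span[1])
    stop("diastole and systole spans must not overlap")
  if (a_wave_center < 0 || a_wave_center > 1) stop("a_wave_center must be in [0,1]")
  structure(list(T = T, diastole_span = diastole_span, e_wave_span = e_wave_span,
                 a_wave_center = a_wave_center, a_wave_width = a_wave_width,
                 systole_span = systole_span, sys_ramp = sys_ramp,
                 release_span = release_span, groups = groups),
            class = "ib_activation_schedule")
}

#' @export
print.ib_activation_schedule <- function(x, ...) {
  cat(sprintf("<ib_activation_schedule> T = %g s, diastole %g-%g, systole %g-%g, A-wave at %g\n",
              x$T, x$diastole_span[1], x$diastole_span[2],
              x$systole_span[1], x$systole_span[2], x$a_wave_center))
  invisible(x)
}

# periodic distance on the unit cycle
cycle_delta <- function(t, c) {
  d <- (t - c) %% 1
  ifelse(d > 0.5, d - 1, d)
}

# systolic plateau activation shape in [0, 1]
shape_systolic <- function(t, sys0, ramp, rel) {
  t <- t %% 1
  m <- numeric(length(t))
  up <- t >= sys0 & t < sys0 + ramp
  m[up] <- 0.5 * (1 - cos(pi * (t[up] - sys0) / ramp))
  plateau <- t >= sys0 + ramp | t < rel[1]
  m[plateau] <- 1
  down <- t >= rel[1] & t < rel[2]
  m[down] <- 0.5 * (1 + cos(pi * (t[down] - rel[1]) / (rel[2] - rel[1])))
  m
}

# single cosine bump centered at c with half-width w
shape_bump <- function(t, c, w) {
  d <- cycle_delta(t %% 1, c)
  ifelse(abs(d) < w, 0.5 * (1 + cos(pi * d / w)), 0)
}

#' Activation multipliers at a cycle time
#'
#' Smooth (C1) piecewise-cosine interpolation between the baseline
#' (1, 1) and the group's peak multipliers, periodic in the normalized
#' cycle time.
#'
#' @param schedule an [activation_schedule()].
#' @param t_norm normalized cycle time in `[0, 1]` (wrapped if outside).
#' @param group fiber group name.
#' @return named vector `c(k = ..., L0 = ...)` of multipliers.
#' @export
activation_value <- function(schedule, t_norm, group) {
  g <- schedule$groups[[group]]
  if (is.null(g) || identical(g$type, "none")) return(c(k = 1, L0 = 1))
  m <- switch(g$type,
    systolic = shape_systolic(t_norm, schedule$systole_span[1], schedule$sys_ramp,
                              schedule$release_span),
    bump = shape_bump(t_norm, schedule$a_wave_center, schedule$a_wave_width),
    stop("unknown activation type: ", g$type)
  )
  c(k = 1 + (g$k - 1) * m, L0 = 1 + (g$L0 - 1) * m)
}

# closed ring of n points with consecutive springs
ring_springs <- function(n, k, L0, group) {
  data.frame(i = seq_len(n), j = c(2:n, 1L), k = k, L0 = L0, group = group)
}

#' Elastic ellipse membrane fixture
#'
#' A closed ring of springs along an ellipse, with no tethers: the
#' canonical verification geometry for the immersed-boundary coupling.
#' With `a != b` the membrane relaxes toward a circle while the enclosed
#' (incompressible) fluid area is conserved; at `a == b` with segments at
#' rest length it is an equilibrium input for [step_fsi()]. The default
#' rest length is the chord of the equal-area circle, so an eccentric
#' ellipse starts under tension.
#'
#' @param a,b semi-axes, cm (must fit in the domain).
#' @param grid an [grid_spec()] (2-D).
#' @param stiffness spring stiffness, dyn/cm.
#' @param n_points number of boundary points; default places two points
#'   per meshwidth of circumference (the anti-leakage rule).
#' @param center ellipse center, cm (default: domain center).
#' @param L0 spring rest length, cm (default: equal-area circle chord).
#' @return list with `model` ([fiber_model()]) and `bstate`
#'   ([boundary_state()]).
#' @export
make_ellipse_membrane <- function(a, b, grid, stiffness = 1e4, n_points = NULL,
                                  center = NULL, L0 = NULL) {
  stopifnot(grid$ndim == 2L)
  if (2 * a >= grid$extent[1] || 2 * b >= grid$extent[2])
    stop("ellipse does not fit in the domain")
  if (is.null(center)) center <- grid$extent / 2
  # perimeter via Ramanujan, then >= 2 points per meshwidth
  hsum <- (a - b)^2 / (a + b)^2
  per <- pi * (a + b) * (1 + 3 * hsum / (10 + sqrt(4 - 3 * hsum)))
  if (is.null(n_points)) n_points <- max(8L, ceiling(2 * per / grid$h))
  # arclength-uniform sampling (uniform angle under-resolves the flat side)
  tt <- seq(0, 2 * pi, length.out = 4096)
  xy <- cbind(center[1] + a * cos(tt), center[2] + b * sin(tt))
  sarc <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  si <- seq(0, sarc[length(sarc)], length.out = n_points + 1L)[-(n_points + 1L)]
  X <- cbind(stats::approx(sarc, xy[, 1], si)$y, stats::approx(sarc, xy[, 2], si)$y)
  seg <- sqrt(rowSums((X[c(2:n_points, 1), ] - X)^2))
  if (max(seg) > grid$h / 2)
    warning("membrane under-resolved: point spacing exceeds h/2 (leakage risk)")
  if (is.null(L0)) L0 <- 2 * sqrt(a * b) * sin(pi / n_points)
  model <- fiber_model(X, ring_springs(n_points, stiffness, L0, "membrane"),
                       ds = mean(seg))
  list(model = model, bstate = boundary_state(model))
}

#' Tethered cylinder fixture
#'
#' A ring of boundary points each tethered stiffly to its rest position,
#' approximating a rigid circular cylinder. Combined with a pair of
#' balanced strip ports (source upstream, sink mid-domain) this
#' reproduces the classic validation flow: a time-periodic vortex street
#' at Reynolds number near 100 and a steady wake near 20.
#'
#' @param center cylinder center, cm.
#' @param radius cylinder radius, cm (at least `4 h`).
#' @param grid an [grid_spec()] (2-D).
#' @param tether_stiffness tether stiffness, dyn/cm.
#' @param ring_stiffness stiffness of the circumferential springs,
#'   dyn/cm.
#' @param n_points number of boundary points (default: two per
#'   meshwidth).
#' @param screen_x optional x positions (cm) of flow-conditioning
#'   screens: columns of stiffly tethered points spanning the domain
#'   height, the numerical analogue of a wind-tunnel honeycomb. Placed
#'   over the sink region they absorb arriving wake vorticity, which
#'   otherwise recirculates through the periodic domain and destabilizes
#'   the stream.
#' @param screen_stiffness tether stiffness of screen points, dyn/cm.
#' @return list with `model` and `bstate`.
#' @export
make_cylinder_ring <- function(center, radius, grid, tether_stiffness = 200,
                               ring_stiffness = 50, n_points = NULL,
                               screen_x = NULL, screen_stiffness = 100) {
  stopifnot(grid$ndim == 2L)
  if (radius < 4 * grid$h) stop("cylinder radius must be at least 4h")
  if (is.null(n_points)) n_points <- max(8L, ceiling(2 * (2 * pi * radius) / grid$h))
  th <- 2 * pi * (seq_len(n_points) - 1) / n_points
  X <- cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
  chord <- 2 * radius * sin(pi / n_points)
  springs <- ring_springs(n_points, ring_stiffness, chord, "cylinder")
  ds <- rep(2 * pi * radius / n_points, n_points)
  teth <- data.frame(point = seq_len(n_points), tx = X[, 1], ty = X[, 2],
                     k = tether_stiffness)
  for (sx in screen_x) {
    ys <- grid$coords[[2]]
    Xs <- cbind(rep(sx, length(ys)), ys)
    idx <- nrow(X) + seq_len(nrow(Xs))
    X <- rbind(X, Xs)
    ds <- c(ds, rep(grid$h, nrow(Xs)))
    teth <- rbind(teth, data.frame(point = idx, tx = Xs[, 1], ty = Xs[, 2],
                                   k = screen_stiffness))
  }
  model <- fiber_model(X, springs, ds = ds, tethers = teth)
  list(model = model, bstate = boundary_state(model))
}

#' Closed ellipsoid shell fixture (3-D smoke test)
#'
#' A latitude--longitude spring network over an ellipsoid, used only to
#' exercise the 3-D code path at small grids; the 2-D fixtures are the
#' primary test geometries.
#'
#' @param semiaxes length-3 semi-axes, cm.
#' @param grid an [grid_spec()] (3-D).
#' @param stiffness spring stiffness, dyn/cm.
#' @param n_lat,n_lon latitude/longitude resolution.
#' @param center shell center, cm (default: domain center).
#' @return list with `model` and `bstate`.
#' @export
make_ellipsoid_shell <- function(semiaxes, grid, stiffness = 1e3,
                                 n_lat = 9L, n_lon = 16L, center = NULL) {
  stopifnot(grid$ndim == 3L, length(semiaxes) == 3L)
  if (is.null(center)) center <- grid$extent / 2
  lat <- pi * seq_len(n_lat) / (n_lat + 1)  # exclude poles
  lon <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  pts <- expand.grid(lat = lat, lon = lon)
  X <- cbind(center[1] + semiaxes[1] * sin(pts$lat) * cos(pts$lon),
             center[2] + semiaxes[2] * sin(pts$lat) * sin(pts$lon),
             center[3] + semiaxes[3] * cos(pts$lat))
  idx <- function(i, j) (j - 1L) * n_lat + i  # lat index i, lon index j
  sp <- list()
  for (j in seq_len(n_lon)) {
    jn <- if (j == n_lon) 1L else j + 1L
    for (i in seq_len(n_lat)) {
      sp[[length(sp) + 1L]] <- c(idx(i, j), idx(i, jn))          # parallel
      if (i < n_lat) sp[[length(sp) + 1L]] <- c(idx(i, j), idx(i + 1L, j))  # meridian
    }
  }
  sp <- do.call(rbind, sp)
  d <- sqrt(rowSums((X[sp[, 1], ] - X[sp[, 2], ])^2))
  springs <- data.frame(i = sp[, 1], j = sp[, 2], k = stiffness, L0 = d,
                        group = "shell")
  area <- 4 * pi * prod(semiaxes)^(2 / 3)  # rough equal-volume sphere area
  model <- fiber_model(X, springs, ds = area / nrow(X))
  list(model = model, bstate = boundary_state(model))
}
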