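#' z-vorticity of a velocity slice
#'
#' `omega_z = dv/dx - du/dy` via centered periodic differences. For a
#' 3-D field pass `z_index` to extract the (u, v) plane first; the slice
#' location can also be given as a normalized coordinate in `[0, 1]`
#' through `z_frac`.
#'
#' @param u list of velocity component arrays (2-D slice or 3-D field).
#' @param grid an [grid_spec()].
#' @param z_index,z_frac slice selection for 3-D input.
#' @return scalar array of vorticity, 1/s.
#' @export
vorticity_z <- function(u, grid, z_index = NULL, z_frac = NULL) {
  if (grid$ndim == 3L) {
    if (is.null(z_index)) {
      if (is.null(z_frac)) stop("give z_index or z_frac for 3-D input")
      z_index <- max(1L, min(grid$n[3], round(z_frac * grid$n[3])))
    }
    ux <- u[[1]][, , z_index]
    uy <- u[[2]][, , z_index]
  } else {
    ux <- u[[1]]
    uy <- u[[2]]
  }
  h <- grid$h
  cdiff(uy, 1L, h) - cdiff(ux, 2L, h)
}

#' Slice kinetic energy
#'
#' Kinetic-energy density `0.5 rho |u|^2` over a 2-D slice;
#' `mode = "max"` returns its maximum, `mode = "total"` the discrete
#' integral (`h^2` per cell). An optional floor masks values below a
#' visualization threshold before reduction.
#'
#' @param u list of velocity component arrays (2-D slice; for 3-D pass
#'   the extracted slice components).
#' @param rho fluid density, g/cm^3.
#' @param grid an [grid_spec()].
#' @param mode `"max"` or `"total"`.
#' @param floor optional energy-density floor; values below it are
#'   dropped.
#' @return scalar, erg/cm^3 density units for `"max"`; erg/cm for
#'   `"total"` over a 2-D slice.
#' @export
kinetic_energy_slice <- function(u, rho, grid, mode = c("max", "total"),
                                 floor = NULL) {
  mode <- match.arg(mode)
  ke <- 0
  for (comp in u) ke <- ke + comp^2
  ke <- 0.5 * rho * ke
  if (!is.null(floor)) ke[ke < floor] <- 0
  if (mode == "max") max(ke) else sum(ke) * grid$h^2
}

# segment-intersection test for polygon self-intersection (non-adjacent edges)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Chamber area / volume from a boundary loop
#'
#' Shoelace area of the closed polygon through the given boundary points
#' (2-D). The loop is closed implicitly from the last point back to the
#' first, so an open chamber wall is closed by a chord across its
#' opening. Orientation does not matter (absolute value). Used for the
#' stroke volume: the chamber area difference between end-diastole and
#' end-systole.
#'
#' @param bstate an [boundary_state()].
#' @param loop ordered point indices of the chamber wall.
#' @param check if TRUE, raise on a self-intersecting loop (O(n^2); turn
#'   off inside tight loops after validating once).
#' @return enclosed area, cm^2.
#' @export
chamber_volume <- function(bstate, loop, check = TRUE) {
  P <- bstate$X[loop, , drop = FALSE]
  n <- nrow(P)
  if (n < 3L) stop("loop needs at least 3 points")
  if (check) {
    nxt <- c(2:n, 1L)
    for (a in seq_len(n - 2L)) {
      bmax <- if (a == 1L) n - 1L else n
      for (b in (a + 2L):bmax) {
        if (segments_cross(P[a, ], P[nxt[a], ], P[b, ], P[nxt[b], ]))
          stop("self-intersecting chamber loop")
      }
    }
  }
  i2 <- c(2:n, 1L)
  abs(sum(P[, 1] * P[i2, 2] - P[i2, 1] * P[, 2])) / 2
}

#' Non-dimensionalize a flow-rate series
#'
#' `Q* = Q T / V_stroke`: flow rate scaled by the stroke volume and the
#' cardiac cycle period, the convention used to compare chamber inflow
#' curves across rigs and subjects. Sign is preserved.
#'
#' @param Q flow-rate series (cm^3/s, or cm^2/s in 2-D).
#' @param T cycle period, s.
#' @param stroke_volume stroke volume (same volume units as `Q * T`).
#' @return dimensionless series.
#' @export
nondimensionalize_flow <- function(Q, T, stroke_volume) {
  if (!is.finite(stroke_volume) || stroke_volume <= 0)
    stop("degenerate cycle: stroke volume must be positive")
  Q * T / stroke_volume
}

#' Count signed vortex cores
#'
#' Thresholds the vorticity field at `threshold_frac * max|omega|`,
#' labels 8-neighbor connected components with periodic wrapping, drops
#' components smaller than `min_cells`, and counts the surviving cores
#' separately by sign. This operationalizes "a pair of vortices": an
#' early-diastolic transmitral jet should yield exactly one positive and
#' one negative dominant core flanking the jet.
#'
#' @param omega vorticity array (2-D).
#' @param threshold_frac fraction of the field maximum, in (0, 1).
#' @param min_cells minimum component size, cells.
#' @param mask optional logical array restricting the analysis region
#'   (e.g. the ventricle interior).
#' @return integer vector `c(n_positive, n_negative)`.
#' @export
count_vortex_cores <- function(omega, threshold_frac = 0.2, min_cells = 4L,
                               mask = NULL) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  if (!is.null(mask)) omega <- omega * mask
  mx <- max(abs(omega))
  if (mx == 0) return(c(n_positive = 0L, n_negative = 0L))
  thr <- threshold_frac * mx
  counts <- integer(2)
  dims <- dim(omega)
  nx <- dims[1]; ny <- dims[2]
  for (sgn in c(1, -1)) {
    active <- if (sgn > 0) omega > thr else omega < -thr
    lab <- array(0L, dims)
    nlab <- 0L
    sizes <- integer(0)
    for (start in which(active & lab == 0L)) {
      nlab <- nlab + 1L
      queue <- start
      lab[start] <- nlab
      sz <- 0L
      while (length(queue)) {
        cell <- queue[length(queue)]
        queue <- queue[-length(queue)]
        sz <- sz + 1L
        i <- (cell - 1L) %% nx
        j <- (cell - 1L) %/% nx
        for (di in -1:1) for (dj in -1:1) {
          if (di == 0L && dj == 0L) next
          ii <- (i + di) %% nx
          jj <- (j + dj) %% ny
          nb <- ii + nx * jj + 1L
          if (active[nb] && lab[nb] == 0L) {
            lab[nb] <- nlab
            queue <- c(queue, nb)
          }
        }
      }
      sizes[nlab] <- sz
    }
    counts[if (sgn > 0) 1L else 2L] <- sum(sizes >= min_cells)
  }
  c(n_positive = counts[1], n_negative = counts[2])
}

#' Detect kinetic-energy peaks
#'
#' Local maxima of a KE series with prominence at least
#' `prominence_frac` of the series maximum, returned in time order.
#' Over a full cardiac cycle of a pumping chamber this picks out the
#' E-wave, A-wave and S-wave peaks.
#'
#' @param ke kinetic-energy series.
#' @param t times (or normalized times) of the samples.
#' @param prominence_frac prominence threshold as a fraction of the
#'   series maximum.
#' @return data frame with columns `t` and `ke` of the peaks (zero rows
#'   for a constant series).
#' @export
detect_ke_peaks <- function(ke, t = seq_along(ke), prominence_frac = 0.1) {
  n <- length(ke)
  stopifnot(length(t) == n)
  if (n < 3L || diff(range(ke)) == 0) {
    return(data.frame(t = numeric(0), ke = numeric(0)))
  }
  cand <- which(diff(sign(diff(ke))) < 0) + 1L
  # plateau-tolerant: also accept flat-topped maxima
  cand <- cand[ke[cand] > ke[pmax(1L, cand - 1L)] | ke[cand] > ke[pmin(n, cand + 1L)]]
  if (!length(cand)) return(data.frame(t = numeric(0), ke = numeric(0)))
  prom <- vapply(cand, function(p) {
    left <- ke[seq_len(p - 1L)]
    right <- ke[seq.int(p + 1L, n)]
    hi_l <- which(left > ke[p])
    hi_r <- which(right > ke[p])
    base_l <- if (length(hi_l)) min(left[seq.int(max(hi_l), p - 1L)]) else min(left)
    base_r <- if (length(hi_r)) min(right[seq_len(min(hi_r))]) else min(right)
    ke[p] - max(base_l, base_r)
  }, 0)
  keep <- prom >= prominence_frac * max(ke)
  data.frame(t = t[cand[keep]], ke = ke[cand[keep]])
}
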