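#' Convert mmHg to CGS pressure units
#'
#' Unit bridge between clinically quoted reservoir pressures and the
#' CGS solver: 1 mmHg = 1333.22 dyn/cm^2 (the weight of a 0.1 cm mercury
#' column).
#'
#' @param p pressure in mmHg.
#' @return pressure in dyn/cm^2.
#' @examples
#' mmhg_to_cgs(80)  # aortic reservoir, 106657.6 dyn/cm^2
#' @export
mmhg_to_cgs <- function(p) p * 1333.22

#' Reservoir pressure port
#'
#' A localized source/sink region tied to a fixed external reservoir
#' pressure through a resistance. This realizes the reservoir pressure
#' boundary condition: at every step the port exchanges volume with the
#' domain at rate `Q = (P_reservoir - p_local) / R`, with `p_local` the
#' kernel-weighted mean fluid pressure over the port support. `Q > 0` is
#' inflow. Reference reservoir pressures for the five openings of the
#' heart are SVC/IVC 100, PV 15, PA 5 and aorta 80 mmHg, held constant
#' through the cycle.
#'
#' @param name port name (e.g. `"PV"`, `"AO"`).
#' @param center port center coordinates, cm.
#' @param radius support radius of the smeared source blob, cm (must be
#'   at least `2 h` on the grid used).
#' @param pressure_mmhg reservoir pressure, mmHg (constant by default).
#' @param resistance hydraulic resistance, mmHg s/cm^3 (mmHg s/cm^2 in
#'   2-D).
#' @param shape `"blob"` (radially symmetric cosine bump) or `"strip"`
#'   (a slab spanning the domain transverse to `axis`; used to create a
#'   uniform background inflow for the cylinder-wake fixture).
#' @param axis for `shape = "strip"`, the axis normal to the strip.
#' @return An object of class `ib_port`.
#' @export
reservoir_port <- function(name, center, radius, pressure_mmhg, resistance,
                           shape = c("blob", "strip"), axis = 1L) {
  shape <- match.arg(shape)
  stopifnot(radius > 0, resistance > 0)
  structure(list(name = name, center = as.numeric(center), radius = radius,
                 pressure_mmhg = pressure_mmhg,
                 pressure_cgs = mmhg_to_cgs(pressure_mmhg),
                 resistance = resistance,
                 resistance_cgs = mmhg_to_cgs(resistance),
                 shape = shape, axis = as.integer(axis)),
            class = "ib_port")
}

#' @export
print.ib_port <- function(x, ...) {
  cat(sprintf("<ib_port> %s (%s): center (%s) cm, radius %g cm, reservoir %g mmHg, R %g mmHg s/cm^%d\n",
              x$name, x$shape, paste(signif(x$center, 4), collapse = ", "),
              x$radius, x$pressure_mmhg, x$resistance, length(x$center)))
  invisible(x)
}

# minimal-image periodic displacement
periodic_delta <- function(x, x0, L) {
  d <- x - x0
  d - L * round(d / L)
}

# normalized weight field of one port (discrete integral h^ndim * sum(W) == 1)
port_weight <- function(port, grid) {
  if (port$radius < 2 * grid$h) {
    stop(sprintf("port %s: radius %g cm under-resolved (need >= 2h = %g cm)",
                 port$name, port$radius, 2 * grid$h))
  }
  nd <- grid$ndim
  if (port$shape == "strip") {
    d <- periodic_delta(grid$coords[[port$axis]], port$center[port$axis],
                        grid$extent[port$axis])
    w1 <- ifelse(abs(d) < port$radius, 0.5 * (1 + cos(pi * d / port$radius)), 0)
    perm <- seq_len(nd)
    perm[c(1L, port$axis)] <- perm[c(port$axis, 1L)]
    W <- aperm(array(w1, dim = grid$n[perm]), perm)
  } else {
    r2 <- 0
    for (d in seq_len(nd)) {
      dd <- periodic_delta(grid$coords[[d]], port$center[d], grid$extent[d])
      perm <- seq_len(nd)
      perm[c(1L, d)] <- perm[c(d, 1L)]
      r2 <- r2 + aperm(array(dd^2, dim = grid$n[perm]), perm)
    }
    r <- sqrt(r2)
    W <- ifelse(r < port$radius, 0.5 * (1 + cos(pi * r / port$radius)), 0)
  }
  W / (sum(W) * grid$h^nd)
}

# attach cached weight, source-blob and pressure-response (Green) fields;
# raises on overlapping blob supports
prepare_ports <- function(ports, grid) {
  if (is.null(ports) || length(ports) == 0) return(ports)
  nb <- which(vapply(ports, function(p) p$shape == "blob", TRUE))
  if (length(nb) > 1) {
    for (a in nb) for (b in nb) {
      if (a < b) {
        d <- periodic_delta(ports[[a]]$center, ports[[b]]$center, grid$extent)
        if (sqrt(sum(d^2)) < ports[[a]]$radius + ports[[b]]$radius)
          stop(sprintf("ports %s and %s have overlapping supports",
                       ports[[a]]$name, ports[[b]]$name))
      }
    }
  }
  ports <- lapply(ports, function(p) {
    p$weight <- port_weight(p, grid)
    # unit-rate source blob, restricted to the solvable Fourier space
    # (uniform compensation = removal of the mean mode)
    bhat <- fftn(p$weight)
    bhat[grid$null_modes] <- 0
    p$blob <- ifftn(bhat)
    # pressure response per unit rate: laplacian(green) = blob
    p$ghat <- bhat * grid$inv_poisson
    p$green <- ifftn(p$ghat)
    p$what_conj <- Conj(fftn(p$weight))
    p
  })
  hV <- grid$h^grid$ndim
  # S[k, j]: weighted mean of port j's unit pressure response at port k
  S <- vapply(ports, function(pj) {
    vapply(ports, function(pk) sum(pk$weight * pj$green) * hV, 0)
  }, numeric(length(ports)))
  attr(ports, "response") <- matrix(S, length(ports), length(ports))
  attr(ports, "Pres") <- vapply(ports, `[[`, 0, "pressure_cgs")
  attr(ports, "Rres") <- vapply(ports, `[[`, 0, "resistance_cgs")
  ports
}

# implicit reservoir-port projection: solves the coupled system so that
# Q_k = (P_k - pbar_k) / R_k holds with pbar evaluated on the projected
# pressure (explicit coupling is violently unstable because the
# projection pressure responds at O(rho/dt) to source changes)
project_with_ports <- function(provisional, ports, params, grid, dt_frac) {
  p_base <- solve_pressure_poisson(NULL, provisional, params, grid, dt_frac)
  if (is.null(ports) || length(ports) == 0) {
    return(list(u = project(provisional, p_base, params, grid, dt_frac),
                p = p_base, Q = numeric(0)))
  }
  hV <- grid$h^grid$ndim
  scale <- params$rho / dt_frac
  pbar0 <- vapply(ports, function(p) sum(p$weight * p_base) * hV, 0)
  Pres <- vapply(ports, `[[`, 0, "pressure_cgs")
  Rres <- vapply(ports, `[[`, 0, "resistance_cgs")
  A <- diag(Rres, length(ports)) - scale * attr(ports, "response")
  Q <- solve(A, Pres - pbar0)
  p <- p_base
  for (k in seq_along(ports)) p <- p - scale * Q[k] * ports[[k]]$green
  names(Q) <- vapply(ports, `[[`, "", "name")
  list(u = project(provisional, p, params, grid, dt_frac), p = p, Q = Q)
}

#' Port volumetric exchange rates
#'
#' For each port, `Q_k = (P_reservoir - pbar_k) / R_k`, with `pbar_k`
#' the weighted mean of the (zero-mean gauge) fluid pressure over the
#' port support, using the same smooth regularized weight as the source
#' field. `Q > 0` is inflow into the domain.
#'
#' @param ports list of [reservoir_port()] objects.
#' @param state an [fluid_state()] with gauge-fixed pressure.
#' @param grid an [grid_spec()].
#' @return named numeric vector of rates, cm^3/s (cm^2/s in 2-D).
#' @export
port_flow_rates <- function(ports, state, grid) {
  if (is.null(ports) || length(ports) == 0) return(numeric(0))
  if (is.null(ports[[1]]$weight)) ports <- prepare_ports(ports, grid)
  hV <- grid$h^grid$ndim
  Q <- vapply(ports, function(p) {
    pbar <- sum(state$p * p$weight) * hV
    (p$pressure_cgs - pbar) / p$resistance_cgs
  }, 0)
  names(Q) <- vapply(ports, `[[`, "", "name")
  Q
}

#' Build the prescribed divergence (source) field
#'
#' Places each port's rate on its normalized smooth blob and removes the
#' net residual as a uniform background divergence, so the domain
#' integral of the result is exactly zero (periodic solvability). The
#' handful of Fourier modes that the composed discrete
#' divergence-gradient stencil cannot represent (the per-axis Nyquist
#' combinations) are filtered out as well, so the projection can match
#' the field exactly.
#'
#' @param ports list of [reservoir_port()] objects.
#' @param rates per-port rates from [port_flow_rates()].
#' @param grid an [grid_spec()].
#' @return list with `q` (scalar divergence field, 1/s) and `port_rates`.
#' @export
build_source_field <- function(ports, rates, grid) {
  if (is.null(ports) || length(ports) == 0 || all(rates == 0)) {
    return(list(q = NULL, port_rates = rates))
  }
  if (is.null(ports[[1]]$weight)) ports <- prepare_ports(ports, grid)
  q <- 0
  for (k in seq_along(ports)) q <- q + rates[k] * ports[[k]]$weight
  qhat <- fftn(q)
  qhat[grid$null_modes] <- 0  # includes the mean: uniform compensation
  list(q = ifftn(qhat), port_rates = rates)
}
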