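# --- geometry helpers -------------------------------------------------------

# points along an ellipse arc, resampled to uniform arclength spacing
pts_arc <- function(center, rx, ry, th0, th1, spacing) {
  tt <- seq(th0, th1, length.out = 1024)
  xy <- cbind(center[1] + rx * cos(tt), center[2] + ry * sin(tt))
  s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  L <- s[length(s)]
  n <- max(2L, ceiling(L / spacing) + 1L)
  si <- seq(0, L, length.out = n)
  cbind(stats::approx(s, xy[, 1], si)$y, stats::approx(s, xy[, 2], si)$y)
}

pts_seg <- function(p0, p1, spacing) {
  L <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(L / spacing) + 1L)
  tt <- seq(0, 1, length.out = n)
  cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]))
}

# incremental fiber assembly: springs with tension modulus K (dyn/cm,
# per-segment k = K / segment length so line tension is resolution-free),
# optional next-nearest-neighbor bending springs, optional tethers
new_fiber_builder <- function() {
  env <- new.env()
  env$X <- list(); env$springs <- list(); env$tethers <- list()
  env$ds <- list(); env$fibers <- list()
  env$M <- 0L; env$last_ds <- NULL
  env
}

add_fiber <- function(bld, X, group, K, closed = FALSE, bend_K = 0,
                      tether_K = 0, tether_idx = NULL, tension_only = FALSE) {
  n <- nrow(X)
  off <- bld$M
  if (n > 1L) {
    seg <- sqrt(rowSums((X[c(2:n, 1L), , drop = FALSE] - X)^2))
    if (!closed) seg <- seg[-n]
    i <- seq_len(if (closed) n else n - 1L)
    j <- if (closed) c(2:n, 1L) else 2:n
    sp <- data.frame(i = off + i, j = off + j, k = K / seg, L0 = seg,
                     group = group, tension_only = tension_only)
    if (bend_K > 0 && n >= 3L) {
      i2 <- seq_len(if (closed) n else n - 2L)
      j2 <- if (closed) c(3:n, 1:2) else 3:n
      d2 <- sqrt(rowSums((X[j2, , drop = FALSE] - X[i2, , drop = FALSE])^2))
      sp <- rbind(sp, data.frame(i = off + i2, j = off + j2, k = bend_K / d2,
                                 L0 = d2, group = group, tension_only = tension_only))
    }
    bld$springs[[length(bld$springs) + 1L]] <- sp
    dsl <- if (closed) mean(seg) else sum(seg) / n
  } else {
    seg <- numeric(0)
    dsl <- bld$last_ds
  }
  bld$last_ds <- dsl
  bld$ds[[length(bld$ds) + 1L]] <- rep(dsl, n)
  if (tether_K > 0) {
    ti <- if (is.null(tether_idx)) seq_len(n) else tether_idx
    bld$tethers[[length(bld$tethers) + 1L]] <- data.frame(
      point = off + ti, tx = X[ti, 1], ty = X[ti, 2], k = tether_K * dsl)
  }
  bld$X[[length(bld$X) + 1L]] <- X
  bld$fibers[[group]] <- c(bld$fibers[[group]], list(off + seq_len(n)))
  bld$M <- off + n
  invisible(off + seq_len(n))
}

build_model <- function(bld) {
  X <- do.call(rbind, bld$X)
  springs <- do.call(rbind, bld$springs)
  tethers <- if (length(bld$tethers)) do.call(rbind, bld$tethers) else NULL
  fiber_model(X, springs, ds = unlist(bld$ds), tethers = tethers)
}

# --- the two-chamber ventricle fixture --------------------------------------

#' Simplified two-chamber ventricle fixture (2-D)
#'
#' A desk-scale stand-in for the anatomical heart: an elastic atrium and
#' a conical-sack ventricle joined by a mitral channel with two free
#' (hinged) valve flaps, an aortic sinus pocket with its own flap pair,
#' a pulmonary-vein source port in the atrium (15 mmHg reservoir) and an
#' aortic port in the sinus (80 mmHg reservoir). The activation schedule
#' contracts the ventricle through systole and releases it in early
#' diastole (E-wave recoil), with an atrial pulse at the A-wave center.
#'
#' All lengths scale with the domain extent, so the same physical
#' geometry is produced on finer grids (only the fiber discretization
#' refines, honoring the two-points-per-meshwidth anti-leakage rule).
#' The flap valves close only approximately -- there is no contact
#' algorithm -- so some mitral regurgitation during systole and a
#' negative pulmonary-vein flow phase are expected features, as they are
#' in the full-heart model this fixture stands in for.
#'
#' @param grid an [grid_spec()], 2-D, at least 48 cells per axis.
#' @param config named list of overrides: tension moduli `K_ventricle`,
#'   `K_atrium`, `K_conduit`, `K_flap` (dyn/cm), tether moduli
#'   `Kt_wall`, `Kt_conduit` (dyn/cm^2), port settings `pv_pressure`,
#'   `ao_pressure` (mmHg), `pv_resistance`, `ao_resistance`
#'   (mmHg s/cm^2), and `schedule` (an [activation_schedule()]).
#' @return list with `model`, `bstate`, `ports`, `schedule`, `chambers`
#'   (ordered point indices of the ventricle and atrium wall loops),
#'   `lv_box` (physical bounding box of the ventricle interior, for
#'   diagnostics), and `dt_suggest` (a stable time step for the default
#'   stiffnesses at this resolution, s).
#' @export
make_ventricle_2d <- function(grid, config = list()) {
  stopifnot(grid$ndim == 2L)
  if (any(grid$n < 48L)) stop("ventricle fixture needs a domain of at least 48^2 cells")
  cfg <- utils::modifyList(list(
    K_ventricle = 2e5, K_atrium = 2e5, K_conduit = 1e5, K_flap = 3e5,
    K_chord = 6e5, flap_bend = 1e5, Kt_wall = 2e4, Kt_conduit = 1.2e7,
    pv_pressure = 15, ao_pressure = 80,
    pv_resistance = 0.22, ao_resistance = 0.35, ao_bias = 2500,
    schedule = activation_schedule()
  ), config)
  s <- grid$extent[1] / 6.4
  sp_el <- grid$h / 2.5   # elastic wall point spacing
  sp_rg <- grid$h / 3     # rigid (tethered) wall point spacing
  off <- grid$h / 4       # half-gap between the two wall layers
  P <- function(x, y) c(x, y) * s

  bld <- new_fiber_builder()

  # the walls are double-layered (two closely offset fiber sheets): a
  # single sheet of the diffuse-interface kernel is measurably porous
  # under pressure heads of tens of mmHg, a double sheet is tight
  actr <- P(3.2, 4.75); Ra <- 1.0 * s
  dga <- asin(0.50 / 1.0)
  atr_idx <- NULL
  for (ro in c(-off, off)) {
    idx <- add_fiber(bld,
      pts_arc(actr, Ra + ro, Ra + ro, 3 * pi / 2 + dga, 3 * pi / 2 + 2 * pi - dga,
              sp_el),
      "atrium", K = cfg$K_atrium / 2, tether_K = cfg$Kt_wall)
    if (ro > 0) atr_idx <- idx
  }

  # ventricle: conical-sack ellipse with mitral (top) and aortic gaps;
  # the valve orifices span ~10 meshwidths on the default grid so the
  # valve flow is resolvable
  vctr <- P(3.2, 2.45); av <- 1.35 * s; bv <- 1.20 * s
  th_ml <- acos(-0.50 / 1.35)            # left mitral edge (x = 2.7)
  th_mr <- acos(0.50 / 1.35)             # right mitral edge (x = 3.7)
  th_ao1 <- 22 * pi / 180                # aortic gap lower edge
  th_ao2 <- 60 * pi / 180                # aortic gap upper edge
  lv_idx <- NULL
  for (ro in c(-off, off)) {
    idx <- add_fiber(bld,
      pts_arc(vctr, av + ro, bv + ro, th_ml, 2 * pi + th_ao1, sp_el),
      "ventricle", K = cfg$K_ventricle / 2, tether_K = cfg$Kt_wall)
    if (ro > 0) lv_idx <- idx
    add_fiber(bld, pts_arc(vctr, av + ro, bv + ro, th_ao2, th_mr, sp_el),
              "ventricle", K = cfg$K_ventricle / 2, tether_K = cfg$Kt_wall)
  }

  edge <- function(th) vctr + c(av * cos(th), bv * sin(th))
  m_l <- edge(th_ml); m_r <- edge(th_mr)
  ao_lo <- edge(th_ao1); ao_hi <- edge(th_ao2)

  # double wall segment offset along its normal
  seg2 <- function(p0, p1, group, K, tether_K) {
    d <- p1 - p0; d <- d / sqrt(sum(d^2))
    nrm <- c(-d[2], d[1])
    for (ro in c(-off, off)) {
      add_fiber(bld, pts_seg(p0 + ro * nrm, p1 + ro * nrm, sp_rg), group,
                K = K, tether_K = tether_K)
    }
  }

  # mitral channel walls join the atrium gap to the ventricle gap
  a_l <- actr + Ra * c(cos(3 * pi / 2 - dga), sin(3 * pi / 2 - dga))
  a_r <- actr + Ra * c(cos(3 * pi / 2 + dga), sin(3 * pi / 2 + dga))
  seg2(a_l, m_l, "conduit", cfg$K_conduit, cfg$Kt_conduit)
  seg2(a_r, m_r, "conduit", cfg$K_conduit, cfg$Kt_conduit)

  # aortic sinus: a walled pocket holding the aortic port
  gv <- ao_hi - ao_lo
  dir_ao <- c(gv[2], -gv[1]) / sqrt(sum(gv^2))  # outward normal of the gap
  if (sum(dir_ao * (ao_lo + ao_hi) / 2 - dir_ao * vctr) < 0) dir_ao <- -dir_ao
  c0 <- (ao_lo + ao_hi) / 2
  sctr <- c0 + 0.95 * s * dir_ao; Rs <- 0.62 * s
  th_back <- atan2(-dir_ao[2], -dir_ao[1])
  dgs <- asin(min(0.9, 0.5 * sqrt(sum((ao_hi - ao_lo)^2)) / Rs))
  for (ro in c(-off, off)) {
    add_fiber(bld, pts_arc(sctr, Rs + ro, Rs + ro, th_back + dgs,
                           th_back + 2 * pi - dgs, sp_rg),
              "conduit", K = cfg$K_conduit, tether_K = cfg$Kt_conduit)
  }
  s_lo <- sctr + Rs * c(cos(th_back - dgs), sin(th_back - dgs))
  s_hi <- sctr + Rs * c(cos(th_back + dgs), sin(th_back + dgs))
  if (sum((s_lo - ao_lo)^2) > sum((s_lo - ao_hi)^2)) { tmp <- s_lo; s_lo <- s_hi; s_hi <- tmp }
  seg2(ao_lo, s_lo, "conduit", cfg$K_conduit, cfg$Kt_conduit)
  seg2(ao_hi, s_hi, "conduit", cfg$K_conduit, cfg$Kt_conduit)

  # valve flaps: fiber chains hinged (tethered) at their first point,
  # starting in the closed position spanning the orifice. Each tip is
  # restrained by a tension-only chord (chorda) anchored on the side the
  # adverse pressure gradient comes from: the chord goes taut exactly at
  # the closed position, so backflow cannot prolapse the flap, while
  # forward flow swings it open freely (the chord falls slack). Closure
  # is approximate -- no contact forces -- so some regurgitation remains.
  add_chord <- function(pt_idx, pt_pos, anc_idx, anc_pos) {
    chord_L <- sqrt(sum((anc_pos - pt_pos)^2))
    bld$springs[[length(bld$springs) + 1L]] <- data.frame(
      i = pt_idx, j = anc_idx, k = cfg$K_chord / chord_L, L0 = chord_L,
      group = "chord", tension_only = TRUE)
  }
  # one flap of a two-flap valve: a hinged chain whose tip is held by
  # two tension-only chords (one to each anchor, so the tip is caged in
  # a cone: any prolapse direction tautens at least one chord) plus a
  # mid-flap chord against bowing through. The chord rest lengths are
  # set by the closed configuration; the chain itself may start in a
  # different (e.g. open) position.
  flap <- function(hinge, closed_tip, anchors, anchor_idx, init_tip = NULL) {
    if (is.null(init_tip)) init_tip <- closed_tip
    Xc <- pts_seg(hinge, closed_tip, sp_el)
    Xf <- pts_seg(hinge, init_tip, sp_el)
    stopifnot(nrow(Xf) == nrow(Xc))
    # leaflets are floppy: tension-only springs, so the closed flap pair
    # cannot prop itself across the orifice as a compressed arch
    idx <- add_fiber(bld, Xf, "flap", K = cfg$K_flap,
                     bend_K = cfg$flap_bend, tether_K = cfg$Kt_conduit,
                     tether_idx = 1L, tension_only = TRUE)
    ntip <- nrow(Xc)
    for (a in 1:2) add_chord(idx[ntip], Xc[ntip, ], anchor_idx[a], anchors[[a]])
    mid <- max(2L, ceiling(ntip / 2))
    near <- which.min(c(sum((anchors[[1]] - Xc[mid, ])^2),
                        sum((anchors[[2]] - Xc[mid, ])^2)))
    add_chord(idx[mid], Xc[mid, ], anchor_idx[near], anchors[[near]])
    idx[ntip]
  }
  valve <- function(hinge1, tip1, hinge2, tip2, anchors, open_limit = NULL,
                    init1 = NULL, init2 = NULL, bias = 0) {
    ai <- vapply(anchors, function(a) {
      add_fiber(bld, matrix(a, 1, 2), "anchor", K = 0, tether_K = cfg$Kt_conduit)[1]
    }, 0L)
    t1 <- flap(hinge1, tip1, anchors, ai, init1)
    t2 <- flap(hinge2, tip2, anchors, ai, init2)
    if (!is.null(open_limit)) {
      # tip-to-tip retainer: slack when closed, taut at the maximum
      # opening, so the flaps can never stream flat against the walls
      # out of reach of the closing backflow
      bld$springs[[length(bld$springs) + 1L]] <- data.frame(
        i = t1, j = t2, k = cfg$K_chord / open_limit, L0 = open_limit,
        group = "chord", tension_only = TRUE)
    }
    if (bias > 0) {
      # weak always-taut opening preload on each tip toward its own
      # sinus-side anchor: a nearly-closed flap pair self-seals by the
      # Bernoulli suction of its own leak slit, so a forward gradient of
      # a few mmHg alone cannot crack it; the preload breaks that
      # equilibrium while staying negligible against the adverse
      # diastolic gradient (which presses the flaps shut through the
      # chord cage)
      tips <- c(t1, t2)
      tpos <- rbind(if (is.null(init1)) tip1 else init1,
                    if (is.null(init2)) tip2 else init2)
      for (kk in 1:2) {
        d0 <- sqrt(sum((anchors[[kk]] - tpos[kk, ])^2))
        # attach just below the tip: the tip itself already carries a
        # cage chord to this anchor and spring pairs are unique
        bld$springs[[length(bld$springs) + 1L]] <- data.frame(
          i = tips[kk] - 1L, j = ai[kk], k = bias / d0, L0 = 0.2 * d0,
          group = "bias", tension_only = TRUE)
      }
    }
  }
  # mitral flaps close across the annulus; chordae anchor deep in the LV.
  # They start in the natural open (hanging) mid-diastolic position so
  # the first passive filling is deterministic; the closed geometry that
  # defines the chord cage is the annulus-spanning position.
  m_mid <- (m_l + m_r) / 2
  # closed tips overlap well past the center line (staggered vertically
  # so the sheets lie on top of each other): a doubled kernel sheet
  # leaks far less than an edge-to-edge butt joint
  tip_l <- m_mid + P(0.16, -0.03)
  tip_r <- m_mid + P(-0.16, -0.08)
  mlen1 <- sqrt(sum((tip_l - m_l)^2))
  mlen2 <- sqrt(sum((tip_r - m_r)^2))
  hang <- function(hinge, len, sgn) hinge + len * c(sgn * 0.33, -0.944)
  valve(m_l, tip_l, m_r, tip_r,
        list(P(2.80, 2.70), P(3.60, 2.70)),
        init1 = hang(m_l, mlen1, 1), init2 = hang(m_r, mlen2, -1))
  # aortic flaps close across the aortic gap; chords anchor in the sinus
  gapw <- sqrt(sum((ao_hi - ao_lo)^2))
  gapdir <- (ao_hi - ao_lo) / gapw
  # the aortic leaflets meet edge-to-edge: overlapped sheets would have
  # to slide apart to open, and the squeeze film between them is not
  # resolvable, which cements the valve shut against forward flow
  valve(ao_lo, c0 - 0.01 * s * gapdir, ao_hi, c0 + 0.01 * s * gapdir,
        list(ao_lo + 0.62 * s * dir_ao, ao_hi + 0.62 * s * dir_ao),
        open_limit = 0.70 * gapw, bias = cfg$ao_bias)

  model <- build_model(bld)
  bstate <- boundary_state(model)

  ports <- list(
    reservoir_port("PV", P(3.2, 5.10), 0.30 * s, cfg$pv_pressure, cfg$pv_resistance),
    reservoir_port("AO", sctr, 0.30 * s, cfg$ao_pressure, cfg$ao_resistance)
  )
  # ports must sit clear of every wall
  for (p in ports) {
    dmin <- sqrt(min(rowSums((model$points - matrix(p$center, nrow(model$points), 2,
                                                   byrow = TRUE))^2)))
    if (dmin < p$radius) stop(sprintf("port %s lies inside a wall", p$name))
  }

  list(model = model, bstate = bstate, ports = ports, schedule = cfg$schedule,
       chambers = list(ventricle = lv_idx, atrium = atr_idx),
       lv_box = rbind(c(1.95, 1.25) * s, c(4.45, 3.40) * s),
       dt_suggest = 2.0e-5 * (grid$h / (0.1 * s))^1.5)
}
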