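#' Standard ventricle analysis protocol
#'
#' The packaged study protocol for the two-chamber ventricle fixture:
#' start quiescent at diastole onset with the mitral leaflets in their
#' natural open position, so the E-wave is the first filling jet driven
#' into a pristine chamber by the pulmonary-vein reservoir head; the
#' atrial pulse and systolic ejection follow within the same cycle.
#' Field snapshots are retained across the early-diastole window so the
#' E-wave vortex pair can be examined at its peak-inflow instant.
#'
#' @param grid an [grid_spec()] (2-D, at least 48 cells).
#' @param config fixture overrides passed to [make_ventricle_2d()].
#' @param dt time step, s (default: the fixture's suggested stable step).
#' @param cycles number of full cycles to record.
#' @param t_stop_norm if not NULL, stop early at this normalized time of
#'   the first recorded cycle (used by the grid-refinement comparison,
#'   which only needs the early-diastolic fields).
#' @param snapshot_t_norm times at which to retain full field
#'   snapshots, as normalized offsets from the start of the run (the
#'   corresponding cycle phase is the protocol start phase plus the
#'   offset).
#' @param record_every diagnostic recording cadence, steps.
#' @return list with the fixture `fix`, `grid`, `params`, diagnostics
#'   `series` (with `t_norm` of the analysis clock), `snapshots`, and
#'   `cycle` (the rows of the first full analysis cycle).
#' @export
ventricle_protocol <- function(grid, config = list(), dt = NULL, cycles = 1L,
                               t_stop_norm = NULL,
                               snapshot_t_norm = seq(0.04, 0.24, by = 0.02),
                               record_every = 8L) {
  fix <- make_ventricle_2d(grid, config)
  if (is.null(dt)) dt <- fix$dt_suggest
  params <- fluid_params(rho = 1, nu = 0.03125, dt = dt)
  T <- fix$schedule$T
  # the activation clock starts where the release ramp ends, so the
  # quiescent rest geometry is consistent with the baseline activation
  # (starting inside the systolic plateau would slam the walls at t = 0)
  t_start_norm <- fix$schedule$release_span[2]
  t0 <- -t_start_norm * T
  t_cycle0 <- 0                          # the first cycle is analyzed
  t_end <- if (is.null(t_stop_norm)) t_cycle0 + cycles * T
           else t_cycle0 + t_stop_norm * T
  n_steps <- ceiling(t_end / dt)
  keep_at <- t_cycle0 + snapshot_t_norm * T
  keep_at <- keep_at[keep_at <= t_end]
  res <- run_fsi_loop(fluid_state(grid), fix$bstate, fix$model, fix$ports,
                      params, grid, schedule = fix$schedule, n_steps = n_steps,
                      t_cycle_start = t0, record_every = record_every,
                      chambers = fix$chambers, ke_box = fix$lv_box,
                      keep_fields_at = keep_at, snapshot_window = 0.008 * T,
                      pressure_probes = list(
                        LV = grid$extent * c(0.5, 0.36),
                        SIN = fix$ports[[2]]$center,
                        ATR = grid$extent * c(0.5, 0.76)))
  cyc <- res$series[res$series$t > t_cycle0 & res$series$t <= t_cycle0 + T, ]
  cyc$phase <- cyc$t / T + t_start_norm   # continuous cycle phase
  list(fix = fix, grid = grid, params = params, series = res$series,
       snapshots = res$snapshots, cycle = cyc, t_cycle0 = t_cycle0,
       t_start_norm = t_start_norm)
}

#' Kinetic-energy peaks of the analysis cycle
#'
#' Beat-resampled (default 32 phase bins) peak analysis of the chamber
#' kinetic-energy series over the protocol's analysis cycle, in
#' continuous phase units (the window runs from the protocol start
#' phase to start phase + 1).
#'
#' @param run result of [ventricle_protocol()].
#' @param bins phase bins per cycle.
#' @param prominence_frac forwarded to [detect_ke_peaks()].
#' @return data frame of peak phases and heights.
#' @export
cycle_ke_peaks <- function(run, bins = 32L, prominence_frac = 0.1) {
  cyc <- run$cycle
  # the window ends where the next release ramp begins: the onset of the
  # following beat's recoil belongs to the next cycle's E-wave and would
  # otherwise mask this cycle's peak structure
  end_phase <- 1 + run$fix$schedule$release_span[1]
  cyc <- cyc[cyc$phase <= end_phase, ]
  span <- end_phase - run$t_start_norm
  kb <- beat_resample((cyc$phase - run$t_start_norm) / span, cyc$ke_max_box, bins)
  pk <- detect_ke_peaks(kb$x, kb$t * span + run$t_start_norm, prominence_frac)
  names(pk)[1] <- "phase"
  pk
}

#' Beat-resolved resampling of a cycle series
#'
#' Block-averages a per-step diagnostic series into `bins` equal phases
#' of the normalized cycle. Clinical cine acquisitions resolve a beat
#' into a few dozen frames; per-step samples additionally carry
#' grid-scale solver ringing that no physical instrument would see, so
#' waveform-level analyses (peak structure, phase means) operate on the
#' beat-resolved series.
#'
#' @param t_norm normalized times of the samples.
#' @param x series values.
#' @param bins number of phase bins per cycle.
#' @return data frame with bin centers `t` and means `x`.
#' @export
beat_resample <- function(t_norm, x, bins = 100L) {
  cut <- pmin(floor(t_norm * bins), bins - 1L)
  agg <- tapply(x, cut, mean)
  data.frame(t = (as.integer(names(agg)) + 0.5) / bins, x = unname(agg))
}

#' Count the E-wave vortex cores of a protocol run
#'
#' Locates the early-diastolic kinetic-energy peak among the retained
#' snapshots and counts signed vortex cores of the z-vorticity field
#' restricted to the ventricle interior.
#'
#' @param run result of [ventricle_protocol()].
#' @param at_t_norm evaluate at this normalized time instead of the KE
#'   peak (used to compare grids at the identical instant).
#' @param threshold_frac,min_cells forwarded to [count_vortex_cores()].
#' @return list with `cores` (named counts), `t_norm` of the snapshot
#'   used, and the vorticity field `omega`.
#' @export
ewave_vortex_cores <- function(run, at_t_norm = NULL, threshold_frac = 0.2,
                               min_cells = 4L) {
  stopifnot(length(run$snapshots) > 0)
  tns <- vapply(run$snapshots, `[[`, 0, "t_norm")
  if (is.null(at_t_norm)) {
    # peak E-wave inflow: maximum smoothed transmitral (PV-side) inflow
    # after the release ramp has finished
    ew <- run$fix$schedule$e_wave_span
    rel <- run$fix$schedule$release_span[2]
    early <- run$cycle[run$cycle$phase >= rel & run$cycle$phase <= ew[2], ]
    qs <- stats::filter(early$Q_PV, rep(1 / 9, 9), sides = 2)
    at_t_norm <- early$phase[which.max(qs)]
  }
  snap <- run$snapshots[[which.min(abs(tns - at_t_norm))]]
  g <- run$grid
  om <- vorticity_z(snap$state$u, g)
  # the analysis is grid-fair: fields from any resolution are brought to
  # the same total effective resolution before structures are counted.
  # That total combines the 0.2 cm analysis blur (about the in-plane
  # voxel size of the clinical velocity mapping this analysis emulates;
  # it also removes collocated-scheme checkerboard noise) with the
  # spreading-kernel footprint (2h) of the fixture reference grid (64
  # cells across the domain), so finer grids receive the extra blur
  # their sharper kernel lacks. The wall-adjacent kernel layer plus a
  # 0.2 cm margin around the current fibers is excluded, and the
  # minimum core area is fixed in cm^2 (min_cells at the reference
  # resolution).
  h_ref <- g$extent[1] / 64
  sig2 <- 0.2^2 + max(0, (2 * h_ref)^2 - (2 * g$h)^2)
  n_pass <- max(1L, round(2 * sig2 / g$h^2))
  n_dil <- max(1L, round(0.2 / g$h))
  min_cells <- max(min_cells, ceiling(min_cells * (h_ref / g$h)^2))
  om <- smooth_field2(om, n_pass)
  box <- run$fix$lv_box
  mask <- outer(g$coords[[1]] >= box[1, 1] & g$coords[[1]] <= box[2, 1],
                g$coords[[2]] >= box[1, 2] & g$coords[[2]] <= box[2, 2])
  mask <- mask & !dilate_mask(near_boundary_mask(snap$bstate, g), n_dil)
  list(cores = count_vortex_cores(om, threshold_frac, min_cells, mask = mask),
       t_norm = snap$t_norm, omega = om)
}
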