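#' Read / write a run configuration
#'
#' YAML with the key tree of [default_run_config()]. All values are in
#' CGS units except the documented port keys, which take mmHg.
#'
#' @param path file path.
#' @return for `read_run_config`, the configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Fiber geometry interchange files
#'
#' Plain-text CSV pair: `<stem>_points.csv` (id, coordinates, ds, and
#' tether target/stiffness columns where tethered) and
#' `<stem>_springs.csv` (i, j, k, L0, group). Round-trips an
#' [fiber_model()] losslessly up to numeric formatting.
#'
#' @param model an [fiber_model()].
#' @param stem output path stem.
#' @return for `read_fiber_csv`, the reconstructed model.
#' @export
write_fiber_csv <- function(model, stem) {
  nd <- model$ndim
  cn <- c("x", "y", "z")[seq_len(nd)]
  pts <- as.data.frame(model$points)
  names(pts) <- cn
  pts <- cbind(id = seq_len(nrow(pts)), pts, ds = model$ds)
  tc <- c("tx", "ty", "tz")[seq_len(nd)]
  for (col in c(tc, "tether_k")) pts[[col]] <- NA_real_
  te <- model$tethers
  if (!is.null(te) && nrow(te)) {
    for (col in tc) pts[[col]][te$point] <- te[[col]]
    pts$tether_k[te$point] <- te$k
  }
  utils::write.csv(pts, paste0(stem, "_points.csv"), row.names = FALSE)
  utils::write.csv(model$springs, paste0(stem, "_springs.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_fiber_csv
#' @export
read_fiber_csv <- function(stem) {
  pts <- utils::read.csv(paste0(stem, "_points.csv"))
  springs <- utils::read.csv(paste0(stem, "_springs.csv"))
  nd <- if ("z" %in% names(pts)) 3L else 2L
  cn <- c("x", "y", "z")[seq_len(nd)]
  tc <- c("tx", "ty", "tz")[seq_len(nd)]
  teth <- NULL
  sel <- !is.na(pts$tether_k)
  if (any(sel)) {
    teth <- data.frame(point = pts$id[sel], pts[sel, tc, drop = FALSE],
                       k = pts$tether_k[sel])
  }
  fiber_model(as.matrix(pts[, cn]), springs, ds = pts$ds, tethers = teth)
}

#' Write a legacy-VTK structured-points snapshot
#'
#' ASCII VTK "STRUCTURED_POINTS" file with one scalar dataset per named
#' field, on the cell-centered grid (origin at `h/2`). Readable by
#' ParaView and VisIt.
#'
#' @param path output path.
#' @param grid an [grid_spec()].
#' @param fields named list of arrays with the grid's dimensions.
#' @param title VTK title line.
#' @export
write_vtk_structured <- function(path, grid, fields, title = "ibcms fields") {
  n <- grid$n
  n3 <- c(n, rep(1L, 3 - length(n)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n3[1], n3[2], n3[3]),
               sprintf("ORIGIN %g %g %g", grid$h / 2, grid$h / 2,
                       if (length(n) == 3L) grid$h / 2 else 0),
               sprintf("SPACING %g %g %g", grid$h, grid$h, grid$h),
               sprintf("POINT_DATA %d", prod(n3))), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(fields[[nm]]), digits = 9, trim = TRUE,
                      scientific = TRUE), con)
  }
  invisible(path)
}

#' Write / load a dense velocity volume
#'
#' Text container for externally supplied velocity data (e.g.
#' PC-MRI-like fields fed to the diagnostics without any simulation): a
#' YAML metadata file (`<stem>.yaml`: dimensions, meshwidth, axis order,
#' time) plus one CSV of flattened component columns (`<stem>_u.csv`).
#' Values are CGS (cm/s). Missing measurements may be encoded as NA;
#' they are kept as NA so downstream diagnostics propagate the mask.
#'
#' @param u list of velocity component arrays.
#' @param grid an [grid_spec()].
#' @param stem path stem.
#' @param t time stamp, s.
#' @param axes axis-order label stored in the metadata (e.g. "xy",
#'   "xyz").
#' @return for `load_velocity_volume`, a list with `u`, `grid` and `t`.
#' @export
write_velocity_volume <- function(u, grid, stem, t = 0,
                                  axes = c("xy", "xyz")[length(u) - 1L]) {
  meta <- list(ndim = grid$ndim, n = as.integer(grid$n),
               extent = as.numeric(grid$extent), h = grid$h, t = t,
               axes = axes, components = length(u))
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  df <- as.data.frame(lapply(u, as.vector))
  names(df) <- paste0("u", seq_along(u))
  utils::write.csv(df, paste0(stem, "_u.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_velocity_volume
#' @export
load_velocity_volume <- function(stem) {
  mpath <- paste0(stem, ".yaml")
  if (!file.exists(mpath)) stop("missing metadata file ", mpath)
  meta <- yaml::read_yaml(mpath)
  need <- c("ndim", "n", "extent", "h", "axes")
  missing <- setdiff(need, names(meta))
  if (length(missing)) stop("velocity volume metadata lacks keys: ",
                            paste(missing, collapse = ", "))
  df <- utils::read.csv(paste0(stem, "_u.csv"))
  n <- as.integer(meta$n)
  perm <- match(strsplit(meta$axes, "")[[1]], c("x", "y", "z")[seq_len(meta$ndim)])
  u <- lapply(df, function(col) {
    a <- array(col, dim = n)
    if (!identical(perm, seq_len(meta$ndim))) a <- aperm(a, perm)
    a
  })
  names(u) <- NULL
  grid <- grid_spec(dim(u[[1]]), as.numeric(meta$extent)[perm], meta$ndim)
  list(u = u, grid = grid, t = if (is.null(meta$t)) NA_real_ else meta$t)
}
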