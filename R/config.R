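#' Study configuration
#'
#' Bundles every run-level choice of the exposure framework: the projected
#' coordinate system, the analysis extent and grid menu, the distance-decay
#' menu and scale parameters, the tunnel radius and point-weighting mode,
#' and the master seed. All user-facing functions accept a `study_config`
#' so a whole study is reproducible from one object.
#'
#' @param crs Either `"local"` (input coordinates are already planar metres)
#'   or `"lonlat"` (inputs are WGS84 longitude/latitude; readers project them
#'   with a local azimuthal equidistant projection about `lonlat_origin`).
#' @param grid_extent Numeric vector `c(xmin, ymin, xmax, ymax)` in metres.
#'   If an extent edge is not a multiple of a requested cell size the grid is
#'   padded upward to the next multiple; the padding is recorded per layer.
#' @param spatial_resolutions Cell sizes in metres (default the 100/150/200 m
#'   menu).
#' @param temporal_resolutions Slot lengths in minutes; each must divide 1440
#'   (default 30 and 10 min).
#' @param decay_methods Subset of `"KD"`, `"ISDD"`, `"NEDD"`.
#' @param decay_params Named list of scale parameters in metres:
#'   `kd_bandwidth` (quartic-kernel support radius), `isdd_d0` (half-weight
#'   distance of the bounded inverse-square), `nedd_d0` (e-folding distance).
#' @param br Tunnel buffer radius in metres (default 100).
#' @param weight_mode `"constant"` (every intersected point weighs 1) or
#'   `"velocity"` (weight `(1/2)^v` with `v` in m/min).
#' @param lonlat_origin Projection origin `c(lon, lat)` in degrees; required
#'   when `crs = "lonlat"`, ignored otherwise.
#' @param seed Master integer seed; generators derive named sub-streams.
#'
#' @return An object of class `study_config` (a named list).
#' @examples
#' cfg <- study_config(grid_extent = c(0, 0, 2000, 2000))
#' cfg$br
#' @export
study_config <- function(crs = "local",
                         grid_extent = c(0, 0, 4000, 4000),
                         spatial_resolutions = c(100, 150, 200),
                         temporal_resolutions = c(30, 10),
                         decay_methods = c("KD", "ISDD", "NEDD"),
                         decay_params = list(kd_bandwidth = 1000,
                                             isdd_d0 = 100,
                                             nedd_d0 = 500),
                         br = 100,
                         weight_mode = c("constant", "velocity"),
                         lonlat_origin = NULL,
                         seed = 1L) {
  weight_mode <- match.arg(weight_mode)
  crs <- match.arg(crs, c("local", "lonlat"))
  stopifnot(is.numeric(grid_extent), length(grid_extent) == 4)
  if (grid_extent[3] <= grid_extent[1] || grid_extent[4] <= grid_extent[2]) {
    stop("grid_extent must have positive width and height", call. = FALSE)
  }
  if (any(spatial_resolutions <= 0)) {
    stop("spatial resolutions must be positive", call. = FALSE)
  }
  if (any(1440 %% temporal_resolutions != 0)) {
    stop("temporal resolutions must divide 1440 minutes", call. = FALSE)
  }
  decay_methods <- match.arg(decay_methods, c("KD", "ISDD", "NEDD"),
                             several.ok = TRUE)
  for (p in c("kd_bandwidth", "isdd_d0", "nedd_d0")) {
    if (is.null(decay_params[[p]])) {
      decay_params[[p]] <- formals(study_config)$decay_params[[p]]
    }
    if (decay_params[[p]] <= 0) {
      stop("decay parameter ", p, " must be positive", call. = FALSE)
    }
  }
  if (br <= 0) stop("br must be positive", call. = FALSE)
  structure(
    list(crs = crs,
         grid_extent = as.numeric(grid_extent),
         spatial_resolutions = as.numeric(spatial_resolutions),
         temporal_resolutions = as.integer(temporal_resolutions),
         decay_methods = decay_methods,
         decay_params = decay_params,
         br = as.numeric(br),
         weight_mode = weight_mode,
         lonlat_origin = lonlat_origin,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  crs:        ", x$crs, "\n")
  cat("  extent (m): ", paste(x$grid_extent, collapse = ", "), "\n")
  cat("  cell sizes: ", paste(x$spatial_resolutions, collapse = ", "), "m\n")
  cat("  slots:      ", paste(x$temporal_resolutions, collapse = ", "), "min\n")
  cat("  decay:      ", paste(x$decay_methods, collapse = ", "), "\n")
  cat("  Br:         ", x$br, "m;  weights:", x$weight_mode, "\n")
  invisible(x)
}

#' Read or write a study configuration file
#'
#' Configurations persist as a single YAML file mirroring the
#' [study_config()] arguments.
#'
#' @param path File path.
#' @return `read_config()` returns a `study_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(study_config, y[intersect(names(y), names(formals(study_config)))])
}

#' @rdname read_config
#' @param config A `study_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  y <- unclass(config)
  y$lonlat_origin <- if (is.null(y$lonlat_origin)) NULL else as.numeric(y$lonlat_origin)
  yaml::write_yaml(y, path)
  invisible(path)
}

# ---- grid geometry (internal) ------------------------------------------

# A grid geometry fixes the raster frame for one cell size: origin at the
# south-west corner of the configured extent, cells indexed row-major from
# the south-west, cell (i, j) covering the half-open square
# [x0+(j-1)s, x0+js) x [y0+(i-1)s, y0+is).
grid_geometry <- function(config, cell_size) {
  ext <- config$grid_extent
  width <- ext[3] - ext[1]
  height <- ext[4] - ext[2]
  nx <- ceiling(width / cell_size - 1e-9)
  ny <- ceiling(height / cell_size - 1e-9)
  list(xmin = ext[1], ymin = ext[2],
       nx = as.integer(nx), ny = as.integer(ny),
       cell_size = cell_size,
       pad_x = nx * cell_size - width,
       pad_y = ny * cell_size - height)
}

# Centroid coordinates of every cell, as vectors indexed j = 1..nx, i = 1..ny.
centroid_x <- function(geom) geom$xmin + (seq_len(geom$nx) - 0.5) * geom$cell_size
centroid_y <- function(geom) geom$ymin + (seq_len(geom$ny) - 0.5) * geom$cell_size

# Column/row index of the cell containing a point (NA outside the grid).
cell_col <- function(geom, x) {
  j <- floor((x - geom$xmin) / geom$cell_size) + 1
  j[j < 1 | j > geom$nx] <- NA_integer_
  as.integer(j)
}
cell_row <- function(geom, y) {
  i <- floor((y - geom$ymin) / geom$cell_size) + 1
  i[i < 1 | i > geom$ny] <- NA_integer_
  as.integer(i)
}

# Named sub-stream seed derivation: one master seed, one fixed offset per
# generator, so adding a generator never perturbs the draws of another.
substream_seed <- function(seed, stream) {
  offsets <- c(outlets = 101L, trajectories = 211L, outcomes = 307L,
               covariates = 401L, acceptance = 503L, generic = 601L)
  off <- offsets[[stream]]
  if (is.null(off)) off <- offsets[["generic"]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}
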