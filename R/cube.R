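#' Build an environmental context cube at 30-min resolution
#'
#' Stacks one food-environment layer per half-hour slot (48 layers at slot
#' starts 00:00, 00:30, ..., 23:30) for one day type, decay method and cell
#' size. The cube is the dynamic representation of the environment: voxel
#' (i, j, l) holds the decayed outlet intensity at cell (i, j) during slot l.
#'
#' @inheritParams build_layer
#' @return An object of class `context_cube`: list with `layers` (list of
#'   numeric matrices), `t_axis` (slot start minutes), `slot_minutes`,
#'   `day_type`, `method`, `cell_size`, `scale`, `geom`, `cutoff`.
#' @export
build_cube <- function(registry, day_type, method, cell_size, config,
                       cutoff = 1e-9) {
  slot_minutes <- 30L
  starts <- seq(0L, 1439L, by = slot_minutes)
  layers <- lapply(starts, function(s) {
    build_layer(registry, day_type, s, method, cell_size, config,
                cutoff = cutoff)$grid
  })
  geom <- grid_geometry(config, cell_size)
  new_context_cube(layers, starts, slot_minutes, day_type, method,
                   cell_size, decay_scale(config, method), geom, cutoff)
}

new_context_cube <- function(layers, t_axis, slot_minutes, day_type, method,
                             cell_size, scale, geom, cutoff) {
  stopifnot(length(layers) == 1440 / slot_minutes,
            length(t_axis) == length(layers),
            !is.unsorted(t_axis, strictly = TRUE))
  structure(list(layers = layers, t_axis = as.numeric(t_axis),
                 slot_minutes = as.integer(slot_minutes),
                 day_type = day_type, method = method,
                 cell_size = cell_size, scale = scale, geom = geom,
                 cutoff = cutoff),
            class = "context_cube")
}

#' @export
print.context_cube <- function(x, ...) {
  cat("<context_cube>", cube_key(x), "|", x$day_type, "|",
      length(x$layers), "layers of", x$geom$ny, "x", x$geom$nx, "cells\n")
  invisible(x)
}

#' Method key of a cube (e.g. `"ISDD100T10"`)
#'
#' The key concatenates decay method, spatial resolution in metres, and
#' temporal resolution in minutes — the naming scheme used throughout the
#' model-comparison harness.
#'
#' @param cube A `context_cube`.
#' @return A string.
#' @export
cube_key <- function(cube) {
  paste0(cube$method, format(cube$cell_size, trim = TRUE), "T",
         cube$slot_minutes)
}

#' Refine a 30-min cube to 10-min temporal resolution
#'
#' Keeps the 48 original layers and inserts two per half-hour by per-pixel
#' linear interpolation between temporally adjacent originals; the layers
#' after 23:30 interpolate toward the 00:00 layer (daily wrap). Output has
#' 144 layers at slot starts 00:00, 00:10, ..., 23:50.
#'
#' @param cube A 30-min `context_cube`.
#' @return A 10-min `context_cube`.
#' @export
refine_cube <- function(cube) {
  stopifnot(inherits(cube, "context_cube"))
  if (cube$slot_minutes != 30L || length(cube$layers) != 48) {
    stop("refine_cube() expects a 30-min cube with 48 layers", call. = FALSE)
  }
  layers <- vector("list", 144)
  for (k in seq_len(48)) {
    l0 <- cube$layers[[k]]
    l1 <- cube$layers[[if (k == 48) 1 else k + 1]]
    base <- (k - 1) * 3
    layers[[base + 1]] <- l0
    layers[[base + 2]] <- (2 / 3) * l0 + (1 / 3) * l1
    layers[[base + 3]] <- (1 / 3) * l0 + (2 / 3) * l1
  }
  new_context_cube(layers, seq(0L, 1439L, by = 10L), 10L, cube$day_type,
                   cube$method, cube$cell_size, cube$scale, cube$geom,
                   cube$cutoff)
}

#' Convert a cube to a 3-D point cloud
#'
#' One point per voxel, located at the cell centroid in x/y and the slot
#' midpoint in t (e.g. 00:15 for slot \[00:00, 00:30)), carrying the voxel
#' value unchanged.
#'
#' @param cube A `context_cube`.
#' @param drop_zero Drop zero-valued points (recorded in the result's
#'   attributes; dropped points contribute 0 to any exposure sum).
#' @return A tibble of class `cube_cloud` with columns `x`, `y`, `t`
#'   (minute of day), `value`; cube identity is carried in attributes
#'   `day_type`, `method`, `cell_size`, `slot_minutes`, `geom`.
#' @export
to_point_cloud <- function(cube, drop_zero = FALSE) {
  stopifnot(inherits(cube, "context_cube"))
  geom <- cube$geom
  cx <- centroid_x(geom); cy <- centroid_y(geom)
  nlay <- length(cube$layers)
  ncell <- geom$nx * geom$ny
  pts <- tibble::tibble(
    x = rep(rep(cx, each = geom$ny), times = nlay),
    y = rep(rep(cy, times = geom$nx), times = nlay),
    t = rep(cube$t_axis + cube$slot_minutes / 2, each = ncell),
    value = unlist(lapply(cube$layers, as.vector), use.names = FALSE)
  )
  if (drop_zero) pts <- pts[pts$value != 0, , drop = FALSE]
  structure(pts,
            class = c("cube_cloud", class(pts)),
            day_type = cube$day_type, method = cube$method,
            cell_size = cube$cell_size, slot_minutes = cube$slot_minutes,
            geom = geom, dropped_zeros = drop_zero)
}

#' Re-voxelise a point cloud into a cube
#'
#' Inverse of [to_point_cloud()] for full (non-filtered) clouds; used to
#' round-trip cubes through their point-cloud form.
#'
#' @param cloud A `cube_cloud`.
#' @param scale,cutoff Optional metadata to restore on the cube.
#' @return A `context_cube`.
#' @export
from_point_cloud <- function(cloud, scale = NA_real_, cutoff = 0) {
  geom <- attr(cloud, "geom")
  slot_minutes <- attr(cloud, "slot_minutes")
  t_axis <- seq(0, 1439, by = slot_minutes)
  mids <- t_axis + slot_minutes / 2
  i <- cell_row(geom, cloud$y)
  j <- cell_col(geom, cloud$x)
  l <- match(cloud$t, mids)
  layers <- rep(list(matrix(0, geom$ny, geom$nx)), length(t_axis))
  for (lv in sort(unique(l))) {
    sel <- which(l == lv)
    m <- matrix(0, geom$ny, geom$nx)
    m[cbind(i[sel], j[sel])] <- cloud$value[sel]
    layers[[lv]] <- m
  }
  new_context_cube(layers, t_axis, slot_minutes, attr(cloud, "day_type"),
                   attr(cloud, "method"), attr(cloud, "cell_size"),
                   scale, geom, cutoff)
}

#' Build the full cube menu
#'
#' Enumerates every (decay method, cell size, day type, temporal resolution)
#' combination of the configuration. With the default menu (3 methods, 3
#' cell sizes, 3 day types, 30- and 10-min slots) this yields 54 cubes, 27
#' per temporal resolution; the 10-min cubes are obtained from their 30-min
#' parents by [refine_cube()].
#'
#' @param registry An `outlet_registry`.
#' @param config A [study_config()].
#' @return A tibble with one row per cube: `method`, `cell_size`,
#'   `slot_minutes`, `day_type`, `method_key`, `cube_id`, and a `cube`
#'   list-column of `context_cube` objects.
#' @export
enumerate_cubes <- function(registry, config) {
  combos <- tidyr::expand_grid(
    method = config$decay_methods,
    cell_size = config$spatial_resolutions,
    day_type = c("weekday", "saturday", "sunday")
  )
  rows <- purrr::pmap_dfr(combos, function(method, cell_size, day_type) {
    c30 <- build_cube(registry, day_type, method, cell_size, config)
    out <- tibble::tibble(method = method, cell_size = cell_size,
                          slot_minutes = 30L, day_type = day_type,
                          cube = list(c30))
    if (10L %in% config$temporal_resolutions) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        method = method, cell_size = cell_size, slot_minutes = 10L,
        day_type = day_type, cube = list(refine_cube(c30))))
    }
    out
  })
  rows <- rows[rows$slot_minutes %in% config$temporal_resolutions, ,
               drop = FALSE]
  rows$method_key <- purrr::map_chr(rows$cube, cube_key)
  rows$cube_id <- paste(rows$method_key, rows$day_type, sep = ".")
  stopifnot(!anyDuplicated(rows$cube_id))
  dplyr::select(rows, "method", "cell_size", "slot_minutes", "day_type",
                "method_key", "cube_id", "cube")
}
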