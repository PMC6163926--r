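#' Write / read an environment layer
#'
#' Layers persist as plain-text ESRI ASCII grid rasters (`.asc`) with a JSON
#' sidecar (`.json`) holding the layer identity (day type, slot start,
#' method, scale, cutoff). ASCII-grid rows run north to south, so the
#' in-memory south-up matrix is flipped on write and restored on read.
#'
#' @param layer An `env_layer` from [build_layer()].
#' @param path_prefix Path without extension; `.asc` and `.json` are added.
#' @return `write_layer()` returns `path_prefix` invisibly; `read_layer()`
#'   returns an `env_layer`.
#' @export
write_layer <- function(layer, path_prefix) {
  stopifnot(inherits(layer, "env_layer"))
  geom <- layer$geom
  header <- c(
    sprintf("ncols %d", geom$nx),
    sprintf("nrows %d", geom$ny),
    sprintf("xllcorner %.10g", geom$xmin),
    sprintf("yllcorner %.10g", geom$ymin),
    sprintf("cellsize %.10g", geom$cell_size),
    "NODATA_value -9999")
  body <- apply(layer$grid[geom$ny:1, , drop = FALSE], 1,
                function(r) paste(format(r, digits = 17, trim = TRUE),
                                  collapse = " "))
  writeLines(c(header, body), paste0(path_prefix, ".asc"))
  side <- layer[c("day_type", "slot_start", "method", "cell_size",
                  "scale", "cutoff")]
  side$pad_x <- geom$pad_x; side$pad_y <- geom$pad_y
  jsonlite::write_json(side, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' @rdname write_layer
#' @export
read_layer <- function(path_prefix) {
  lines <- readLines(paste0(path_prefix, ".asc"))
  hdr <- strsplit(lines[1:6], "\\s+")
  hv <- stats::setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                        tolower(vapply(hdr, `[`, "", 1)))
  grid <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  grid <- grid[nrow(grid):1, , drop = FALSE]   # back to south-up
  side <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  geom <- list(xmin = unname(hv["xllcorner"]), ymin = unname(hv["yllcorner"]),
               nx = as.integer(hv["ncols"]), ny = as.integer(hv["nrows"]),
               cell_size = unname(hv["cellsize"]),
               pad_x = side$pad_x %||% 0, pad_y = side$pad_y %||% 0)
  structure(list(grid = grid, day_type = side$day_type,
                 slot_start = side$slot_start, method = side$method,
                 cell_size = side$cell_size, scale = side$scale,
                 geom = geom, cutoff = side$cutoff),
            class = "env_layer")
}

#' Write / read a cube point cloud as CSV
#'
#' Columns `x`, `y` (metres), `t` (minute of day, slot midpoint), `value`;
#' the cube identity travels in a JSON sidecar so the cloud can be
#' re-voxelised.
#'
#' @param cloud A `cube_cloud` from [to_point_cloud()].
#' @param path CSV path; the sidecar replaces the extension with `.json`.
#' @return `write_point_cloud()` returns `path` invisibly;
#'   `read_point_cloud()` returns a `cube_cloud`.
#' @export
write_point_cloud <- function(cloud, path) {
  readr::write_csv(tibble::as_tibble(cloud)[c("x", "y", "t", "value")],
                   path, progress = FALSE)
  geom <- attr(cloud, "geom")
  side <- list(day_type = attr(cloud, "day_type"),
               method = attr(cloud, "method"),
               cell_size = attr(cloud, "cell_size"),
               slot_minutes = attr(cloud, "slot_minutes"),
               dropped_zeros = isTRUE(attr(cloud, "dropped_zeros")),
               geom = geom)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  pts <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  geom <- side$geom
  geom$nx <- as.integer(geom$nx); geom$ny <- as.integer(geom$ny)
  structure(pts, class = c("cube_cloud", class(pts)),
            day_type = side$day_type, method = side$method,
            cell_size = side$cell_size,
            slot_minutes = as.integer(side$slot_minutes),
            geom = geom, dropped_zeros = isTRUE(side$dropped_zeros))
}

sidecar_path <- function(path) sub("\\.[A-Za-z0-9]+$", ".json", path)

#' Persist a cube as a directory of layer rasters
#'
#' Writes one ASCII-grid layer per time slot plus a `cube.json` manifest
#' (slot times, day type, method, resolutions).
#'
#' @param cube A `context_cube`.
#' @param dir Output directory (created if needed).
#' @return `write_cube()` returns `dir` invisibly; `read_cube()` returns a
#'   `context_cube`.
#' @export
write_cube <- function(cube, dir) {
  stopifnot(inherits(cube, "context_cube"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(cube$layers)) {
    lay <- structure(list(grid = cube$layers[[k]], day_type = cube$day_type,
                          slot_start = cube$t_axis[k], method = cube$method,
                          cell_size = cube$cell_size, scale = cube$scale,
                          geom = cube$geom, cutoff = cube$cutoff),
                     class = "env_layer")
    write_layer(lay, file.path(dir, sprintf("layer_%04d", cube$t_axis[k])))
  }
  jsonlite::write_json(
    list(day_type = cube$day_type, method = cube$method,
         cell_size = cube$cell_size, slot_minutes = cube$slot_minutes,
         t_axis = cube$t_axis, scale = cube$scale, cutoff = cube$cutoff),
    file.path(dir, "cube.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cube
#' @export
read_cube <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "cube.json"),
                             simplifyVector = TRUE)
  layers <- lapply(man$t_axis, function(t0) {
    read_layer(file.path(dir, sprintf("layer_%04d", t0)))$grid
  })
  geom <- read_layer(file.path(dir, sprintf("layer_%04d", man$t_axis[1])))$geom
  new_context_cube(layers, man$t_axis, man$slot_minutes, man$day_type,
                   man$method, man$cell_size, man$scale, geom, man$cutoff)
}
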