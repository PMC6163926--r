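#' Distance-decay weight of an outlet at a given distance
#'
#' Three decay families describe how an outlet's influence attenuates with
#' planar Euclidean distance `d`:
#'
#' * `KD` — quartic (biweight) kernel, `3/(pi h^2) * (1 - (d/h)^2)^2` for
#'   `d < h`, else 0. Each outlet's surface integrates to 1 over the plane;
#'   `scale` is the bandwidth `h` (support radius, metres).
#' * `ISDD` — bounded inverse-square, `1 / (1 + (d/d0)^2)`. Value 1 at the
#'   outlet, 1/2 at `d0`, and `~ (d0/d)^2` for `d >> d0`, avoiding the
#'   `1/d^2` singularity at the outlet itself.
#' * `NEDD` — negative exponential, `exp(-d/d0)`; `d0` is the e-folding
#'   distance.
#'
#' @param method `"KD"`, `"ISDD"` or `"NEDD"`.
#' @param distance Non-negative distance(s) in metres.
#' @param scale The method's scale parameter in metres (`h` for KD, `d0`
#'   otherwise); must be positive.
#' @return Numeric weight(s), non-negative and non-increasing in distance.
#' @examples
#' decay_value("NEDD", 500, 500)   # exp(-1)
#' decay_value("ISDD", 100, 100)   # 0.5
#' decay_value("KD", 1200, 1000)   # 0 beyond the kernel support
#' @export
decay_value <- function(method, distance, scale) {
  method <- match.arg(method, c("KD", "ISDD", "NEDD"))
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale <= 0) {
    stop("decay scale parameter must be a positive number", call. = FALSE)
  }
  if (any(distance < 0)) stop("distance must be non-negative", call. = FALSE)
  switch(method,
         KD = {
           u <- distance / scale
           ifelse(u < 1, 3 / (pi * scale^2) * (1 - u^2)^2, 0)
         },
         ISDD = 1 / (1 + (distance / scale)^2),
         NEDD = exp(-distance / scale))
}

decay_scale <- function(config, method) {
  switch(method,
         KD = config$decay_params$kd_bandwidth,
         ISDD = config$decay_params$isdd_d0,
         NEDD = config$decay_params$nedd_d0)
}

#' Outlets open at a given day type and minute of day
#'
#' An outlet is open at minute `t` of day type `d` when `t` lies in
#' `[open, close)` of its `d` schedule. Overnight schedules (`close < open`)
#' wrap: they cover `[open, 1440)` on their own day type and `[0, close)`
#' on the following day type (weekday follows weekday, saturday follows
#' weekday, sunday follows saturday).
#'
#' @param registry An `outlet_registry` tibble (see [read_outlets()]).
#' @param day_type `"weekday"`, `"saturday"` or `"sunday"`.
#' @param slot_start Minute of day in `[0, 1440)`.
#' @return The subset of `registry` rows open at that instant.
#' @export
open_outlets <- function(registry, day_type, slot_start) {
  day_type <- match.arg(day_type, c("weekday", "saturday", "sunday"))
  stopifnot(slot_start >= 0, slot_start < 1440)
  prev <- c(weekday = "weekday", saturday = "weekday", sunday = "saturday")
  o <- registry[[paste0("open_", day_type)]]
  cl <- registry[[paste0("close_", day_type)]]
  own <- !is.na(o) & !is.na(cl) &
    ifelse(cl >= o, slot_start >= o & slot_start < cl, slot_start >= o)
  op <- registry[[paste0("open_", prev[[day_type]])]]
  cp <- registry[[paste0("close_", prev[[day_type]])]]
  spill <- !is.na(op) & !is.na(cp) & cp < op & slot_start < cp
  registry[own | spill, , drop = FALSE]
}

#' Build one time-slice food-environment layer
#'
#' Evaluates, at every grid-cell centroid, the sum of distance-decayed
#' influences of all outlets open at `slot_start` on the given day type.
#' Cells are laid out from the south-west corner of the configured extent;
#' values below `cutoff` are set to exactly 0 to keep rasters sparse.
#'
#' @inheritParams open_outlets
#' @param method,cell_size Decay method and cell size (metres) for this layer.
#' @param config A [study_config()] fixing the extent and decay parameters.
#' @param cutoff Values strictly below this are zeroed (default `1e-9`).
#' @return An object of class `env_layer`: list with `grid` (numeric matrix,
#'   rows = south-to-north cell rows, columns = west-to-east), `day_type`,
#'   `slot_start`, `method`, `cell_size`, `scale`, `geom`, `cutoff`.
#' @export
build_layer <- function(registry, day_type, slot_start, method, cell_size,
                        config, cutoff = 1e-9) {
  method <- match.arg(method, c("KD", "ISDD", "NEDD"))
  geom <- grid_geometry(config, cell_size)
  open <- open_outlets(registry, day_type, slot_start)
  scale <- decay_scale(config, method)
  grid <- matrix(0, nrow = geom$ny, ncol = geom$nx)
  if (nrow(open) > 0) {
    cx <- centroid_x(geom); cy <- centroid_y(geom)
    for (k in seq_len(nrow(open))) {
      dx2 <- (cx - open$x[k])^2
      dy2 <- (cy - open$y[k])^2
      d <- sqrt(outer(dy2, dx2, `+`))
      grid <- grid + decay_value(method, d, scale)
    }
  }
  grid[grid < cutoff] <- 0
  structure(list(grid = grid, day_type = day_type,
                 slot_start = as.numeric(slot_start),
                 method = method, cell_size = cell_size, scale = scale,
                 geom = geom, cutoff = cutoff),
            class = "env_layer")
}

#' @export
print.env_layer <- function(x, ...) {
  cat("<env_layer>", x$method, "|", x$day_type, "|",
      sprintf("slot %02d:%02d", x$slot_start %/% 60, round(x$slot_start) %% 60),
      "|", x$geom$ny, "x", x$geom$nx, "cells @", x$cell_size, "m\n")
  invisible(x)
}

#' Tidy a layer into a long tibble
#'
#' @param x An `env_layer`.
#' @param ... Unused.
#' @return A tibble with cell centroid coordinates and values
#'   (`x`, `y`, `value`, plus the layer's identity columns).
#' @export
tidy.env_layer <- function(x, ...) {
  cx <- centroid_x(x$geom); cy <- centroid_y(x$geom)
  tibble::tibble(
    x = rep(cx, each = x$geom$ny),
    y = rep(cy, times = x$geom$nx),
    value = as.vector(x$grid),
    day_type = x$day_type, slot_start = x$slot_start,
    method = x$method, cell_size = x$cell_size
  )
}

#' @export
autoplot.env_layer <- function(object, ...) {
  df <- tidy.env_layer(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "context") +
    ggplot2::labs(
      title = sprintf("%s layer, %s %02d:%02d", object$method, object$day_type,
                      object$slot_start %/% 60, round(object$slot_start) %% 60),
      x = "x (m)", y = "y (m)")
}
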