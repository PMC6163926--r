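#' GPS trajectory buffer (GTB)
#'
#' The 2-D planar buffer of radius `radius` around the participant's
#' valid-day GPS polyline. Unimputed gaps (> 1 h) break the polyline; each
#' contiguous run is buffered and the union taken. The buffer is represented
#' as the union of discs around a densified point set along the polyline
#' (spacing `radius / 10`, which bounds the boundary error by
#' `spacing^2 / (8 radius)`, about 0.13 m at the 100 m default); its area is
#' evaluated by an exact-in-x scanline quadrature at vertical step
#' `area_step` (default `radius / 10`, which still resolves disc and
#' stadium areas to about 0.1% because the x-direction is exact).
#'
#' @param traj A screened trajectory tibble for one participant (or pass
#'   `participant_id`).
#' @param radius Buffer radius in metres (default 100).
#' @param participant_id Participant to delineate (defaults to the only one
#'   present).
#' @param area_step Scanline step for the area quadrature, metres.
#' @return An `exposure_space` object (kind `"GTB"`).
#' @export
gtb <- function(traj, radius = 100, participant_id = NULL, area_step = NULL) {
  runs <- valid_runs(traj, participant_id)
  pts <- dplyr::bind_rows(runs)
  if (nrow(pts) < 2) stop("GTB needs at least two GPS points", call. = FALSE)
  centers <- densify_runs(runs, spacing = radius / 10)
  if (is.null(area_step)) area_step <- radius / 10
  area <- disc_union_area(centers$x, centers$y, radius, step = area_step)
  new_exposure_space("GTB", attr(runs, "participant_id"), area,
                     centers = centers, radius = radius)
}

#' Minimum convex polygon (MCP)
#'
#' The smallest convex polygon containing every valid-day GPS point.
#'
#' @inheritParams gtb
#' @return An `exposure_space` object (kind `"MCP"`).
#' @export
mcp <- function(traj, participant_id = NULL) {
  runs <- valid_runs(traj, participant_id)
  pts <- dplyr::bind_rows(runs)
  if (nrow(pts) < 3) stop("MCP needs at least three GPS points", call. = FALSE)
  hull_idx <- grDevices::chull(pts$x, pts$y)
  if (length(hull_idx) < 3) {
    stop("GPS points are collinear; the minimum convex polygon is degenerate",
         call. = FALSE)
  }
  hx <- pts$x[hull_idx]; hy <- pts$y[hull_idx]
  area <- shoelace_area(hx, hy)
  if (area <= 0) stop("degenerate (zero-area) convex hull", call. = FALSE)
  new_exposure_space("MCP", attr(runs, "participant_id"), area,
                     hull = cbind(x = hx, y = hy))
}

#' Standard deviational ellipse (SDE)
#'
#' The classic directional-distribution ellipse of the valid-day GPS
#' points: centred on the mean centre, axes along the eigenvectors of the
#' sample (n - 1) covariance matrix, semi-axis lengths `k_sd` times the
#' standard deviations of the coordinates projected on those axes (the
#' Yuill rotation). `k_sd = 2` therefore scales both axes — and quadruples
#' the area — relative to `k_sd = 1`.
#'
#' @inheritParams gtb
#' @param k_sd 1 or 2 standard deviations.
#' @return An `exposure_space` object (kind `"SDE1"` or `"SDE2"`).
#' @export
sde <- function(traj, k_sd = 1, participant_id = NULL) {
  stopifnot(k_sd %in% c(1, 2))
  runs <- valid_runs(traj, participant_id)
  pts <- dplyr::bind_rows(runs)
  if (nrow(pts) < 3) stop("SDE needs at least three GPS points", call. = FALSE)
  cov <- stats::cov(cbind(pts$x, pts$y))
  eg <- eigen(cov, symmetric = TRUE)
  if (min(eg$values) <= 1e-12) {
    stop("zero variance along one axis; the deviational ellipse is degenerate",
         call. = FALSE)
  }
  theta <- atan2(eg$vectors[2, 1], eg$vectors[1, 1]) %% pi
  a <- k_sd * sqrt(eg$values[1])
  b <- k_sd * sqrt(eg$values[2])
  new_exposure_space(paste0("SDE", k_sd), attr(runs, "participant_id"),
                     pi * a * b,
                     center = c(mean(pts$x), mean(pts$y)),
                     theta = theta, semi_major = a, semi_minor = b)
}

new_exposure_space <- function(kind, participant_id, area_m2, ...) {
  structure(c(list(kind = kind, participant_id = participant_id,
                   area_m2 = area_m2), list(...)),
            class = "exposure_space")
}

#' @export
print.exposure_space <- function(x, ...) {
  cat("<exposure_space>", x$kind, "|", x$participant_id %||% "?",
      "| area", format(round(x$area_m2)), "m2\n")
  invisible(x)
}

#' Point-membership test for an exposure space
#'
#' Boundary points count as inside (closed-region convention).
#'
#' @param space An `exposure_space`.
#' @param x,y Point coordinates (vectorised), metres.
#' @return Logical vector.
#' @export
space_contains <- function(space, x, y) {
  tol <- 1e-9
  switch(space$kind,
         GTB = {
           d2 <- min_dist2_to_points(x, y, space$centers$x, space$centers$y)
           d2 <= space$radius^2 + tol
         },
         MCP = point_in_convex(x, y, space$hull),
         SDE1 = ,
         SDE2 = {
           u <- (x - space$center[1]) * cos(space$theta) +
             (y - space$center[2]) * sin(space$theta)
           v <- -(x - space$center[1]) * sin(space$theta) +
             (y - space$center[2]) * cos(space$theta)
           (u / space$semi_major)^2 + (v / space$semi_minor)^2 <= 1 + 1e-9
         },
         stop("unknown exposure-space kind ", space$kind, call. = FALSE))
}

#' Outline polygon of an exposure space
#'
#' @param space An `exposure_space` of kind MCP, SDE1 or SDE2 (GTB has no
#'   single-polygon outline; export its spine instead).
#' @param n Vertex count for ellipse approximation (default 256).
#' @return A tibble of `x`, `y` vertices (closed implicitly).
#' @export
as_polygon <- function(space, n = 256) {
  switch(space$kind,
         MCP = tibble::as_tibble(as.data.frame(space$hull)),
         SDE1 = ,
         SDE2 = {
           ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
           u <- space$semi_major * cos(ang); v <- space$semi_minor * sin(ang)
           tibble::tibble(
             x = space$center[1] + u * cos(space$theta) - v * sin(space$theta),
             y = space$center[2] + u * sin(space$theta) + v * cos(space$theta))
         },
         stop("no polygon outline for kind ", space$kind, call. = FALSE))
}

#' Outlet density of an exposure space
#'
#' The static comparator exposure: outlets inside or on the boundary of the
#' delineation, per square kilometre. Business hours are deliberately
#' ignored — that temporal blindness is what the dynamic framework is
#' contrasted against.
#'
#' @param space An `exposure_space`.
#' @param registry An `outlet_registry`.
#' @return Outlets per km2.
#' @export
outlet_density <- function(space, registry) {
  if (space$area_m2 <= 0) stop("exposure space has zero area", call. = FALSE)
  n_in <- sum(space_contains(space, registry$x, registry$y))
  n_in / (space$area_m2 / 1e6)
}

#' Cohort activity-space exposures
#'
#' Delineates the requested activity spaces for every participant in a
#' screened trajectory table and scores each as outlet density, z-scored
#' across the cohort per kind.
#'
#' @param traj A screened trajectory tibble.
#' @param registry An `outlet_registry`.
#' @param kinds Subset of `c("GTB", "MCP", "SDE1", "SDE2")`.
#' @param radius GTB radius in metres.
#' @param area_step GTB scanline step (see [gtb()]).
#' @return A tibble: `participant_id`, `method_key` (the kind),
#'   `density_raw` (outlets per km2), `density_z`, `area_km2`.
#' @export
activity_space_exposures <- function(traj, registry,
                                     kinds = c("GTB", "MCP", "SDE1", "SDE2"),
                                     radius = 100, area_step = NULL) {
  kinds <- match.arg(kinds, c("GTB", "MCP", "SDE1", "SDE2"), several.ok = TRUE)
  if (!"valid_day" %in% names(traj)) traj <- flag_valid_days(traj)
  rows <- list()
  # one pass per participant: the valid-day runs are shared by all kinds
  for (sub in split(tibble::as_tibble(traj), traj$participant_id)) {
    id <- sub$participant_id[1]
    for (kind in kinds) {
      sp <- switch(kind,
                   GTB = gtb(sub, radius, id, area_step = area_step),
                   MCP = mcp(sub, id),
                   SDE1 = sde(sub, 1, id),
                   SDE2 = sde(sub, 2, id))
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = id, method_key = kind,
        density_raw = outlet_density(sp, registry),
        area_km2 = sp$area_m2 / 1e6)
    }
  }
  out <- dplyr::bind_rows(rows)
  standardize_exposures(out, value_col = "density_raw")
}

# ---- internal geometry ---------------------------------------------------

# Contiguous valid-day runs of one participant's records (list of tibbles
# with x, y), polyline-break at unimputed gaps and day boundaries.
valid_runs <- function(traj, participant_id = NULL) {
  traj <- tibble::as_tibble(traj)
  if (is.null(participant_id)) {
    participant_id <- unique(traj$participant_id)
    stopifnot(length(participant_id) == 1)
  }
  if (!"valid_day" %in% names(traj)) traj <- flag_valid_days(traj)
  recs <- traj[traj$participant_id == participant_id & traj$valid_day, ,
               drop = FALSE]
  recs <- recs[order(recs$time), , drop = FALSE]
  if (nrow(recs) == 0) {
    out <- list()
  } else {
    mins <- as.numeric(recs$time) / 60
    run <- cumsum(c(1, diff(mins) > 1 + 1e-9))
    out <- lapply(split(seq_len(nrow(recs)), run), function(ix) {
      tibble::tibble(x = recs$x[ix], y = recs$y[ix])
    })
  }
  attr(out, "participant_id") <- participant_id
  out
}

# Points along each run's polyline at most `spacing` apart (vertices kept).
densify_runs <- function(runs, spacing) {
  parts <- lapply(runs, function(r) {
    n <- nrow(r)
    if (n == 1) return(r)
    dx <- diff(r$x); dy <- diff(r$y)
    m <- pmax(1, ceiling(sqrt(dx^2 + dy^2) / spacing))
    seg <- rep(seq_len(n - 1), m)
    f <- (sequence(m) - 1) / rep(m, m)
    tibble::tibble(x = c(r$x[seg] + f * dx[seg], r$x[n]),
                   y = c(r$y[seg] + f * dy[seg], r$y[n]))
  })
  dplyr::bind_rows(parts)
}

# Area of the union of equal-radius discs by scanline quadrature: exact
# interval unions in x, midpoint rule at step `step` in y.
disc_union_area <- function(cx, cy, r, step) {
  ylo <- min(cy) - r; yhi <- max(cy) + r
  lines <- seq(ylo + step / 2, yhi, by = step)
  ord <- order(cy)
  cx <- cx[ord]; cy <- cy[ord]
  lo_idx <- findInterval(lines - r, cy) + 1
  hi_idx <- findInterval(lines + r, cy)
  reps <- pmax(0, hi_idx - lo_idx + 1)
  line_id <- rep(seq_along(lines), reps)
  nz <- reps > 0
  cidx <- sequence(reps[nz], from = lo_idx[nz])
  dy <- lines[line_id] - cy[cidx]
  half <- sqrt(pmax(0, r^2 - dy^2))
  keep <- half > 0
  if (!any(keep)) return(0)
  s <- cx[cidx[keep]] - half[keep]
  e <- cx[cidx[keep]] + half[keep]
  g <- line_id[keep]
  o <- order(g, s)
  s <- s[o]; e <- e[o]; g <- g[o]
  big <- (max(e) - min(s)) + 2 * r + 1
  # grouped running max of interval ends: adding big*g makes every earlier
  # scanline's entries strictly smaller, so cummax never crosses groups
  cm <- cummax(e + big * g) - big * g
  lag_cm <- c(-Inf, cm[-length(cm)])
  lag_cm[c(TRUE, diff(g) != 0)] <- -Inf        # reset at each scanline
  covered <- pmax(0, e - pmax(s, lag_cm))
  sum(covered) * step
}

shoelace_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Closed convex-polygon membership: the point is inside when it is on the
# inner side of (or on) every edge. Accepts either vertex orientation.
point_in_convex <- function(px, py, hull) {
  n <- nrow(hull)
  signed2 <- sum(hull[, 1] * hull[c(2:n, 1), 2] -
                   hull[c(2:n, 1), 1] * hull[, 2])
  if (signed2 > 0) hull <- hull[n:1, , drop = FALSE]   # force clockwise
  scale <- max(abs(hull)) + 1
  inside <- rep(TRUE, length(px))
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    cr <- (hull[k2, 1] - hull[k, 1]) * (py - hull[k, 2]) -
      (hull[k2, 2] - hull[k, 2]) * (px - hull[k, 1])
    inside <- inside & (cr <= 1e-9 * scale^2)
  }
  inside
}

min_dist2_to_points <- function(px, py, cx, cy) {
  vapply(seq_along(px),
         function(k) min((cx - px[k])^2 + (cy - py[k])^2),
         numeric(1))
}
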