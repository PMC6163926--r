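#' Build an individual space-time tunnel
#'
#' The tunnel (ISTT) is the 3-D region swept by a horizontal disc of radius
#' `br` centred on the participant's time-interpolated position, over every
#' instant of the valid days of one day type. Instants that fall inside
#' unimputed gaps (> 1 h) are not covered — the tunnel has temporal holes
#' there. The disc is purely horizontal: metres and minutes are never mixed
#' in one metric, matching the sweep reading of the 3-D buffer.
#'
#' @param traj A screened trajectory tibble ([flag_valid_days()] /
#'   [select_participants()]) for (at least) one participant.
#' @param participant_id Which participant to build the tunnel for (defaults
#'   to the only one present).
#' @param day_type `"weekday"`, `"saturday"` or `"sunday"`.
#' @param br Buffer radius in metres (> 0); the framework default is 100 m.
#' @return An object of class `space_time_tunnel`: list with
#'   `participant_id`, `day_type`, `br`, and `days` — a list (named by date)
#'   of per-day tibbles `minute`, `x`, `y`, `velocity` for every non-missing
#'   minute of that valid day.
#' @export
build_tunnel <- function(traj, day_type, br = 100, participant_id = NULL) {
  stopifnot(br > 0)
  day_type <- match.arg(day_type, c("weekday", "saturday", "sunday"))
  traj <- tibble::as_tibble(traj)
  if (is.null(participant_id)) {
    participant_id <- unique(traj$participant_id)
    stopifnot(length(participant_id) == 1)
  }
  if (!"valid_day" %in% names(traj)) traj <- flag_valid_days(traj)
  sel <- traj$participant_id == participant_id & traj$valid_day &
    traj$day_type == day_type
  recs <- traj[sel, , drop = FALSE]
  if (nrow(recs) == 0) {
    warning("participant ", participant_id, " has no valid ", day_type,
            " days; tunnel is empty", call. = FALSE)
    days <- list()
  } else {
    recs$minute <- as.numeric(recs$time - as.POSIXct(recs$date, tz = "UTC"),
                              units = "mins")
    days <- lapply(split(recs, as.character(recs$date)), function(d) {
      tibble::tibble(minute = d$minute, x = d$x, y = d$y,
                     velocity = d$velocity)
    })
  }
  structure(list(participant_id = participant_id, day_type = day_type,
                 br = as.numeric(br), days = days),
            class = "space_time_tunnel")
}

#' @export
print.space_time_tunnel <- function(x, ...) {
  cat("<space_time_tunnel>", x$participant_id, "|", x$day_type, "|",
      length(x$days), "valid day(s) | Br =", x$br, "m\n")
  invisible(x)
}

# Interpolated positions (and segment velocities) of one tunnel day at
# arbitrary minute-of-day times. Positions exist only inside contiguous
# 1-min runs; times inside unimputed gaps get ok = FALSE.
positions_at <- function(day_tab, times) {
  m <- day_tab$minute
  n <- length(times)
  px <- rep(NA_real_, n); py <- rep(NA_real_, n); vel <- rep(NA_real_, n)
  if (length(m) == 0) return(list(x = px, y = py, velocity = vel, ok = !is.na(px)))
  run <- cumsum(c(1, diff(m) > 1 + 1e-9))
  for (r in unique(run)) {
    ix <- which(run == r)
    lo <- m[ix[1]]; hi <- m[ix[length(ix)]]
    inside <- which(times >= lo & times <= hi)
    if (length(inside) == 0) next
    if (length(ix) == 1) {
      px[inside] <- day_tab$x[ix]; py[inside] <- day_tab$y[ix]
      vel[inside] <- day_tab$velocity[ix]
    } else {
      px[inside] <- stats::approx(m[ix], day_tab$x[ix], xout = times[inside])$y
      py[inside] <- stats::approx(m[ix], day_tab$y[ix], xout = times[inside])$y
      # the velocity of the segment containing t is stored on its later record
      vel[inside] <- stats::approx(m[ix], day_tab$velocity[ix],
                                   xout = times[inside],
                                   method = "constant", f = 1)$y
    }
  }
  list(x = px, y = py, velocity = vel, ok = !is.na(px))
}

#' Intersect a tunnel with a cube point cloud
#'
#' A cloud point (x, y, t) is intersected when, on a valid day of the
#' tunnel's day type, the participant has a position at time t (linear
#' interpolation between the bracketing 1-min fixes) whose planar distance
#' to (x, y) is at most `br`. A point revisited on several valid days is
#' counted once per day — repeat exposure accumulates.
#'
#' @param tunnel A [build_tunnel()] object.
#' @param cloud A [to_point_cloud()] tibble of matching day type.
#' @param weight_mode `"constant"` or `"velocity"` (see [point_weight()]).
#' @return A tibble of intersection points: `day`, `x`, `y`, `t`, `value`,
#'   `velocity`, `weight`.
#' @export
intersect_tunnel <- function(tunnel, cloud, weight_mode = "constant") {
  stopifnot(inherits(tunnel, "space_time_tunnel"))
  dt_cloud <- attr(cloud, "day_type")
  if (!is.null(dt_cloud) && dt_cloud != tunnel$day_type) {
    stop("tunnel day type (", tunnel$day_type, ") does not match cloud (",
         dt_cloud, ")", call. = FALSE)
  }
  times <- sort(unique(cloud$t))
  t_idx <- match(cloud$t, times)
  out <- vector("list", length(tunnel$days))
  for (k in seq_along(tunnel$days)) {
    pos <- positions_at(tunnel$days[[k]], times)
    px <- pos$x[t_idx]; py <- pos$y[t_idx]
    hit <- pos$ok[t_idx] &
      (cloud$x - px)^2 + (cloud$y - py)^2 <= tunnel$br^2 + 1e-9
    hit[is.na(hit)] <- FALSE
    if (!any(hit)) next
    out[[k]] <- tibble::tibble(
      day = names(tunnel$days)[k],
      x = cloud$x[hit], y = cloud$y[hit], t = cloud$t[hit],
      value = cloud$value[hit],
      velocity = pos$velocity[t_idx][hit])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(day = character(0), x = numeric(0), y = numeric(0),
                          t = numeric(0), value = numeric(0),
                          velocity = numeric(0))
  }
  res$weight <- point_weight(res$velocity, weight_mode)
  res
}

#' Point weight from movement velocity
#'
#' In constant mode every intersected point weighs 1 (the reference
#' analysis setting). In velocity mode a point passed at velocity `v`
#' (m/min) weighs `(1/2)^v`, so a stationary subject (`v = 0`) weighs 1 and
#' faster passage geometrically discounts the exposure.
#'
#' @param velocity Non-negative velocity (m/min); vectorised.
#' @param mode `"constant"` or `"velocity"`.
#' @return Weights in (0, 1].
#' @examples
#' point_weight(c(0, 1, 2), "velocity")  # 1, 0.5, 0.25
#' @export
point_weight <- function(velocity, mode = c("constant", "velocity")) {
  mode <- match.arg(mode)
  if (any(velocity < 0, na.rm = TRUE)) {
    stop("velocity must be non-negative", call. = FALSE)
  }
  if (mode == "constant") return(rep(1, length(velocity)))
  ifelse(velocity == 0, 1, 0.5^velocity)
}

#' Environmental context exposure index from intersection points
#'
#' `ECEI = sum(value_i * weight_i) / T`: the weighted sum of intersected
#' cube values per unit observation time.
#'
#' @param points An [intersect_tunnel()] tibble (columns `value`, `weight`).
#' @param t_hours Observation time T in hours (> 0).
#' @return The raw ECEI (exposure per observed hour).
#' @export
ecei <- function(points, t_hours) {
  if (!is.numeric(t_hours) || length(t_hours) != 1 || is.na(t_hours) ||
        t_hours <= 0) {
    stop("t_hours must be a positive number", call. = FALSE)
  }
  if (nrow(points) == 0) return(0)
  sum(points$value * points$weight) / t_hours
}

#' Z-score exposures across the cohort
#'
#' Standardises a long exposure table within each method key using the
#' sample standard deviation, so exposures measured on different decay
#' scales become comparable.
#'
#' @param records A tibble with `participant_id`, `method_key` and a raw
#'   value column.
#' @param value_col Name of the raw column (default `"ecei_raw"`).
#' @return `records` with an added `<value_col minus _raw>_z` column
#'   (`ecei_z` for the default). Keys with zero variance get all-zero
#'   z-scores with a warning.
#' @export
standardize_exposures <- function(records, value_col = "ecei_raw") {
  z_col <- sub("_raw$", "_z", value_col)
  if (z_col == value_col) z_col <- paste0(value_col, "_z")
  grp <- dplyr::group_by(records, .data$method_key)
  if (any(dplyr::summarise(grp, n = dplyr::n())$n < 2)) {
    stop("z-scoring needs at least two participants per method key",
         call. = FALSE)
  }
  sds <- dplyr::summarise(grp, sd = stats::sd(.data[[value_col]]),
                          .groups = "drop")
  if (any(sds$sd == 0 | is.na(sds$sd))) {
    warning("method key(s) with zero exposure variance; z-scores set to 0: ",
            paste(sds$method_key[sds$sd == 0 | is.na(sds$sd)], collapse = ", "),
            call. = FALSE)
  }
  out <- dplyr::mutate(
    grp,
    !!z_col := {
      s <- stats::sd(.data[[value_col]])
      if (is.na(s) || s == 0) rep(0, dplyr::n())
      else (.data[[value_col]] - mean(.data[[value_col]])) / s
    })
  dplyr::ungroup(out)
}

#' Compute cohort ECEI exposures for a cube menu
#'
#' For every participant and every (method, cell size, temporal resolution)
#' key, intersects the participant's day-type tunnels with the matching
#' day-type cubes, evaluates `ECEI = sum(value * weight) / T` per day type,
#' and combines day types by a valid-day-weighted mean. By default T is the
#' participant's total valid observation time (hours) on days of that day
#' type; `t_mode = "span"` instead uses the time span of the intersected
#' points.
#'
#' @param traj A screened trajectory tibble.
#' @param cubes A cube menu from [enumerate_cubes()].
#' @param br Tunnel radius in metres.
#' @param weight_mode `"constant"` or `"velocity"`.
#' @param t_mode `"observed"` (default) or `"span"`.
#' @return A tibble: `participant_id`, `method_key`, `ecei_raw`, `ecei_z`,
#'   `n_points`, `t_hours`.
#' @export
compute_ecei <- function(traj, cubes, br = 100, weight_mode = "constant",
                         t_mode = c("observed", "span")) {
  t_mode <- match.arg(t_mode)
  if (!"valid_day" %in% names(traj)) traj <- flag_valid_days(traj)
  ds <- day_summaries(traj)
  ids <- unique(traj$participant_id)
  keys <- unique(cubes$method_key)
  dts <- c("weekday", "saturday", "sunday")

  # dense voxel arrays, one per cube row
  arrays <- lapply(cubes$cube, function(cb) {
    array(unlist(cb$layers, use.names = FALSE),
          dim = c(cb$geom$ny, cb$geom$nx, length(cb$layers)))
  })
  geoms <- lapply(cubes$cube, `[[`, "geom")
  mids <- lapply(cubes$cube, function(cb) cb$t_axis + cb$slot_minutes / 2)
  # cube rows grouped by (day_type, cell_size, slot_minutes): the candidate
  # geometry (interpolated positions, voxel windows) is shared within a group
  grp_key <- paste(cubes$day_type, cubes$cell_size, cubes$slot_minutes)
  groups <- split(seq_len(nrow(cubes)), grp_key)

  acc_dim <- c(length(ids), length(keys), length(dts))
  S <- array(0, acc_dim); NP <- array(0L, acc_dim)
  TLO <- array(Inf, acc_dim); THI <- array(-Inf, acc_dim)

  valid <- traj[traj$valid_day, , drop = FALSE]
  valid$minute <- as.numeric(valid$time -
                               as.POSIXct(valid$date, tz = "UTC"),
                             units = "mins")
  by_id <- split(valid, valid$participant_id)
  for (id_i in seq_along(ids)) {
    pdat <- by_id[[ids[id_i]]]
    if (is.null(pdat)) next
    for (day_df in split(pdat, as.character(pdat$date))) {
      dt_i <- match(day_df$day_type[1], dts)
      slot_pos <- list()  # interpolated positions per slot length
      for (g in groups) {
        g1 <- cubes$cube[[g[1]]]
        if (g1$day_type != dts[dt_i]) next
        sl <- as.character(g1$slot_minutes)
        if (is.null(slot_pos[[sl]])) {
          slot_pos[[sl]] <- positions_at(day_df, mids[[g[1]]])
        }
        cand <- window_candidates(slot_pos[[sl]], geoms[[g[1]]], br)
        if (cand$n == 0) next
        w <- point_weight(cand$velocity, weight_mode)
        tl <- min(mids[[g[1]]][cand$l]); th <- max(mids[[g[1]]][cand$l])
        lookup <- cbind(cand$i, cand$j, cand$l)
        for (r in g) {
          key_i <- match(cubes$method_key[r], keys)
          S[id_i, key_i, dt_i] <- S[id_i, key_i, dt_i] +
            sum(arrays[[r]][lookup] * w)
          NP[id_i, key_i, dt_i] <- NP[id_i, key_i, dt_i] + cand$n
          TLO[id_i, key_i, dt_i] <- min(TLO[id_i, key_i, dt_i], tl)
          THI[id_i, key_i, dt_i] <- max(THI[id_i, key_i, dt_i], th)
        }
      }
    }
  }

  contrib <- tibble::tibble(
    participant_id = rep(ids, times = length(keys) * length(dts)),
    method_key = rep(rep(keys, each = length(ids)), times = length(dts)),
    day_type = rep(dts, each = length(ids) * length(keys)),
    s = as.vector(S), n_points = as.vector(NP),
    t_lo = as.vector(TLO), t_hi = as.vector(THI))
  contrib <- contrib[contrib$n_points > 0, , drop = FALSE]

  # observation time per (participant, day_type)
  obs <- dplyr::summarise(
    dplyr::group_by(ds[ds$is_valid_day, , drop = FALSE],
                    .data$participant_id, .data$day_type),
    t_hours = sum(.data$valid_minutes) / 60,
    n_days = dplyr::n(), .groups = "drop")

  frame <- tidyr::expand_grid(participant_id = ids, method_key = keys)
  by_dt <- dplyr::mutate(contrib,
                         t_span = (.data$t_hi - .data$t_lo) / 60)
  by_dt <- dplyr::left_join(by_dt, obs, by = c("participant_id", "day_type"))
  if (t_mode == "span" && nrow(by_dt) > 0) {
    by_dt$t_hours <- pmax(by_dt$t_span, 1 / 60)
  }
  # day types with zero intersection still contribute 0 exposure over their
  # observed time; complete against the full observed grid
  full <- tidyr::expand_grid(frame, day_type = unique(obs$day_type))
  full <- dplyr::inner_join(full, obs, by = c("participant_id", "day_type"))
  full <- dplyr::left_join(
    full, dplyr::select(by_dt, "participant_id", "method_key", "day_type",
                        "s", "n_points", t_hours_int = "t_hours"),
    by = c("participant_id", "method_key", "day_type"))
  full$s[is.na(full$s)] <- 0
  full$n_points[is.na(full$n_points)] <- 0L
  if (t_mode == "span") {
    full$t_hours <- ifelse(is.na(full$t_hours_int), full$t_hours,
                           full$t_hours_int)
  }
  full$ecei_dt <- full$s / full$t_hours
  agg <- dplyr::summarise(
    dplyr::group_by(full, .data$participant_id, .data$method_key),
    ecei_raw = stats::weighted.mean(.data$ecei_dt, .data$n_days),
    n_points = sum(.data$n_points),
    t_hours = sum(.data$t_hours), .groups = "drop")
  standardize_exposures(agg)
}

# Candidate voxel indices within br of the interpolated position, per cloud
# time. Internal fast path; must agree with intersect_tunnel() exactly.
# `pos` is a positions_at() result evaluated at the cube's slot midpoints.
window_candidates <- function(pos, geom, br) {
  ok <- which(pos$ok)
  if (length(ok) == 0) {
    return(list(i = integer(0), j = integer(0), l = integer(0),
                velocity = numeric(0), n = 0L))
  }
  wr <- ceiling(br / geom$cell_size) + 1
  offs <- as.matrix(expand.grid(di = -wr:wr, dj = -wr:wr))
  noff <- nrow(offs)
  px <- pos$x[ok]; py <- pos$y[ok]; vel <- pos$velocity[ok]
  i0 <- floor((py - geom$ymin) / geom$cell_size) + 1
  j0 <- floor((px - geom$xmin) / geom$cell_size) + 1
  i <- rep(i0, each = noff) + rep(offs[, 1], times = length(ok))
  j <- rep(j0, each = noff) + rep(offs[, 2], times = length(ok))
  l <- rep(ok, each = noff)
  pxr <- rep(px, each = noff); pyr <- rep(py, each = noff)
  velr <- rep(vel, each = noff)
  inb <- i >= 1 & i <= geom$ny & j >= 1 & j <= geom$nx
  cx <- geom$xmin + (j - 0.5) * geom$cell_size
  cy <- geom$ymin + (i - 0.5) * geom$cell_size
  hit <- inb & (cx - pxr)^2 + (cy - pyr)^2 <= br^2 + 1e-9
  list(i = as.integer(i[hit]), j = as.integer(j[hit]),
       l = l[hit], velocity = velr[hit], n = sum(hit))
}
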