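#' Read an outlet registry
#'
#' Reads point features ("food outlets") with a category and day-type-specific
#' operating hours from delimited text or GeoJSON. Coordinates are brought
#' into the configured planar CRS (metres); schedules are parsed into
#' minute-of-day intervals.
#'
#' The schedule schema has six columns, `weekday_open`, `weekday_close`,
#' `saturday_open`, `saturday_close`, `sunday_open`, `sunday_close`, each
#' `"HH:MM"` or one of the sentinels `"24h"` (open all day, in either column)
#' and `"closed"` (closed that day type). `open == close` is interpreted as
#' closed that day type, with a warning. Overnight hours (`close < open`,
#' e.g. 18:00-02:00) wrap past midnight: the outlet is open `[open, 1440)`
#' on its own day type and `[0, close)` on the following day type.
#'
#' @param path Path to a `.csv`/`.tsv` file (columns `id`, `x`, `y` or
#'   `lon`, `lat`, `category`, and the six schedule columns) or a `.geojson`
#'   file (Point features with the same properties).
#' @param config A [study_config()]. When `config$crs == "lonlat"` input
#'   coordinates are longitude/latitude and are projected to local metres.
#' @return A tibble of class `outlet_registry` with columns `outlet_id`,
#'   `x`, `y` (metres), `category`, and integer minute-of-day columns
#'   `open_weekday`, `close_weekday`, `open_saturday`, `close_saturday`,
#'   `open_sunday`, `close_sunday` (`NA` = closed all that day type;
#'   close may exceed open or wrap, see Details).
#' @seealso [write_outlets()], [open_outlets()]
#' @export
read_outlets <- function(path, config) {
  stopifnot(inherits(config, "study_config"))
  if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE)) {
    raw <- read_outlets_geojson(path)
  } else {
    raw <- readr::read_delim(path, delim = guess_delim(path),
                             show_col_types = FALSE, progress = FALSE,
                             col_types = readr::cols(.default = readr::col_character()))
  }
  required <- c("id", "category", schedule_cols())
  coord_ok <- all(c("x", "y") %in% names(raw)) || all(c("lon", "lat") %in% names(raw))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0 || !coord_ok) {
    if (!coord_ok) missing_cols <- c(missing_cols, "x/y (or lon/lat)")
    stop("outlet file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (all(c("lon", "lat") %in% names(raw)) && config$crs == "lonlat") {
    xy <- lonlat_to_local(as.numeric(raw$lon), as.numeric(raw$lat), config)
  } else if (all(c("x", "y") %in% names(raw))) {
    xy <- list(x = as.numeric(raw$x), y = as.numeric(raw$y))
  } else {
    # lon/lat columns only: treating degrees as planar metres is never
    # right, so project (this requires config$lonlat_origin)
    xy <- lonlat_to_local(as.numeric(raw$lon), as.numeric(raw$lat), config)
  }

  sched <- parse_schedules(raw)
  bad <- sched$bad_rows
  if (length(bad) > 0) {
    warning("rejecting ", length(bad), " outlet row(s) with unparseable schedules: row ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)

  out <- tibble::tibble(
    outlet_id = as.character(raw$id)[keep],
    x = xy$x[keep], y = xy$y[keep],
    category = as.character(raw$category)[keep]
  )
  out <- dplyr::bind_cols(out, sched$minutes[keep, , drop = FALSE])

  ext <- config$grid_extent
  outside <- out$x < ext[1] | out$x > ext[3] | out$y < ext[2] | out$y > ext[4]
  if (any(outside)) {
    warning(sum(outside), " outlet(s) fall outside the grid extent; ",
            "retained (they can still influence in-extent cells via decay)",
            call. = FALSE)
  }
  class(out) <- c("outlet_registry", class(out))
  out
}

#' Write an outlet registry
#'
#' @param registry An `outlet_registry` tibble.
#' @param path Output path; `.geojson` writes GeoJSON (coordinates as
#'   longitude/latitude when `config$crs == "lonlat"`), anything else CSV
#'   with planar metre coordinates.
#' @param config The [study_config()] used to read the registry.
#' @return `path`, invisibly.
#' @export
write_outlets <- function(registry, path, config) {
  df <- tibble::as_tibble(registry)
  sched_chr <- minutes_to_schedule_chr(df)
  if (grepl("\\.geojson$|\\.json$", path, ignore.case = TRUE)) {
    if (config$crs == "lonlat") {
      ll <- local_to_lonlat(df$x, df$y, config)
      coords <- Map(c, ll$lon, ll$lat)
    } else {
      coords <- Map(c, df$x, df$y)
    }
    feats <- lapply(seq_len(nrow(df)), function(k) {
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = coords[[k]]),
           properties = c(list(id = df$outlet_id[k], category = df$category[k]),
                          as.list(sched_chr[k, ])))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    out <- tibble::tibble(id = df$outlet_id, x = df$x, y = df$y,
                          category = df$category)
    out <- dplyr::bind_cols(out, sched_chr)
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

schedule_cols <- function() {
  as.vector(outer(c("weekday", "saturday", "sunday"),
                  c("open", "close"), function(d, s) paste(d, s, sep = "_")))
}

guess_delim <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

# "HH:MM" -> minute of day; sentinels handled by caller. NA for unparseable.
parse_hhmm <- function(x) {
  m <- stringr::str_match(stringr::str_trim(x), "^([0-9]{1,2}):([0-9]{2})$")
  h <- as.integer(m[, 2]); mi <- as.integer(m[, 3])
  out <- h * 60L + mi
  out[is.na(h) | h > 24 | mi > 59 | out > 1440L] <- NA_integer_
  out
}

# Parse the six schedule columns of a raw character table into minute-of-day
# open/close pairs per day type. Returns the minutes tibble plus the indices
# of rows with unparseable schedules.
parse_schedules <- function(raw) {
  day_types <- c("weekday", "saturday", "sunday")
  n <- nrow(raw)
  minutes <- tibble::tibble(.rows = n)
  bad <- logical(n)
  degenerate <- logical(n)
  for (d in day_types) {
    oc <- stringr::str_trim(tolower(as.character(raw[[paste0(d, "_open")]])))
    cc <- stringr::str_trim(tolower(as.character(raw[[paste0(d, "_close")]])))
    open <- rep(NA_integer_, n); close <- rep(NA_integer_, n)
    all_day <- oc == "24h" | cc == "24h"
    closed <- oc == "closed" | cc == "closed"
    plain <- !all_day & !closed
    open[plain] <- parse_hhmm(oc[plain])
    close[plain] <- parse_hhmm(cc[plain])
    bad <- bad | (plain & (is.na(open) | is.na(close)) &
                    !(is.na(oc) & is.na(cc)))
    deg <- plain & !is.na(open) & !is.na(close) & open == close
    degenerate <- degenerate | deg
    open[deg] <- NA_integer_; close[deg] <- NA_integer_
    open[all_day] <- 0L; close[all_day] <- 1440L
    open[closed] <- NA_integer_; close[closed] <- NA_integer_
    minutes[[paste0("open_", d)]] <- open
    minutes[[paste0("close_", d)]] <- close
  }
  if (any(degenerate)) {
    warning("outlet row(s) with open == close treated as closed that day type: row ",
            paste(which(degenerate), collapse = ", "), call. = FALSE)
  }
  list(minutes = minutes, bad_rows = which(bad))
}

minutes_to_schedule_chr <- function(df) {
  fmt <- function(m) sprintf("%02d:%02d", m %/% 60L, m %% 60L)
  out <- tibble::tibble(.rows = nrow(df))
  for (d in c("weekday", "saturday", "sunday")) {
    o <- df[[paste0("open_", d)]]; cl <- df[[paste0("close_", d)]]
    oc <- ifelse(is.na(o), "closed", ifelse(o == 0L & cl == 1440L, "24h", fmt(o)))
    cc <- ifelse(is.na(cl), "closed", ifelse(o == 0L & cl == 1440L, "24h", fmt(cl %% 1440L)))
    out[[paste0(d, "_open")]] <- oc
    out[[paste0(d, "_close")]] <- cc
  }
  out
}

read_outlets_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- g$features
  props <- purrr::map(feats, "properties")
  coords <- purrr::map(feats, c("geometry", "coordinates"))
  tb <- purrr::map_dfr(props, function(p) {
    tibble::as_tibble(lapply(p, function(v) if (is.null(v)) NA_character_ else as.character(v)))
  })
  tb$lon <- purrr::map_dbl(coords, 1)
  tb$lat <- purrr::map_dbl(coords, 2)
  tb
}

# ---- local projection ---------------------------------------------------
# Spherical azimuthal equidistant projection about a study-area origin.
# At county scale (<~50 km) the distortion relative to an ellipsoidal
# projection is sub-metre, which is far below the 100 m grid resolution.

.earth_radius <- 6371008.8

lonlat_origin <- function(config) {
  if (is.null(config$lonlat_origin)) {
    stop("config$lonlat_origin (c(lon, lat)) is required when crs = \"lonlat\"",
         call. = FALSE)
  }
  config$lonlat_origin
}

lonlat_to_local <- function(lon, lat, config) {
  o <- lonlat_origin(config)
  lam <- lon * pi / 180; phi <- lat * pi / 180
  lam0 <- o[1] * pi / 180; phi0 <- o[2] * pi / 180
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- .earth_radius * k * cos(phi) * sin(lam - lam0)
  y <- .earth_radius * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  list(x = x, y = y)
}

local_to_lonlat <- function(x, y, config) {
  o <- lonlat_origin(config)
  lam0 <- o[1] * pi / 180; phi0 <- o[2] * pi / 180
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / .earth_radius
  phi <- ifelse(rho < 1e-9, phi0,
                asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / pmax(rho, 1e-12)))
  lam <- lam0 + atan2(x * sin(c_ang),
                      rho * cos(phi0) * cos(c_ang) - y * sin(phi0) * sin(c_ang))
  list(lon = lam * 180 / pi, lat = phi * 180 / pi)
}
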