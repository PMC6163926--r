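#' Read raw GPS trajectories
#'
#' Reads nominal 1-minute GPS fixes for one or more participants from
#' delimited text (columns `participant_id`, `timestamp`, `x`, `y` or
#' `lon`/`lat`) or from a GPX track file. Records are sorted by time within
#' participant, duplicate timestamps are collapsed to their first occurrence
#' with a warning, and each record is tagged with its schedule day type
#' (weekday / saturday / sunday) from the local calendar date.
#'
#' Timestamps are local civil time and are treated as timezone-naive:
#' business hours are civil-time concepts, so no UTC conversion is applied.
#'
#' @param path Path to a `.csv`/`.tsv` or `.gpx` file.
#' @param config A [study_config()]; `crs = "lonlat"` triggers projection of
#'   `lon`/`lat` columns (or GPX coordinates) to local metres.
#' @param participant_id Used for GPX input, which carries no participant
#'   column; defaults to the file name without extension.
#' @return A tibble with columns `participant_id`, `time` (POSIXct, UTC-naive
#'   local clock), `date`, `day_type`, `x`, `y`, ordered by participant and
#'   time.
#' @export
read_gps <- function(path, config, participant_id = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (grepl("\\.gpx$", path, ignore.case = TRUE)) {
    raw <- read_gpx_track(path)
    raw$participant_id <- participant_id %||%
      sub("\\.gpx$", "", basename(path), ignore.case = TRUE)
  } else {
    raw <- readr::read_delim(path, delim = guess_delim(path),
                             show_col_types = FALSE, progress = FALSE)
  }
  required <- c("participant_id", "timestamp")
  if (!"timestamp" %in% names(raw) && "time" %in% names(raw)) {
    raw$timestamp <- raw$time
  }
  missing_cols <- setdiff(required, names(raw))
  coord_ok <- all(c("x", "y") %in% names(raw)) || all(c("lon", "lat") %in% names(raw))
  if (length(missing_cols) > 0 || !coord_ok) {
    if (!coord_ok) missing_cols <- c(missing_cols, "x/y (or lon/lat)")
    stop("GPS file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (all(c("lon", "lat") %in% names(raw)) &&
      (config$crs == "lonlat" || !all(c("x", "y") %in% names(raw)))) {
    xy <- lonlat_to_local(as.numeric(raw$lon), as.numeric(raw$lat), config)
    raw$x <- xy$x; raw$y <- xy$y
  }
  tm <- raw$timestamp
  if (!inherits(tm, "POSIXct")) {
    tm <- lubridate::ymd_hms(as.character(tm), tz = "UTC", quiet = TRUE)
    if (anyNA(tm)) stop("unparseable ISO 8601 timestamps in GPS file", call. = FALSE)
  }
  gps <- tibble::tibble(participant_id = as.character(raw$participant_id),
                        time = tm,
                        x = as.numeric(raw$x), y = as.numeric(raw$y))
  as_gps_table(gps)
}

#' Normalise an in-memory GPS table
#'
#' Applies the same ordering, duplicate-collapsing and day-type tagging as
#' [read_gps()] to a data frame already holding `participant_id`, `time`,
#' `x`, `y`.
#'
#' @param gps A data frame with columns `participant_id`, `time` (POSIXct),
#'   `x`, `y`.
#' @return The normalised tibble (see [read_gps()]).
#' @export
as_gps_table <- function(gps) {
  gps <- tibble::as_tibble(gps)
  gps <- dplyr::arrange(gps, .data$participant_id, .data$time)
  n0 <- nrow(gps)
  gps <- dplyr::distinct(gps, .data$participant_id, .data$time, .keep_all = TRUE)
  if (nrow(gps) < n0) {
    warning(n0 - nrow(gps), " duplicate (participant, timestamp) record(s) ",
            "collapsed to first occurrence", call. = FALSE)
  }
  empty <- is.na(gps$x) | is.na(gps$y)
  if (any(empty)) gps <- gps[!empty, , drop = FALSE]
  counts <- dplyr::count(gps, .data$participant_id)
  if (any(counts$n == 0)) {
    warning("dropping participant(s) with no records", call. = FALSE)
  }
  gps$date <- lubridate::as_date(gps$time)
  gps$day_type <- day_type_of(gps$date)
  dplyr::select(gps, "participant_id", "time", "date", "day_type", "x", "y")
}

#' Schedule day type of a calendar date
#'
#' @param date A `Date` vector.
#' @return `"weekday"`, `"saturday"` or `"sunday"` per element.
#' @export
day_type_of <- function(date) {
  wd <- lubridate::wday(date, week_start = 1)  # 1 = Monday ... 7 = Sunday
  dplyr::case_when(wd == 6 ~ "saturday", wd == 7 ~ "sunday", TRUE ~ "weekday")
}

#' Write a GPS table as CSV
#'
#' @param gps A GPS tibble (raw or preprocessed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gps <- function(gps, path) {
  out <- tibble::as_tibble(gps)
  out$timestamp <- format(out$time, "%Y-%m-%dT%H:%M:%S")
  out <- dplyr::select(out, "participant_id", "timestamp",
                       dplyr::any_of(c("x", "y", "imputed", "velocity")))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

read_gpx_track <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trkpt")
  tibble::tibble(
    lon = as.numeric(xml2::xml_attr(pts, "lon")),
    lat = as.numeric(xml2::xml_attr(pts, "lat")),
    timestamp = xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
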