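#' Impute short GPS gaps
#'
#' Fills breaks in the nominal 1-min cadence per participant. For each gap
#' between temporally adjacent records `a` and `b` (elapsed time > 1 min
#' but < 1 h):
#'
#' * endpoint distance < 30 m — every missing 1-min slot is inserted at the
#'   earlier point's coordinates (stationary fill, velocity 0);
#' * endpoint distance >= 30 m — missing 1-min slots are linearly
#'   interpolated between the endpoints (constant velocity).
#'
#' Periods of an hour or longer are considered missing and never imputed,
#' whatever the endpoint distance. Exactly 30 m falls in the interpolation
#' branch and an exactly 60-min gap is left missing. Original records are never altered; inserted records are
#' flagged `imputed`. The record velocity column is (re)computed as the
#' planar distance to the previous record divided by the elapsed minutes
#' (first record of a participant: 0).
#'
#' @param gps A GPS tibble from [read_gps()] / [as_gps_table()] (or a
#'   previous [impute_gaps()] pass — the operation is idempotent).
#' @return A trajectory tibble: `participant_id`, `time`, `date`,
#'   `day_type`, `x`, `y`, `imputed`, `velocity` (m/min).
#' @export
impute_gaps <- function(gps) {
  gps <- tibble::as_tibble(gps)
  if (!"imputed" %in% names(gps)) gps$imputed <- FALSE
  parts <- split(gps, gps$participant_id)
  out <- lapply(parts, impute_gaps_one)
  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$participant_id, .data$time)
  res$date <- lubridate::as_date(res$time)
  res$day_type <- day_type_of(res$date)
  res <- add_velocity(res)
  dplyr::select(res, "participant_id", "time", "date", "day_type",
                "x", "y", "imputed", "velocity")
}

impute_gaps_one <- function(df) {
  df <- df[order(df$time), , drop = FALSE]
  n <- nrow(df)
  if (n < 2) return(df)
  tmin <- as.numeric(df$time) / 60
  dt <- diff(tmin)
  gap_at <- which(dt > 1 + 1e-9)
  if (length(gap_at) == 0) return(df)
  dist <- sqrt(diff(df$x)^2 + diff(df$y)^2)
  fills <- vector("list", length(gap_at))
  for (k in seq_along(gap_at)) {
    a <- gap_at[k]
    n_miss <- floor(dt[a] - 1e-9)
    if (n_miss * 1 >= dt[a]) n_miss <- n_miss - 1   # exact multiples
    if (n_miss < 1) next
    step <- seq_len(n_miss)
    if (dt[a] >= 60) next                     # >= 1 h: missing, never imputed
    if (dist[a] < 30) {
      fx <- rep(df$x[a], n_miss); fy <- rep(df$y[a], n_miss)
    } else {
      f <- step / dt[a]  # fraction of elapsed time at each inserted minute
      fx <- df$x[a] + f * (df$x[a + 1] - df$x[a])
      fy <- df$y[a] + f * (df$y[a + 1] - df$y[a])
    }
    fills[[k]] <- tibble::tibble(
      participant_id = df$participant_id[a],
      time = df$time[a] + step * 60,
      x = fx, y = fy, imputed = TRUE)
  }
  fills <- dplyr::bind_rows(fills)
  if (nrow(fills) == 0) return(df)
  dplyr::bind_rows(df, fills)
}

add_velocity <- function(res) {
  grp <- res$participant_id
  dx <- c(0, diff(res$x)); dy <- c(0, diff(res$y))
  dtm <- c(1, diff(as.numeric(res$time) / 60))
  first <- !duplicated(grp)
  v <- sqrt(dx^2 + dy^2) / pmax(dtm, 1e-9)
  v[first] <- 0
  res$velocity <- v
  res
}

#' Flag valid survey days
#'
#' A participant's local date is a valid day when it has at least eight
#' hours (480 minutes) of non-missing records — recorded or imputed minutes
#' both count.
#'
#' @param traj A trajectory tibble from [impute_gaps()].
#' @return The same tibble with a logical `valid_day` column; the per-day
#'   table is attached as attribute `"day_summaries"` and retrievable with
#'   [day_summaries()].
#' @export
flag_valid_days <- function(traj) {
  traj <- tibble::as_tibble(traj)
  days <- dplyr::summarise(
    dplyr::group_by(traj, .data$participant_id, .data$date, .data$day_type),
    valid_minutes = dplyr::n(), .groups = "drop")
  days$is_valid_day <- days$valid_minutes >= 480
  traj$valid_day <- NULL
  traj <- dplyr::left_join(
    traj, dplyr::select(days, "participant_id", "date",
                        valid_day = "is_valid_day"),
    by = c("participant_id", "date"))
  attr(traj, "day_summaries") <- days
  traj
}

#' Per-day validity summaries
#'
#' @param traj A trajectory tibble from [flag_valid_days()].
#' @return A tibble: `participant_id`, `date`, `day_type`, `valid_minutes`,
#'   `is_valid_day`.
#' @export
day_summaries <- function(traj) {
  ds <- attr(traj, "day_summaries")
  if (is.null(ds)) ds <- attr(flag_valid_days(traj), "day_summaries")
  ds
}

#' Select valid participants
#'
#' Keeps participants with at least five valid weekdays and at least two
#' valid weekend days (Saturday or Sunday), and reports how many were kept
#' and dropped.
#'
#' @param traj A trajectory tibble from [flag_valid_days()].
#' @param min_weekdays,min_weekend_days Screening thresholds (defaults 5
#'   and 2).
#' @return The trajectory tibble restricted to surviving participants
#'   (day summaries attribute updated alongside).
#' @export
select_participants <- function(traj, min_weekdays = 5, min_weekend_days = 2) {
  ds <- day_summaries(traj)
  tally <- dplyr::summarise(
    dplyr::group_by(ds, .data$participant_id),
    n_weekday = sum(.data$is_valid_day & .data$day_type == "weekday"),
    n_weekend = sum(.data$is_valid_day & .data$day_type != "weekday"),
    .groups = "drop")
  keep <- tally$participant_id[tally$n_weekday >= min_weekdays &
                                 tally$n_weekend >= min_weekend_days]
  message(length(keep), " participant(s) kept, ",
          nrow(tally) - length(keep), " dropped by the ",
          min_weekdays, "+", min_weekend_days, " valid-day screen")
  if (length(keep) == 0) {
    stop("no participant passes the valid-day screen; relax the scenario ",
         "(more days, fewer gaps) or the thresholds", call. = FALSE)
  }
  out <- traj[traj$participant_id %in% keep, , drop = FALSE]
  attr(out, "day_summaries") <- ds[ds$participant_id %in% keep, , drop = FALSE]
  out
}

#' Preprocess raw GPS data end to end
#'
#' Convenience wrapper chaining [impute_gaps()], [flag_valid_days()] and
#' [select_participants()].
#'
#' @inheritParams impute_gaps
#' @inheritParams select_participants
#' @return A screened trajectory tibble with `valid_day` flags and a
#'   `"day_summaries"` attribute.
#' @export
preprocess_gps <- function(gps, min_weekdays = 5, min_weekend_days = 2) {
  gps |>
    impute_gaps() |>
    flag_valid_days() |>
    select_participants(min_weekdays, min_weekend_days)
}

#' Classify GPS gaps for quality control
#'
#' Scans a (raw or imputed) GPS table for cadence breaks and classifies each
#' by the imputation rule it triggers.
#'
#' @param gps A GPS tibble.
#' @return A tibble with one row per gap: `participant_id`, `start`
#'   (last time before the gap), `gap_minutes`, `endpoint_distance`, and
#'   `class` (`"stationary_fill"`, `"interpolate"`, `"missing"`).
#' @export
gap_classes <- function(gps) {
  gps <- dplyr::arrange(tibble::as_tibble(gps),
                        .data$participant_id, .data$time)
  grp <- gps$participant_id
  dtm <- c(NA, diff(as.numeric(gps$time) / 60))
  dist <- c(NA, sqrt(diff(gps$x)^2 + diff(gps$y)^2))
  dtm[!duplicated(grp)] <- NA
  sel <- which(!is.na(dtm) & dtm > 1 + 1e-9)
  tibble::tibble(
    participant_id = grp[sel],
    start = gps$time[sel - 1],
    gap_minutes = dtm[sel],
    endpoint_distance = dist[sel],
    class = dplyr::case_when(
      dtm[sel] >= 60 ~ "missing",
      dist[sel] < 30 ~ "stationary_fill",
      TRUE ~ "interpolate"))
}
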