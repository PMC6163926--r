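# Shared fixtures, built in code. The small study is computed once per test
# run and memoised in this environment.

.fixture_env <- new.env(parent = emptyenv())

tiny_config <- function(extent = c(0, 0, 2000, 2000), ...) {
  study_config(grid_extent = extent, ...)
}

tiny_scenario <- function(seed = 11, n_participants = 6, n_outlets = 40,
                          n_days = 7, ...) {
  synth_scenario(config = tiny_config(),
                 n_participants = n_participants, n_outlets = n_outlets,
                 n_days = n_days, poor_wear_frac = 0, seed = seed, ...)
}

# a 6-participant preprocessed cohort plus registry, shared across files
small_study <- function() {
  if (is.null(.fixture_env$small)) {
    sc <- tiny_scenario()
    reg <- make_outlets(sc)
    gps <- suppressWarnings(make_trajectories(sc))
    traj <- suppressMessages(preprocess_gps(gps))
    .fixture_env$small <- list(scenario = sc, registry = reg,
                               gps = gps, traj = traj)
  }
  .fixture_env$small
}

# hand-built GPS table: one participant, one day, given minute/x/y vectors
gps_from_minutes <- function(minutes, x, y, id = "P1",
                             date = as.Date("2026-04-06")) {
  tibble::tibble(
    participant_id = id,
    time = as.POSIXct(date, tz = "UTC") + minutes * 60,
    x = x, y = y) |>
    as_gps_table()
}

# a stationary full-day trajectory at (px, py)
stationary_day <- function(px, py, id = "P1", date = as.Date("2026-04-06")) {
  gps_from_minutes(0:1439, rep(px, 1440), rep(py, 1440), id = id,
                   date = date)
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
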