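test_that("velocity weights follow the halving rule", {
  expect_equal(point_weight(0, "velocity"), 1)
  expect_equal(point_weight(1, "velocity"), 0.5)
  expect_equal(point_weight(2, "velocity"), 0.25)
  expect_equal(point_weight(c(0, 3.5, 10), "constant"), c(1, 1, 1))
  expect_equal(point_weight(3.5, "velocity"), 0.5^3.5)
  expect_error(point_weight(-1, "velocity"), "non-negative")
})

test_that("the exposure index is the weighted value sum per unit time", {
  one <- tibble::tibble(value = 2, weight = 1)
  expect_equal(ecei(one, 1), 2)
  n <- 37; c0 <- 0.83
  unif <- tibble::tibble(value = rep(c0, n), weight = rep(1, n))
  expect_equal(ecei(unif, 4), c0 * n / 4)
  withr::with_seed(61, {
    pts <- tibble::tibble(value = stats::runif(500), weight = stats::runif(500))
  })
  oracle <- 0
  for (k in seq_len(500)) oracle <- oracle + pts$value[k] * pts$weight[k]
  expect_equal(ecei(pts, 7.3), oracle / 7.3, tolerance = 1e-12)
  expect_error(ecei(one, 0), "positive")
})

test_that("z-scoring centres and scales each method key", {
  rec <- tibble::tibble(participant_id = c("a", "b", "c"),
                        method_key = "K", ecei_raw = c(1, 2, 3))
  out <- standardize_exposures(rec)
  expect_equal(out$ecei_z, c(-1, 0, 1))
  expect_error(standardize_exposures(rec[1, ]), "two participants")
  const <- tibble::tibble(participant_id = c("a", "b"),
                          method_key = "K", ecei_raw = c(5, 5))
  expect_warning(outc <- standardize_exposures(const), "zero")
  expect_equal(outc$ecei_z, c(0, 0))
  withr::with_seed(62, {
    many <- tibble::tibble(participant_id = sprintf("p%02d", 1:46),
                           method_key = "K",
                           ecei_raw = stats::rlnorm(46))
  })
  z <- standardize_exposures(many)$ecei_z
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(stats::sd(z) - 1), 1e-12)
})

test_that("tunnels cover valid days only and honour Br provenance", {
  traj <- flag_valid_days(impute_gaps(stationary_day(500, 500)))
  tun <- build_tunnel(traj, "weekday", br = 100)
  expect_equal(tun$br, 100)
  expect_length(tun$days, 1)
  expect_equal(nrow(tun$days[[1]]), 1440)
  expect_warning(empty <- build_tunnel(traj, "sunday", br = 100),
                 "no valid sunday")
  expect_length(empty$days, 0)
})

test_that("an empty tunnel intersects nothing", {
  cfg <- tiny_config()
  reg <- make_outlets(tiny_scenario(seed = 63))
  cloud <- to_point_cloud(build_cube(reg, "sunday", "ISDD", 200, cfg))
  traj <- flag_valid_days(impute_gaps(stationary_day(500, 500)))
  tun <- suppressWarnings(build_tunnel(traj, "sunday", br = 100))
  expect_equal(nrow(intersect_tunnel(tun, cloud)), 0)
})

test_that("a stationary day over a cell centroid hits one voxel column", {
  cfg <- tiny_config()
  reg <- tibble::tibble(
    outlet_id = "o", x = 700, y = 700, category = "fast_food",
    open_weekday = 0L, close_weekday = 1440L,
    open_saturday = 0L, close_saturday = 1440L,
    open_sunday = 0L, close_sunday = 1440L)
  cube10 <- refine_cube(build_cube(reg, "weekday", "NEDD", 200, cfg))
  cloud <- to_point_cloud(cube10)
  traj <- flag_valid_days(impute_gaps(stationary_day(700, 700)))
  tun <- build_tunnel(traj, "weekday", br = 80)    # br < cell_size / 2
  hits <- intersect_tunnel(tun, cloud)
  expect_equal(nrow(hits), 144)
  expect_equal(unique(hits$x), 700)
  expect_equal(unique(hits$y), 700)
  expect_equal(sort(hits$t), seq(5, 1435, by = 10))
  expect_true(all(hits$weight == 1))
})

test_that("a day with a long unimputed gap leaves a temporal hole", {
  # 90-min dropout 10:00-11:30 across 600 m, track along a centroid row
  mins <- c(0:599, 690:1439)
  xs <- c(rep(100, 600), rep(700, 750))
  traj <- flag_valid_days(impute_gaps(gps_from_minutes(mins, xs,
                                                       rep(100, 1350))))
  cfg <- tiny_config()
  reg <- make_outlets(tiny_scenario(seed = 65))
  reg$open_weekday <- 0L; reg$close_weekday <- 1440L
  cloud <- to_point_cloud(build_cube(reg, "weekday", "ISDD", 200, cfg))
  tun <- build_tunnel(traj, "weekday", br = 100)
  hits <- intersect_tunnel(tun, cloud)
  in_hole <- hits$t > 600 & hits$t < 690
  expect_equal(sum(in_hole), 0)
  expect_gt(nrow(hits), 0)
})

test_that("intersection matches the brute-force all-pairs oracle", {
  cfg <- tiny_config(extent = c(0, 0, 4000, 4000))
  sc <- tiny_scenario(seed = 67, n_participants = 1)
  gps <- suppressWarnings(make_trajectories(sc))
  # keep two weekday dates, with the generator's gaps intact
  traj <- suppressMessages(preprocess_gps(gps, min_weekdays = 1,
                                          min_weekend_days = 0))
  dates <- unique(traj$date[traj$day_type == "weekday"])[1:2]
  traj <- traj[traj$date %in% dates, , drop = FALSE]
  traj <- flag_valid_days(traj)
  reg <- make_outlets(sc)
  cloud <- to_point_cloud(build_cube(reg, "weekday", "ISDD", 200, cfg))
  expect_equal(nrow(cloud), 20 * 20 * 48)
  tun <- build_tunnel(traj, "weekday", br = 100)
  got <- intersect_tunnel(tun, cloud)
  want <- oracle_intersect(tun$days, cloud, br = 100)
  key <- function(d) sort(paste(d$day, d$x, d$y, d$t, signif(d$value, 12)))
  expect_equal(key(got), key(want))
})

test_that("enlarging Br yields a superset of intersections", {
  cfg <- tiny_config()
  sc <- tiny_scenario(seed = 69, n_participants = 1)
  traj <- suppressMessages(preprocess_gps(suppressWarnings(
    make_trajectories(sc)), min_weekdays = 1, min_weekend_days = 0))
  reg <- make_outlets(sc)
  cloud <- to_point_cloud(build_cube(reg, "weekday", "ISDD", 200, cfg))
  t1 <- build_tunnel(traj, "weekday", br = 60)
  t2 <- build_tunnel(traj, "weekday", br = 140)
  h1 <- intersect_tunnel(t1, cloud)
  h2 <- intersect_tunnel(t2, cloud)
  k <- function(d) paste(d$day, d$x, d$y, d$t)
  expect_true(all(k(h1) %in% k(h2)))
  expect_gte(sum(h2$value), sum(h1$value))  # non-negative values
})

test_that("a zero cube gives exactly zero exposure for everyone", {
  s <- small_study()
  cfg <- s$scenario$config
  cube <- build_cube(s$registry, "weekday", "ISDD", 200, cfg)
  cube$layers <- rep(list(matrix(0, cube$geom$ny, cube$geom$nx)), 48)
  cubes <- tibble::tibble(method = "ISDD", cell_size = 200,
                          slot_minutes = 30L, day_type = "weekday",
                          method_key = "ISDD200T30",
                          cube_id = "ISDD200T30.weekday", cube = list(cube))
  out <- suppressWarnings(compute_ecei(s$traj, cubes, br = 100))
  expect_true(all(out$ecei_raw == 0))
})

test_that("the fast exposure path agrees with the contract intersection", {
  s <- small_study()
  cfg <- s$scenario$config
  cfg$decay_methods <- "ISDD"
  cfg$spatial_resolutions <- 200
  cubes <- enumerate_cubes(s$registry, cfg)      # 6 cubes: 3 days x 2 res
  ids <- unique(s$traj$participant_id)[1:3]
  traj <- s$traj[s$traj$participant_id %in% ids, , drop = FALSE]
  traj <- flag_valid_days(traj)
  got <- compute_ecei(traj, cubes, br = 100)

  ds <- day_summaries(traj)
  obs <- ds[ds$is_valid_day, ] |>
    dplyr::group_by(participant_id, day_type) |>
    dplyr::summarise(t_hours = sum(valid_minutes) / 60,
                     n_days = dplyr::n(), .groups = "drop")
  for (id in ids) {
    for (mk in unique(cubes$method_key)) {
      vals <- c(); wts <- c()
      for (r in which(cubes$method_key == mk)) {
        dt <- cubes$day_type[r]
        o <- obs[obs$participant_id == id & obs$day_type == dt, ]
        if (nrow(o) == 0) next
        tun <- suppressWarnings(build_tunnel(traj, dt, br = 100,
                                             participant_id = id))
        cloud <- to_point_cloud(cubes$cube[[r]])
        pts <- intersect_tunnel(tun, cloud)
        e_dt <- if (nrow(pts) == 0) 0 else ecei(pts, o$t_hours)
        vals <- c(vals, e_dt); wts <- c(wts, o$n_days)
      }
      want <- stats::weighted.mean(vals, wts)
      expect_equal(got$ecei_raw[got$participant_id == id &
                                  got$method_key == mk],
                   want, tolerance = 1e-10,
                   info = paste(id, mk))
    }
  }
})

test_that("velocity mode downweights moving intersections", {
  cfg <- tiny_config()
  reg <- tibble::tibble(
    outlet_id = "o", x = 500, y = 100, category = "fast_food",
    open_weekday = 0L, close_weekday = 1440L,
    open_saturday = 0L, close_saturday = 1440L,
    open_sunday = 0L, close_sunday = 1440L)
  # walk east at 10 m/min for the whole day
  traj <- flag_valid_days(impute_gaps(
    gps_from_minutes(0:1439, 10 * (0:1439) %% 2000, rep(100, 1440))))
  cloud <- to_point_cloud(build_cube(reg, "weekday", "ISDD", 200, cfg))
  tun <- build_tunnel(traj, "weekday", br = 100)
  hits <- intersect_tunnel(tun, cloud, weight_mode = "velocity")
  moving <- hits$velocity > 0
  expect_true(any(moving))
  expect_equal(hits$weight[moving], 0.5^hits$velocity[moving])
  expect_true(all(hits$weight[!moving] == 1))
})
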