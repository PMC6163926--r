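# distance from a point to each edge of a polygon tibble (boundary checks)
point_segment_dist <- function(px, py, poly) {
  n <- nrow(poly)
  d <- numeric(n)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    ax <- poly$x[k]; ay <- poly$y[k]; bx <- poly$x[k2]; by <- poly$y[k2]
    t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) /
      max((bx - ax)^2 + (by - ay)^2, 1e-12)
    t <- min(1, max(0, t))
    d[k] <- sqrt((ax + t * (bx - ax) - px)^2 + (ay + t * (by - ay) - py)^2)
  }
  d
}

test_that("GTB of a stationary point is a disc of the right area", {
  traj <- flag_valid_days(impute_gaps(stationary_day(1000, 1000)))
  # jitter-free: every fix at the same point
  sp <- gtb(traj, radius = 100)
  expect_equal(sp$area_m2, pi * 100^2, tolerance = 0.005)
  expect_true(all(space_contains(sp, 1000, 1000)))
  expect_true(space_contains(sp, 1099.9, 1000))
  expect_false(space_contains(sp, 1101, 1000))
})

test_that("GTB of a straight track is a stadium", {
  # 1000 m east-west track walked at 25 m/min, then back, all day
  xs <- 1000 + 25 * (0:40)
  path_x <- rep(c(xs, rev(xs)), length.out = 1440)
  traj <- flag_valid_days(impute_gaps(
    gps_from_minutes(0:1439, path_x, rep(500, 1440))))
  sp <- gtb(traj, radius = 100)
  want <- 2 * 100 * 1000 + pi * 100^2
  expect_equal(sp$area_m2, want, tolerance = 0.005)
})

test_that("GTB and MCP contain every GPS point", {
  s <- small_study()
  id <- unique(s$traj$participant_id)[1]
  pts <- s$traj[s$traj$participant_id == id & s$traj$valid_day, ]
  b <- gtb(s$traj, 100, participant_id = id)
  h <- mcp(s$traj, participant_id = id)
  expect_true(all(space_contains(b, pts$x, pts$y)))
  expect_true(all(space_contains(h, pts$x, pts$y)))
})

test_that("MCP of a square is the square", {
  pts <- gps_from_minutes(0:479,
                          rep(c(0, 1000, 1000, 0), 120),
                          rep(c(0, 0, 1000, 1000), 120))
  traj <- flag_valid_days(impute_gaps(pts))
  h <- mcp(traj)
  expect_equal(h$area_m2, 1e6)
  expect_equal(nrow(h$hull), 4)
})

test_that("MCP vertices equal the gift-wrapping oracle on random points", {
  withr::with_seed(71, {
    x <- stats::runif(200, 0, 3000); y <- stats::runif(200, 0, 3000)
  })
  traj <- flag_valid_days(impute_gaps(gps_from_minutes(
    0:599, rep(x, length.out = 600), rep(y, length.out = 600))))
  h <- mcp(traj)
  oracle_idx <- oracle_hull(x, y)
  got <- h$hull[order(h$hull[, 1], h$hull[, 2]), , drop = FALSE]
  want <- cbind(x = x[oracle_idx], y = y[oracle_idx])
  want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(want))
})

test_that("collinear points make the MCP degenerate", {
  traj <- flag_valid_days(impute_gaps(gps_from_minutes(
    0:499, seq(0, 4990, by = 10), seq(0, 4990, by = 10))))
  expect_error(mcp(traj), "collinear|degenerate")
})

test_that("SDE axes recover the spread of an isotropic cloud", {
  withr::with_seed(73, {
    x <- stats::rnorm(10000, 1000, 100); y <- stats::rnorm(10000, 1000, 100)
  })
  traj <- flag_valid_days(impute_gaps(gps_from_minutes(
    0:1339, rep(x, length.out = 1340), rep(y, length.out = 1340))))
  e1 <- sde(traj, 1)
  expect_equal(e1$semi_major, 100, tolerance = 0.05)
  expect_equal(e1$semi_minor, 100, tolerance = 0.05)
  expect_equal(e1$center, c(1000, 1000), tolerance = 0.01)
})

test_that("SDE2 doubles the axes and quadruples the area of SDE1", {
  s <- small_study()
  id <- unique(s$traj$participant_id)[2]
  e1 <- sde(s$traj, 1, participant_id = id)
  e2 <- sde(s$traj, 2, participant_id = id)
  expect_equal(e2$theta, e1$theta)
  expect_equal(e2$semi_major, 2 * e1$semi_major)
  expect_equal(e2$area_m2, 4 * e1$area_m2)
  # SDE1 strictly inside SDE2: every SDE1 boundary vertex lies in SDE2
  p1 <- as_polygon(e1)
  expect_true(all(space_contains(e2, p1$x, p1$y)))
})

test_that("SDE orientation is equivariant under rotation", {
  withr::with_seed(75, {
    x0 <- stats::rnorm(2000, 0, 300); y0 <- stats::rnorm(2000, 0, 60)
  })
  ang <- 30 * pi / 180
  rot_x <- 2000 + cos(ang) * x0 - sin(ang) * y0
  rot_y <- 2000 + sin(ang) * x0 + cos(ang) * y0
  t0 <- flag_valid_days(impute_gaps(gps_from_minutes(
    0:1999, 2000 + x0, 2000 + y0)))
  t1 <- flag_valid_days(impute_gaps(gps_from_minutes(
    0:1999, rot_x, rot_y)))
  th0 <- sde(t0, 1)$theta
  th1 <- sde(t1, 1)$theta
  expect_equal((th1 - th0) %% pi, ang, tolerance = 1e-9)
})

test_that("degenerate scatter makes the SDE fatal", {
  traj <- flag_valid_days(impute_gaps(gps_from_minutes(
    0:499, seq_len(500), rep(10, 500))))
  expect_error(sde(traj, 1), "zero variance|degenerate")
})

test_that("outlet density is count per square kilometre, boundary included", {
  # unit-km square MCP with 5 inside outlets and one exactly on the edge
  traj <- flag_valid_days(impute_gaps(gps_from_minutes(
    0:479, rep(c(0, 1000, 1000, 0), 120), rep(c(0, 0, 1000, 1000), 120))))
  h <- mcp(traj)
  reg <- tibble::tibble(
    outlet_id = sprintf("o%d", 1:7),
    x = c(100, 500, 900, 250, 750, 1000, 1500),
    y = c(100, 500, 900, 750, 250, 500, 1500),
    category = "fast_food",
    open_weekday = 0L, close_weekday = 1440L,
    open_saturday = 0L, close_saturday = 1440L,
    open_sunday = 0L, close_sunday = 1440L)
  # five interior + one on the boundary = 6 per km^2; the outside one ignored
  expect_equal(outlet_density(h, reg), 6)
})

test_that("point-in-polygon agrees with the ray-casting oracle", {
  s <- small_study()
  id <- unique(s$traj$participant_id)[3]
  h <- mcp(s$traj, participant_id = id)
  withr::with_seed(77, {
    qx <- stats::runif(400, -100, 2100); qy <- stats::runif(400, -100, 2100)
  })
  got <- space_contains(h, qx, qy)
  want <- oracle_ray_cast(qx, qy, h$hull)
  disagree <- which(got != want)
  if (length(disagree) > 0) {
    # any disagreement must be a boundary grazing, not an interior error
    p <- as_polygon(h)
    for (k in disagree) {
      d <- min(point_segment_dist(qx[k], qy[k], p))
      expect_lt(d, 1e-6)
    }
  }
  expect_gt(sum(got), 0)
  expect_lt(sum(got), length(got))
})

test_that("ellipse membership agrees with ray casting on its polygon", {
  s <- small_study()
  id <- unique(s$traj$participant_id)[1]
  e2 <- sde(s$traj, 2, participant_id = id)
  poly <- as.matrix(as_polygon(e2, n = 720))
  withr::with_seed(79, {
    qx <- stats::runif(300, 0, 2000); qy <- stats::runif(300, 0, 2000)
  })
  got <- space_contains(e2, qx, qy)
  want <- oracle_ray_cast(qx, qy, poly)
  expect_gt(mean(got == want), 0.99)
  # the 720-gon underestimates the ellipse by < 0.01%, so only points
  # essentially on the boundary may differ
  mism <- which(got != want)
  if (length(mism) > 0) {
    u <- ((qx[mism] - e2$center[1]) * cos(e2$theta) +
            (qy[mism] - e2$center[2]) * sin(e2$theta)) / e2$semi_major
    v <- (-(qx[mism] - e2$center[1]) * sin(e2$theta) +
            (qy[mism] - e2$center[2]) * cos(e2$theta)) / e2$semi_minor
    expect_true(all(abs(u^2 + v^2 - 1) < 1e-3))
  }
})

test_that("exposure values are invariant under joint translation", {
  s <- small_study()
  ids <- unique(s$traj$participant_id)[1:2]
  traj <- flag_valid_days(s$traj[s$traj$participant_id %in% ids, ])
  shift <- c(5000, -3000)
  traj2 <- traj
  traj2$x <- traj$x + shift[1]; traj2$y <- traj$y + shift[2]
  traj2 <- flag_valid_days(traj2)
  reg2 <- s$registry
  reg2$x <- reg2$x + shift[1]; reg2$y <- reg2$y + shift[2]
  e1 <- suppressWarnings(activity_space_exposures(traj, s$registry))
  e2 <- suppressWarnings(activity_space_exposures(traj2, reg2))
  expect_equal(e2$density_raw, e1$density_raw, tolerance = 1e-6)
})

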