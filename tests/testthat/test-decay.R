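test_that("decay closed forms hold", {
  expect_equal(decay_value("NEDD", 500, 500), exp(-1))
  expect_equal(decay_value("ISDD", 0, 100), 1)
  expect_equal(decay_value("ISDD", 100, 100), 0.5)
  expect_equal(decay_value("KD", 1000, 1000), 0)    # support boundary
  expect_equal(decay_value("KD", 1500, 1000), 0)    # beyond support
  expect_equal(decay_value("KD", 0, 1000), 3 / (pi * 1e6))
  expect_error(decay_value("NEDD", 10, -5), "positive")
  expect_error(decay_value("NEDD", -1, 100), "non-negative")
})

test_that("every decay family is non-increasing in distance", {
  d <- seq(0, 3000, by = 7)
  for (m in c("KD", "ISDD", "NEDD")) {
    v <- decay_value(m, d, 400)
    expect_true(all(diff(v) <= 1e-15), info = m)
    expect_true(all(v >= 0), info = m)
  }
})

test_that("the quartic kernel integrates to one over the plane", {
  # radial integral of 3/(pi h^2) (1 - (r/h)^2)^2 * 2 pi r dr on [0, h]
  h <- 700
  f <- function(r) decay_value("KD", r, h) * 2 * pi * r
  expect_equal(stats::integrate(f, 0, h)$value, 1, tolerance = 1e-8)
})

test_that("outlets are open exactly on [open, close) of their day type", {
  reg <- tibble::tibble(
    outlet_id = "a", x = 0, y = 0, category = "fast_food",
    open_weekday = 600L, close_weekday = 1320L,
    open_saturday = 660L, close_saturday = 1320L,
    open_sunday = NA_integer_, close_sunday = NA_integer_)
  expect_equal(nrow(open_outlets(reg, "weekday", 570)), 0)   # 09:30 closed
  expect_equal(nrow(open_outlets(reg, "weekday", 600)), 1)   # 10:00 open
  expect_equal(nrow(open_outlets(reg, "weekday", 1319)), 1)
  expect_equal(nrow(open_outlets(reg, "weekday", 1320)), 0)  # close excluded
  expect_equal(nrow(open_outlets(reg, "saturday", 600)), 0)  # Sat opens 11:00
  # closed all day type -> excluded from every slot
  expect_true(all(vapply(seq(0, 1439, 60),
                         function(s) nrow(open_outlets(reg, "sunday", s)),
                         numeric(1)) == 0))
})

test_that("overnight schedules wrap into the following day type", {
  reg <- tibble::tibble(
    outlet_id = "n", x = 0, y = 0, category = "fast_food",
    open_weekday = 1080L, close_weekday = 120L,     # 18:00-02:00
    open_saturday = 1080L, close_saturday = 120L,
    open_sunday = 1080L, close_sunday = 120L)
  expect_equal(nrow(open_outlets(reg, "weekday", 0)), 1)     # 00:00 open
  expect_equal(nrow(open_outlets(reg, "weekday", 119)), 1)
  expect_equal(nrow(open_outlets(reg, "weekday", 180)), 0)   # 03:00 closed
  expect_equal(nrow(open_outlets(reg, "weekday", 1080)), 1)  # 18:00 open
  # Saturday 00:30 is covered by Friday's (weekday) overnight tail
  reg2 <- reg
  reg2$open_saturday <- NA_integer_; reg2$close_saturday <- NA_integer_
  expect_equal(nrow(open_outlets(reg2, "saturday", 30)), 1)
  expect_equal(nrow(open_outlets(reg2, "saturday", 200)), 0)
})

test_that("a layer equals direct evaluation at an outlet-centred cell", {
  cfg <- tiny_config(extent = c(0, 0, 1000, 1000))
  geom <- expocube:::grid_geometry(cfg, 100)
  # outlet exactly at the centroid of cell (3, 4): x = 350, y = 250
  reg <- tibble::tibble(
    outlet_id = "a", x = 350, y = 250, category = "fast_food",
    open_weekday = 0L, close_weekday = 1440L,
    open_saturday = 0L, close_saturday = 1440L,
    open_sunday = 0L, close_sunday = 1440L)
  lay <- build_layer(reg, "weekday", 720, "ISDD", 100, cfg)
  expect_equal(lay$grid[3, 4], 1.0)
  neigh <- 1 / (1 + (100 / 100)^2)
  expect_equal(lay$grid[2, 4], neigh)
  expect_equal(lay$grid[4, 4], neigh)
  expect_equal(lay$grid[3, 3], neigh)
  expect_equal(lay$grid[3, 5], neigh)
})

test_that("a slot with no open outlets yields an all-zero grid", {
  cfg <- tiny_config()
  reg <- make_outlets(tiny_scenario(seed = 31, schedule_mix = 0))
  reg$open_weekday <- 600L; reg$close_weekday <- 700L
  lay <- build_layer(reg, "weekday", 100, "NEDD", 200, cfg)
  expect_true(all(lay$grid == 0))
})

test_that("layers match the brute-force double loop to 1e-12 relative", {
  cfg <- tiny_config(extent = c(0, 0, 4000, 4000))
  withr::with_seed(99, {
    open_xy <- tibble::tibble(x = stats::runif(10, 0, 4000),
                              y = stats::runif(10, 0, 4000))
  })
  reg <- tibble::tibble(
    outlet_id = sprintf("o%d", 1:10), x = open_xy$x, y = open_xy$y,
    category = "fast_food",
    open_weekday = 0L, close_weekday = 1440L,
    open_saturday = 0L, close_saturday = 1440L,
    open_sunday = 0L, close_sunday = 1440L)
  geom <- expocube:::grid_geometry(cfg, 200)       # 20 x 20 grid
  for (m in c("KD", "ISDD", "NEDD")) {
    scale <- switch(m, KD = cfg$decay_params$kd_bandwidth,
                    ISDD = cfg$decay_params$isdd_d0,
                    NEDD = cfg$decay_params$nedd_d0)
    lay <- build_layer(reg, "weekday", 720, m, 200, cfg, cutoff = 0)
    expect_equal(lay$grid, oracle_layer(open_xy, m, scale, geom),
                 tolerance = 1e-12, info = m)
  }
})

test_that("layers superpose over disjoint outlet sets", {
  cfg <- tiny_config()
  reg <- make_outlets(tiny_scenario(seed = 33, n_outlets = 20))
  reg$open_weekday <- 0L; reg$close_weekday <- 1440L
  a <- reg[1:8, ]; b <- reg[9:20, ]
  la <- build_layer(a, "weekday", 300, "NEDD", 200, cfg, cutoff = 0)
  lb <- build_layer(b, "weekday", 300, "NEDD", 200, cfg, cutoff = 0)
  lab <- build_layer(reg, "weekday", 300, "NEDD", 200, cfg, cutoff = 0)
  expect_equal(lab$grid, la$grid + lb$grid, tolerance = 1e-12)
})

test_that("layers are equivariant under joint translation", {
  shift <- c(1300, -700)
  cfg1 <- tiny_config(extent = c(0, 0, 2000, 2000))
  cfg2 <- tiny_config(extent = c(shift[1], shift[2],
                                 2000 + shift[1], 2000 + shift[2]))
  reg <- make_outlets(tiny_scenario(seed = 35, n_outlets = 15))
  reg2 <- reg
  reg2$x <- reg$x + shift[1]; reg2$y <- reg$y + shift[2]
  l1 <- build_layer(reg, "weekday", 720, "ISDD", 100, cfg1)
  l2 <- build_layer(reg2, "weekday", 720, "ISDD", 100, cfg2)
  expect_equal(l2$grid, l1$grid, tolerance = 1e-12)
})
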