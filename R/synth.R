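#' Define a synthetic study scenario
#'
#' Fixes every parameter of the synthetic world used to exercise the
#' framework end to end: a clustered outlet registry with heterogeneous
#' day-type schedules, multi-day 1-min GPS tracks with realistic dropouts,
#' and participant covariates with an overweight outcome drawn from a known
#' logistic model on the true exposure. All generators are pure functions of
#' (scenario, seed); each draws from a named sub-stream of the master seed,
#' so adding a generator never perturbs another.
#'
#' Defaults emulate the framework's reference study conditions: 51 enrolled
#' participants of whom a poor-wear minority fails the valid-day screen
#' (leaving a cohort of 46), nine study days spanning seven weekdays and one
#' Saturday and Sunday, ~120 outlets clustered along two corridors with 60%
#' of them keeping different Saturday hours, and a strong positive exposure
#' effect (logit slope 3 per SD of true exposure) on overweight status.
#'
#' @param config A [study_config()]; its extent frames the synthetic world.
#' @param n_outlets,n_participants,n_days Counts (`n_days >= 7` so the
#'   participant screen can pass).
#' @param start_date First study date (default a Monday, so nine days give
#'   7 weekdays + Saturday + Sunday).
#' @param schedule_mix Fraction of outlets whose Saturday hours differ from
#'   weekday hours (by construction, at least `ceiling(schedule_mix *
#'   n_outlets)` do).
#' @param gap_model List: `enabled`, per-day class probabilities `p_short`
#'   (stationary dropouts with endpoints < 30 m), `p_travel` (sub-hour
#'   dropouts spanning a travel leg, endpoints >= 30 m), `p_long`
#'   (unimputable dropouts > 1 h). When enabled, one gap of each class is
#'   additionally injected deterministically so every imputation branch is
#'   always exercised.
#' @param poor_wear_frac Fraction of participants whose device wear is too
#'   sparse to pass the valid-participant screen.
#' @param outcome_model Named coefficients of the data-generating logistic
#'   model: `intercept`, `exposure` (per SD of true exposure), `female`,
#'   `age31_65`, `age65p`, `college`.
#' @param speed_range,speed_max,jitter Travel speed range (m/min), hard
#'   speed cap, and bounded per-coordinate GPS jitter (m).
#' @param p_lunch_errand,p_evening_errand Weekday side-trip probabilities.
#' @param seed Master integer seed for all three generators.
#' @return An object of class `synth_scenario`.
#' @export
synth_scenario <- function(config = study_config(),
                           n_outlets = 120,
                           n_participants = 51,
                           n_days = 9,
                           start_date = as.Date("2026-04-06"),
                           schedule_mix = 0.6,
                           gap_model = list(enabled = TRUE, p_short = 0.35,
                                            p_travel = 0.25, p_long = 0.15),
                           poor_wear_frac = 0.1,
                           outcome_model = c(intercept = -0.17, exposure = 3,
                                             female = 0.8, age31_65 = 0.3,
                                             age65p = 0.5, college = -0.8),
                           speed_range = c(150, 200),
                           speed_max = 250,
                           jitter = 5,
                           p_lunch_errand = 0.5,
                           p_evening_errand = 0.3,
                           seed = 1L) {
  stopifnot(inherits(config, "study_config"),
            n_days >= 7, n_outlets >= 1, n_participants >= 1,
            schedule_mix >= 0, schedule_mix <= 1,
            poor_wear_frac >= 0, poor_wear_frac < 1)
  gm <- utils::modifyList(list(enabled = TRUE, p_short = 0.35,
                               p_travel = 0.25, p_long = 0.15), gap_model)
  stopifnot(all(unlist(gm[c("p_short", "p_travel", "p_long")]) >= 0),
            all(unlist(gm[c("p_short", "p_travel", "p_long")]) <= 1))
  structure(list(config = config, n_outlets = as.integer(n_outlets),
                 n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days),
                 start_date = as.Date(start_date),
                 schedule_mix = schedule_mix, gap_model = gm,
                 poor_wear_frac = poor_wear_frac,
                 outcome_model = outcome_model,
                 speed_range = speed_range, speed_max = speed_max,
                 jitter = jitter,
                 p_lunch_errand = p_lunch_errand,
                 p_evening_errand = p_evening_errand,
                 seed = as.integer(seed)),
            class = "synth_scenario")
}

#' Generate a synthetic outlet registry
#'
#' Outlets are placed by a Poisson cluster process whose parents sit on two
#' crossing corridors of the study extent (emulating commercial strips).
#' Every outlet gets three day-type schedules; exactly
#' `ceiling(schedule_mix * n_outlets)` of them have Saturday hours that
#' differ from weekday hours (and about half of those also differ on
#' Sunday). Opening and closing minutes are drawn on a 10-minute lattice;
#' a few outlets are open 24 h, closed on Sundays, or open overnight.
#'
#' @param scenario A [synth_scenario()].
#' @return An `outlet_registry` tibble (see [read_outlets()]).
#' @export
make_outlets <- function(scenario) {
  stopifnot(inherits(scenario, "synth_scenario"))
  cfg <- scenario$config
  n <- scenario$n_outlets
  withr::with_seed(substream_seed(scenario$seed, "outlets"), {
    ext <- cfg$grid_extent
    w <- ext[3] - ext[1]; h <- ext[4] - ext[2]
    # two corridors: horizontal at 0.4 h, vertical at 0.6 w
    n_par <- max(4, round(n / 12))
    par_on_h <- stats::rbinom(1, n_par, 0.5)
    parents <- rbind(
      cbind(ext[1] + stats::runif(par_on_h) * w,
            ext[2] + 0.4 * h + stats::rnorm(par_on_h, 0, 0.02 * h)),
      cbind(ext[1] + 0.6 * w + stats::rnorm(n_par - par_on_h, 0, 0.02 * w),
            ext[2] + stats::runif(n_par - par_on_h) * h)
    )
    pick <- sample.int(n_par, n, replace = TRUE)
    x <- parents[pick, 1] + stats::rnorm(n, 0, 150)
    y <- parents[pick, 2] + stats::rnorm(n, 0, 150)
    x <- pmin(pmax(x, ext[1]), ext[3])
    y <- pmin(pmax(y, ext[2]), ext[4])

    grid10 <- function(lo, hi, n) 10L * sample(seq(lo / 10, hi / 10), n, replace = TRUE)
    open_wd <- grid10(360, 660, n)          # 06:00-11:00
    close_wd <- grid10(1020, 1380, n)       # 17:00-23:00
    kind <- sample(c("plain", "allday", "overnight"), n, replace = TRUE,
                   prob = c(0.90, 0.05, 0.05))
    open_wd[kind == "allday"] <- 0L; close_wd[kind == "allday"] <- 1440L
    open_wd[kind == "overnight"] <- grid10(1020, 1200, sum(kind == "overnight"))
    close_wd[kind == "overnight"] <- grid10(60, 180, sum(kind == "overnight"))

    open_sa <- open_wd; close_sa <- close_wd
    n_diff <- ceiling(scenario$schedule_mix * n)
    diff_idx <- if (n_diff > 0) sample.int(n, n_diff) else integer(0)
    shiftable <- diff_idx[kind[diff_idx] == "plain"]
    sh_open <- 10L * sample(c(-6:-1, 1:12), length(shiftable), replace = TRUE)
    sh_close <- 10L * sample(-12:6, length(shiftable), replace = TRUE)
    open_sa[shiftable] <- pmin(pmax(open_wd[shiftable] + sh_open, 0L), 1430L)
    close_sa[shiftable] <- pmin(pmax(close_wd[shiftable] + sh_close, 0L), 1440L)
    # non-plain selected outlets flip kind on Saturday so they still differ
    flip <- setdiff(diff_idx, shiftable)
    open_sa[flip] <- grid10(600, 720, length(flip))
    close_sa[flip] <- grid10(1200, 1320, length(flip))
    bad <- open_sa >= close_sa & close_wd >= open_wd  # keep schedules simple
    close_sa[bad] <- pmin(open_sa[bad] + 480L, 1440L)

    open_su <- open_sa; close_su <- close_sa
    half <- diff_idx[seq_len(floor(length(diff_idx) / 2))]
    open_su[half] <- pmin(open_sa[half] + 60L, 1380L)
    close_su[half] <- pmax(pmin(close_sa[half] - 60L, 1440L), open_su[half] + 60L)
    closed_sun <- sample.int(n, max(0, round(0.1 * n)))
    open_su[closed_sun] <- NA_integer_; close_su[closed_sun] <- NA_integer_

    out <- tibble::tibble(
      outlet_id = sprintf("O%04d", seq_len(n)),
      x = x, y = y,
      category = sample(c("fast_food", "convenience", "pizzeria", "bakery",
                          "candy", "meat_market"), n, replace = TRUE),
      open_weekday = open_wd, close_weekday = close_wd,
      open_saturday = open_sa, close_saturday = close_sa,
      open_sunday = open_su, close_sunday = close_su
    )
    class(out) <- c("outlet_registry", class(out))
    out
  })
}

#' Generate synthetic raw GPS tables
#'
#' Per participant, `n_days` of nominal 1-min fixes following a
#' home-work-errand anchor routine with travel at bounded speed and bounded
#' uniform jitter, plus GPS dropouts drawn from the scenario's gap model.
#' When gaps are enabled, one gap of each class — stationary endpoints
#' < 30 m apart, sub-hour with endpoints >= 30 m apart, and > 1 h — is
#' always present. A `poor_wear_frac` subset of participants records too
#' little data to pass the valid-participant screen.
#'
#' @param scenario A [synth_scenario()].
#' @return A raw GPS tibble (`participant_id`, `time`, `date`, `day_type`,
#'   `x`, `y`) as returned by [as_gps_table()].
#' @export
make_trajectories <- function(scenario) {
  stopifnot(inherits(scenario, "synth_scenario"))
  cfg <- scenario$config
  ext <- cfg$grid_extent
  w <- ext[3] - ext[1]; h <- ext[4] - ext[2]
  np <- scenario$n_participants
  dates <- scenario$start_date + seq_len(scenario$n_days) - 1
  dtypes <- day_type_of(dates)

  withr::with_seed(substream_seed(scenario$seed, "trajectories"), {
    # anchors: homes anywhere, work near the corridor cross, errands near
    # the corridors for "food-prone" participants, elsewhere for the rest
    home <- cbind(ext[1] + stats::runif(np, 0.05, 0.95) * w,
                  ext[2] + stats::runif(np, 0.05, 0.95) * h)
    work <- cbind(ext[1] + 0.6 * w + stats::rnorm(np, 0, 0.1 * w),
                  ext[2] + 0.4 * h + stats::rnorm(np, 0, 0.1 * h))
    prone <- stats::runif(np) < 0.5
    errand <- cbind(
      ifelse(prone, ext[1] + stats::runif(np, 0.45, 0.75) * w,
             ext[1] + stats::runif(np, 0.05, 0.95) * w),
      ifelse(prone, ext[2] + stats::runif(np, 0.30, 0.50) * h,
             ext[2] + stats::runif(np, 0.05, 0.95) * h))
    clamp <- function(p) cbind(pmin(pmax(p[, 1], ext[1]), ext[3]),
                               pmin(pmax(p[, 2], ext[2]), ext[4]))
    work <- clamp(work); errand <- clamp(errand)

    n_poor <- round(scenario$poor_wear_frac * np)
    poor <- if (n_poor > 0) sample.int(np, n_poor) else integer(0)
    wk_idx <- which(dtypes == "weekday")
    sat_idx <- which(dtypes == "saturday")
    # poor wearers keep full data on too few days to pass the 5+2 screen
    poor_full_days <- c(wk_idx[seq_len(min(3, length(wk_idx)))],
                        sat_idx[seq_len(min(1, length(sat_idx)))])

    nd <- scenario$n_days
    day0 <- as.numeric(as.POSIXct(dates, tz = "UTC"))
    tt <- vector("list", np * nd); xx <- tt; yy <- tt
    nper <- integer(np)
    for (p in seq_len(np)) {
      for (d in seq_len(nd)) {
        pos <- simulate_day(scenario, home[p, ], work[p, ], errand[p, ],
                            dtypes[d])
        keep <- seq_len(1440)
        if (p %in% poor && !(d %in% poor_full_days)) keep <- 1:300
        force_class <- if (scenario$gap_model$enabled && p == 1 && d <= 3 &&
                             dtypes[d] == "weekday") c("a", "b", "c")[d] else NULL
        keep <- inject_gaps(scenario, keep, pos, force_class)
        k <- (p - 1) * nd + d
        tt[[k]] <- day0[d] + (keep - 1) * 60
        xx[[k]] <- pos$x[keep]; yy[[k]] <- pos$y[keep]
        nper[p] <- nper[p] + length(keep)
      }
    }
    gps <- tibble::tibble(
      participant_id = rep(sprintf("P%03d", seq_len(np)), nper),
      time = as.POSIXct(unlist(tt), tz = "UTC", origin = "1970-01-01"),
      x = unlist(xx), y = unlist(yy))
    suppressWarnings(as_gps_table(gps))
  })
}

# One day of 1440 per-minute positions from a keyframe itinerary.
simulate_day <- function(scenario, home, work, errand, day_type) {
  speed <- function() stats::runif(1, scenario$speed_range[1], scenario$speed_range[2])
  key_t <- 0; key_x <- home[1]; key_y <- home[2]
  add_leg <- function(t_depart, to) {
    from <- c(key_x[length(key_x)], key_y[length(key_y)])
    t_depart <- max(t_depart, key_t[length(key_t)] + 1)
    dur <- max(1, ceiling(sqrt(sum((to - from)^2)) / speed()))
    key_t <<- c(key_t, t_depart, t_depart + dur)
    key_x <<- c(key_x, from[1], to[1])
    key_y <<- c(key_y, from[2], to[2])
    t_depart + dur
  }
  if (day_type == "weekday") {
    t <- add_leg(480 + sample(-30:30, 1), work)
    if (stats::runif(1) < scenario$p_lunch_errand) {
      t <- add_leg(720 + sample(0:20, 1), errand)
      t <- add_leg(t + 30, work)
    }
    t <- add_leg(1020 + sample(-20:40, 1), home)
    if (stats::runif(1) < scenario$p_evening_errand) {
      t <- add_leg(1140 + sample(0:30, 1), errand)
      t <- add_leg(t + sample(20:40, 1), home)
    }
  } else {
    t <- add_leg(600 + sample(-60:60, 1), errand)
    t <- add_leg(t + sample(40:90, 1), home)
    if (stats::runif(1) < 0.5) {
      t <- add_leg(900 + sample(0:60, 1), errand)
      t <- add_leg(t + sample(30:60, 1), home)
    }
  }
  key_t <- c(key_t, 1439)
  key_x <- c(key_x, key_x[length(key_x)])
  key_y <- c(key_y, key_y[length(key_y)])
  ok <- !duplicated(key_t)
  xs <- stats::approx(key_t[ok], key_x[ok], xout = 0:1439, rule = 2)$y
  ys <- stats::approx(key_t[ok], key_y[ok], xout = 0:1439, rule = 2)$y
  j <- scenario$jitter
  list(x = xs + stats::runif(1440, -j, j),
       y = ys + stats::runif(1440, -j, j),
       key_t = key_t[ok])
}

# Drop minute indices from `keep` according to the gap model. Gap classes:
# a = stationary endpoints (< 30 m), 2-10 min; b = spans a travel leg
# (endpoints >= 30 m), < 1 h; c = 70-150 min (not imputable).
inject_gaps <- function(scenario, keep, pos, force_class = NULL) {
  gm <- scenario$gap_model
  if (!gm$enabled || length(keep) < 400) return(keep)
  full <- length(keep) == 1440
  drop <- integer(0)
  legs <- travel_windows(pos$key_t)
  want <- c(
    if ((full && stats::runif(1) < gm$p_short) || "a" %in% force_class) "a",
    if ((full && stats::runif(1) < gm$p_travel) || "b" %in% force_class) "b",
    if ((full && stats::runif(1) < gm$p_long) || "c" %in% force_class) "c")
  for (cl in want) {
    if (cl == "a") {
      start <- sample(120:360, 1)              # night-time, stationary at home
      len <- sample(2:10, 1)
      drop <- c(drop, start:(start + len - 1))
    } else if (cl == "b" && nrow(legs) > 0) {
      # first leg (in random order) whose window is sub-hour and whose
      # endpoints are genuinely far apart
      for (li in sample.int(nrow(legs))) {
        leg <- legs[li, ]
        lo <- max(2, leg$from); hi <- min(1438, leg$to + 2)
        far <- sqrt((pos$x[hi + 2] - pos$x[lo])^2 +
                      (pos$y[hi + 2] - pos$y[lo])^2) >= 50
        if (hi - lo + 1 < 59 && far) {
          drop <- c(drop, lo:hi)
          break
        }
      }
    } else if (cl == "c") {
      start <- sample(1260:1300, 1)            # late evening at home
      len <- sample(70:130, 1)
      drop <- c(drop, start:min(start + len - 1, 1438))
    }
  }
  setdiff(keep, drop + 1L)  # minute m lives at index m + 1
}

travel_windows <- function(key_t) {
  # keyframes alternate stay/move; moves are (t_depart, t_arrive) pairs
  if (length(key_t) < 3) return(tibble::tibble(from = integer(0), to = integer(0)))
  starts <- key_t[seq(2, length(key_t) - 1, by = 2)]
  ends <- key_t[seq(3, length(key_t), by = 2)]
  n <- min(length(starts), length(ends))
  tibble::tibble(from = round(starts[seq_len(n)]), to = round(ends[seq_len(n)]))
}

#' Generate participant covariates and overweight outcomes
#'
#' Covariate categories follow the reference cohort's composition (61%
#' female; age bands 18-30 / 31-65 / 65+ at 57/41/2%; 57% with a college
#' degree). Overweight status is drawn Bernoulli with
#' `logit(p) = intercept + b_exposure * z(exposure) + covariate effects`,
#' and a BMI value consistent with the flag is attached (>= 25 when
#' overweight).
#'
#' @param scenario A [synth_scenario()].
#' @param true_exposure Tibble with `participant_id` and `exposure` (the
#'   data-generating exposure, one row per participant), or a named vector.
#' @return A tibble: `participant_id`, `gender`, `age_group`, `education`,
#'   `bmi`, `overweight` (0/1), `p_true` (the generating probability).
#' @export
make_outcomes <- function(scenario, true_exposure) {
  stopifnot(inherits(scenario, "synth_scenario"))
  if (is.data.frame(true_exposure)) {
    ids <- as.character(true_exposure$participant_id)
    expo <- as.numeric(true_exposure$exposure)
  } else {
    ids <- names(true_exposure); expo <- as.numeric(true_exposure)
  }
  stopifnot(length(ids) == length(expo), !anyNA(expo))
  b <- scenario$outcome_model
  z <- if (stats::sd(expo) > 0) (expo - mean(expo)) / stats::sd(expo) else expo * 0
  n <- length(ids)
  withr::with_seed(substream_seed(scenario$seed, "outcomes"), {
    gender <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.61, 0.39))
    age_group <- sample(c("18-30", "31-65", "65+"), n, replace = TRUE,
                        prob = c(0.565, 0.413, 0.022))
    education <- sample(c("college", "no_college"), n, replace = TRUE,
                        prob = c(0.565, 0.435))
    eta <- b[["intercept"]] + b[["exposure"]] * z +
      b[["female"]] * (gender == "female") +
      b[["age31_65"]] * (age_group == "31-65") +
      b[["age65p"]] * (age_group == "65+") +
      b[["college"]] * (education == "college")
    p <- stats::plogis(eta)
    overweight <- stats::rbinom(n, 1, p)
    bmi <- ifelse(overweight == 1,
                  25 + abs(stats::rnorm(n, 3.5, 2.5)),
                  25 - abs(stats::rnorm(n, 2.5, 1.6)) - 0.1)
    tibble::tibble(participant_id = ids, gender = gender,
                   age_group = age_group, education = education,
                   bmi = round(bmi, 1), overweight = overweight, p_true = p)
  })
}
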