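# Independent brute-force oracles. These deliberately re-derive results by
# the most direct method available (double loops, all-pairs scans, textbook
# formulas) and never call the package's optimised paths.

# decay layer by explicit double loop over cells x outlets
oracle_layer <- function(open_xy, method, scale, geom) {
  cx <- geom$xmin + (seq_len(geom$nx) - 0.5) * geom$cell_size
  cy <- geom$ymin + (seq_len(geom$ny) - 0.5) * geom$cell_size
  g <- matrix(0, geom$ny, geom$nx)
  for (i in seq_len(geom$ny)) {
    for (j in seq_len(geom$nx)) {
      v <- 0
      for (k in seq_len(nrow(open_xy))) {
        d <- sqrt((cx[j] - open_xy$x[k])^2 + (cy[i] - open_xy$y[k])^2)
        v <- v + switch(method,
                        KD = if (d < scale)
                          3 / (pi * scale^2) * (1 - (d / scale)^2)^2 else 0,
                        ISDD = 1 / (1 + (d / scale)^2),
                        NEDD = exp(-d / scale))
      }
      g[i, j] <- v
    }
  }
  g
}

# tunnel x cloud intersection by an all-points x all-days distance check,
# with its own linear interpolation between bracketing fixes
oracle_intersect <- function(day_tabs, cloud, br) {
  hits <- list()
  for (nm in names(day_tabs)) {
    d <- day_tabs[[nm]]
    for (p in seq_len(nrow(cloud))) {
      t <- cloud$t[p]
      lo <- max(which(d$minute <= t), -Inf)
      hi <- min(which(d$minute >= t), Inf)
      if (!is.finite(lo) || !is.finite(hi)) next
      if (d$minute[hi] - d$minute[lo] > 1 + 1e-9) next  # inside a real gap
      if (lo == hi) {
        px <- d$x[lo]; py <- d$y[lo]
      } else {
        f <- (t - d$minute[lo]) / (d$minute[hi] - d$minute[lo])
        px <- d$x[lo] + f * (d$x[hi] - d$x[lo])
        py <- d$y[lo] + f * (d$y[hi] - d$y[lo])
      }
      if ((cloud$x[p] - px)^2 + (cloud$y[p] - py)^2 <= br^2 + 1e-9) {
        hits[[length(hits) + 1]] <-
          data.frame(day = nm, x = cloud$x[p], y = cloud$y[p], t = t,
                     value = cloud$value[p])
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(day = character(0), x = numeric(0), y = numeric(0),
                      t = numeric(0), value = numeric(0)))
  }
  do.call(rbind, hits)
}

# convex hull by gift wrapping (Jarvis march), independent of grDevices
oracle_hull <- function(x, y) {
  n <- length(x)
  start <- which.min(x + 1e-12 * y)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (k in seq_len(n)) {
      if (k == cur || k == cand) next
      cr <- (x[cand] - x[cur]) * (y[k] - y[cur]) -
        (y[cand] - y[cur]) * (x[k] - x[cur])
      d_cand <- (x[cand] - x[cur])^2 + (y[cand] - y[cur])^2
      d_k <- (x[k] - x[cur])^2 + (y[k] - y[cur])^2
      if (cr < 0 || (abs(cr) < 1e-9 && d_k > d_cand)) cand <- k
    }
    cur <- cand
    if (cur == start) break
  }
  hull
}

# even-odd ray casting on a closed polygon (matrix of x, y vertices)
oracle_ray_cast <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  for (q in seq_along(px)) {
    cnt <- 0
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1 else k + 1
      y1 <- poly[k, 2]; y2 <- poly[k2, 2]
      if ((y1 > py[q]) != (y2 > py[q])) {
        xint <- poly[k, 1] + (py[q] - y1) / (y2 - y1) *
          (poly[k2, 1] - poly[k, 1])
        if (px[q] < xint) cnt <- cnt + 1
      }
    }
    inside[q] <- cnt %% 2 == 1
  }
  inside
}

# textbook Pearson r and its t-based two-sided p-value
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}
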