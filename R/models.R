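#' Pearson correlations between exposure measures
#'
#' Bivariate Pearson correlation (with two-sided p-values) between every
#' pair of exposure measures across participants.
#'
#' @param exposures Long tibble with `participant_id`, `method_key` and the
#'   value column `value_col` (default `"exposure_z"`).
#' @param value_col Column to correlate.
#' @return A tibble with one row per unordered pair: `method_a`,
#'   `method_b`, `r`, `p`, `n`. Pairs involving a constant measure get
#'   `r = NA`. The full correlation matrix is attached as attribute
#'   `"matrix"`.
#' @export
correlate_measures <- function(exposures, value_col = "exposure_z") {
  wide <- tidyr::pivot_wider(
    dplyr::select(exposures, "participant_id", "method_key",
                  dplyr::all_of(value_col)),
    names_from = "method_key", values_from = dplyr::all_of(value_col))
  keys <- setdiff(names(wide), "participant_id")
  if (length(keys) < 2 || nrow(wide) < 3) {
    stop("correlation needs >= 2 measures and >= 3 participants", call. = FALSE)
  }
  m <- as.matrix(wide[keys])
  cmat <- matrix(NA_real_, length(keys), length(keys),
                 dimnames = list(keys, keys))
  diag(cmat) <- 1
  rows <- list()
  for (a in seq_along(keys)) {
    for (b in seq_along(keys)) {
      if (b <= a) next
      xa <- m[, a]; xb <- m[, b]
      ok <- stats::sd(xa) > 0 && stats::sd(xb) > 0
      if (ok) {
        ct <- stats::cor.test(xa, xb)
        r <- unname(ct$estimate); p <- ct$p.value
      } else {
        r <- NA_real_; p <- NA_real_
      }
      cmat[a, b] <- cmat[b, a] <- r
      rows[[length(rows) + 1]] <- tibble::tibble(
        method_a = keys[a], method_b = keys[b], r = r, p = p, n = nrow(m))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "matrix") <- cmat
  out
}

#' Fit one exposure-overweight logistic model
#'
#' Binary logistic regression of overweight status on one standardised
#' exposure measure, adjusted for gender (reference male), age band
#' (reference 18-30) and education (reference below college). Reports AIC,
#' Nagelkerke R-squared, the likelihood-ratio chi-square against the
#' intercept-only model, and the exposure odds ratio with its 95% Wald CI.
#'
#' @param data A data frame with columns `overweight` (0/1; derived from
#'   `bmi >= 25` when absent), `exposure_z`, `gender`, `age_group`,
#'   `education`.
#' @param model_key Label for the fitted model.
#' @param null_model `"intercept"` (default: the LR test measures the whole
#'   model) or `"covariates"` (LR isolates the exposure term).
#' @return An object of class `exposure_model`.
#' @export
fit_logit <- function(data, model_key = "exposure",
                      null_model = c("intercept", "covariates")) {
  null_model <- match.arg(null_model)
  df <- as.data.frame(data)
  if (!"overweight" %in% names(df)) {
    if (!"bmi" %in% names(df)) {
      stop("data needs an overweight flag or a bmi column", call. = FALSE)
    }
    df$overweight <- dichotomize_bmi(df$bmi)
  }
  stopifnot(all(df$overweight %in% 0:1))
  df$gender <- stats::relevel(factor(df$gender, c("male", "female")), "male")
  df$age_group <- stats::relevel(
    factor(df$age_group, c("18-30", "31-65", "65+")), "18-30")
  df$education <- stats::relevel(
    factor(df$education, c("no_college", "college")), "no_college")
  rhs <- c("exposure_z",
           if (dplyr::n_distinct(df$gender) > 1) "gender",
           if (dplyr::n_distinct(df$age_group) > 1) "age_group",
           if (dplyr::n_distinct(df$education) > 1) "education")
  form <- stats::reformulate(rhs, response = "overweight")
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = df))
  covars <- setdiff(rhs, "exposure_z")
  null_form <- if (null_model == "intercept" || length(covars) == 0)
    overweight ~ 1 else stats::reformulate(covars, response = "overweight")
  fit0 <- stats::glm(null_form, family = stats::binomial(), data = df)

  n <- nrow(df)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(fit0))
  lr <- max(0, 2 * (ll1 - ll0))
  lr_df <- length(stats::coef(fit)) - length(stats::coef(fit0))
  r2_cs <- 1 - exp(2 / n * (ll0 - ll1))
  denom <- 1 - exp(2 / n * ll0)
  r2_n <- if (denom > 0) r2_cs / denom else NA_real_
  cf <- summary(fit)$coefficients
  if ("exposure_z" %in% rownames(cf)) {
    be <- cf["exposure_z", "Estimate"]
    se <- cf["exposure_z", "Std. Error"]
    p_exp <- cf["exposure_z", "Pr(>|z|)"]
    # separation on the exposure term itself (a sparse covariate cell, e.g.
    # a single 65+ participant, should not suppress the exposure OR)
    separated <- !fit$converged || abs(be) > 15 || se > 50
  } else {
    # exposure aliased (constant): no OR is estimable
    be <- NA_real_; se <- NA_real_; p_exp <- NA_real_
    separated <- TRUE
  }
  structure(list(
    model_key = model_key, fit = fit, n = n,
    aic = stats::AIC(fit),
    nagelkerke_r2 = r2_n,
    lr_chi2 = lr, lr_df = lr_df,
    lr_p = stats::pchisq(lr, lr_df, lower.tail = FALSE),
    or_exposure = if (separated) NA_real_ else exp(be),
    or_ci = if (separated) c(NA_real_, NA_real_) else
      exp(be + c(-1, 1) * 1.96 * se),
    p_exposure = p_exp,
    separated = separated,
    null_model = null_model),
    class = "exposure_model")
}

#' Dichotomise BMI into overweight status
#'
#' @param bmi BMI in kg/m2.
#' @return Integer 0/1; 1 when `bmi >= 25.0`.
#' @export
dichotomize_bmi <- function(bmi) as.integer(bmi >= 25.0)

#' @export
print.exposure_model <- function(x, ...) {
  cat("<exposure_model>", x$model_key,
      sprintf("| n=%d AIC=%.3f NagR2=%.4f LRchi2=%.3f (df=%d, p=%.3g)",
              x$n, x$aic, x$nagelkerke_r2, x$lr_chi2, x$lr_df, x$lr_p), "\n")
  if (x$separated) {
    cat("  [!] separation detected; exposure OR not reported\n")
  } else {
    cat(sprintf("  exposure OR %.2f (95%% CI %.2f-%.2f), p=%.3g\n",
                x$or_exposure, x$or_ci[1], x$or_ci[2], x$p_exposure))
  }
  invisible(x)
}

#' @export
tidy.exposure_model <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    model_key = x$model_key,
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    statistic = cf[, "z value"],
    p_value = cf[, "Pr(>|z|)"],
    odds_ratio = exp(cf[, "Estimate"]),
    or_low = exp(cf[, "Estimate"] - 1.96 * cf[, "Std. Error"]),
    or_high = exp(cf[, "Estimate"] + 1.96 * cf[, "Std. Error"]))
}

#' @export
glance.exposure_model <- function(x, ...) {
  tibble::tibble(model_key = x$model_key, n = x$n, aic = x$aic,
                 nagelkerke_r2 = x$nagelkerke_r2, lr_chi2 = x$lr_chi2,
                 lr_df = x$lr_df, lr_p = x$lr_p,
                 or_exposure = x$or_exposure,
                 or_low = x$or_ci[1], or_high = x$or_ci[2],
                 p_exposure = x$p_exposure, separated = x$separated)
}

#' Combine dynamic and activity-space exposure tables
#'
#' Stacks [compute_ecei()] output and [activity_space_exposures()] output
#' into one long table with a common `exposure_z` column.
#'
#' @param ecei_tbl Output of [compute_ecei()].
#' @param space_tbl Output of [activity_space_exposures()].
#' @return Tibble: `participant_id`, `method_key`, `exposure_raw`,
#'   `exposure_z`.
#' @export
combine_exposures <- function(ecei_tbl, space_tbl) {
  dplyr::bind_rows(
    dplyr::transmute(ecei_tbl, .data$participant_id, .data$method_key,
                     exposure_raw = .data$ecei_raw,
                     exposure_z = .data$ecei_z),
    dplyr::transmute(space_tbl, .data$participant_id, .data$method_key,
                     exposure_raw = .data$density_raw,
                     exposure_z = .data$density_z))
}

#' Run the full 22-model comparison
#'
#' Fits one adjusted logistic model per exposure measure — the 18 cube-based
#' ECEI keys (3 decay methods x 3 cell sizes x 2 temporal resolutions) and
#' the 4 activity-space comparators — and ranks them by AIC.
#'
#' @param exposures Long exposure table from [combine_exposures()] (or of
#'   the same shape).
#' @param participants Covariate/outcome table (see [make_outcomes()]).
#' @param expected_keys Method keys that must all be present (default: the
#'   full 18 + 4 menu). Pass `NULL` to fit whatever is present.
#' @param null_model Passed to [fit_logit()].
#' @param include_fits Keep the `exposure_model` objects in a list-column.
#' @return A tibble of class `model_comparison`, one row per model with the
#'   [glance.exposure_model()] columns plus `rank` (1 = lowest AIC),
#'   ordered by AIC.
#' @export
run_model_comparison <- function(exposures, participants,
                                 expected_keys = default_model_keys(),
                                 null_model = "intercept",
                                 include_fits = FALSE) {
  present <- unique(exposures$method_key)
  if (!is.null(expected_keys)) {
    miss <- setdiff(expected_keys, present)
    if (length(miss) > 0) {
      stop("exposure table is missing method key(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    present <- expected_keys
  }
  fits <- lapply(present, function(key) {
    sub <- exposures[exposures$method_key == key, , drop = FALSE]
    df <- dplyr::inner_join(sub, participants, by = "participant_id")
    model_key <- if (key %in% c("GTB", "MCP", "SDE1", "SDE2"))
      paste0("M-", key) else key
    fit_logit(df, model_key = model_key, null_model = null_model)
  })
  out <- dplyr::bind_rows(lapply(fits, glance.exposure_model))
  out <- dplyr::arrange(out, .data$aic)
  out$rank <- seq_len(nrow(out))
  if (include_fits) {
    out$fit <- fits[match(out$model_key,
                          purrr::map_chr(fits, "model_key"))]
  }
  class(out) <- c("model_comparison", class(out))
  out
}

#' The full 22-key model menu
#'
#' @param methods,cell_sizes,slot_minutes Cube menu components.
#' @return Character vector of 18 cube keys plus GTB/MCP/SDE1/SDE2.
#' @export
default_model_keys <- function(methods = c("KD", "ISDD", "NEDD"),
                               cell_sizes = c(100, 150, 200),
                               slot_minutes = c(10, 30)) {
  cube_keys <- as.vector(outer(
    as.vector(outer(methods, cell_sizes, paste0)),
    slot_minutes, function(a, b) paste0(a, "T", b)))
  c(sort(cube_keys), "GTB", "MCP", "SDE1", "SDE2")
}

#' @export
autoplot.model_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$model_key <- stats::reorder(df$model_key, -df$aic)
  df$family <- ifelse(grepl("^M-", df$model_key), "activity space",
                      sub("^([A-Z]+).*", "\\1", df$model_key))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aic, y = .data$model_key,
                                   colour = .data$family)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "AIC (lower is better)", y = NULL, colour = NULL,
                  title = "Exposure-model comparison")
}

#' Plot cohort exposure profiles
#'
#' Standardised exposure per participant for a set of measures, one line
#' per measure — the cohort-level view of how strongly the measures
#' disagree.
#'
#' @param exposures Long exposure table (`participant_id`, `method_key`,
#'   `exposure_z`).
#' @param keys Measures to show (default: all present).
#' @return A ggplot.
#' @export
plot_exposures <- function(exposures, keys = NULL) {
  df <- tibble::as_tibble(exposures)
  if (!is.null(keys)) df <- df[df$method_key %in% keys, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$participant_id,
                                   y = .data$exposure_z,
                                   colour = .data$method_key,
                                   group = .data$method_key)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "participant", y = "standardised exposure (z)",
                  colour = NULL)
}
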