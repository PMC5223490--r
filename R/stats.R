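#' Average left/right knees of the same subject
#'
#' For subjects contributing both knees, results are averaged per VOI (and
#' per modality, if present) before any further analysis; subjects with a
#' single knee pass through unchanged.
#'
#' @param results data.frame with columns `subject`, `side` and any numeric
#'   result columns; optional grouping columns `voi_name` and `modality` are
#'   respected.
#' @return data.frame with one row per subject (x VOI x modality), numeric
#'   columns averaged.
#' @export
average_paired_sides <- function(results) {
  stopifnot(is.data.frame(results))
  if (!all(c("subject", "side") %in% names(results)))
    stop("`results` needs `subject` and `side` columns", call. = FALSE)
  keys <- intersect(c("subject", "voi_name", "modality"), names(results))
  kf <- interaction(c(results[c(keys, "side")]), drop = TRUE)
  if (anyDuplicated(kf))
    stop("duplicate side for a subject (same subject/side/VOI appears twice)",
         call. = FALSE)
  num <- names(results)[vapply(results, is.numeric, logical(1))]
  agg <- stats::aggregate(results[num], by = results[keys], FUN = mean)
  agg[do.call(order, agg[keys]), , drop = FALSE]
}

#' Ordinary least-squares regression between two modalities
#'
#' Slope, intercept, R-squared and the two-sided p-value for slope != 0 of
#' `y ~ x`. A constant `y` yields slope 0 and, by convention, R-squared 0
#' and p-value 1.
#'
#' @param x,y numeric series of equal length >= 3; `x` must vary.
#' @return list of class `regression_result` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("degenerate x: no variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r2 <- 0
    p <- 1
  } else {
    r2 <- 1 - ssr / sst
    p <- if (ssr <= 1e-12 * sst) 0 else summary(fit)$coefficients[2, 4]
  }
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, p_value = p, n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("R^2 = %.3f (p = %.3g) [slope %.4g, intercept %.4g], n = %d\n",
              x$r_squared, x$p_value, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = a - b`; `mean_diff = mean(d)`; limit of agreement
#' `loa = 1.96 * sd(d)` (population SD, the package-wide convention); and the
#' percent error `pct_err = loa / reference_mean` (the reference is the mean
#' of the higher-resolution series by convention).
#'
#' @param a,b paired numeric series of equal length >= 2.
#' @param reference_mean scalar reference for the percent error (e.g. the
#'   mean of the HR-pQCT series).
#' @return list of class `bland_altman_result` with `mean_diff`, `loa`,
#'   `pct_err`, `n`, and `within_loa` (logical per pair: inside
#'   `mean_diff +/- loa`).
#' @export
bland_altman <- function(a, b, reference_mean) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("series must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  loa <- 1.96 * sqrt(mean((d - md)^2))
  structure(list(mean_diff = md, loa = loa,
                 pct_err = if (reference_mean != 0) loa / reference_mean else NA_real_,
                 n = length(d),
                 within_loa = d >= md - loa - 1e-12 & d <= md + loa + 1e-12),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("mean diff %.4g, LOA %.4g (pct err %.3g), n = %d, %d outlier(s)\n",
              x$mean_diff, x$loa, x$pct_err, x$n, sum(!x$within_loa)))
  invisible(x)
}

#' Resolution-dependence ratio D
#'
#' `D = TP_hr / TP_ct` for a texture parameter measured on the same anatomy
#' at the two resolutions; D = 1 means the parameter does not depend on
#' spatial resolution in the investigated range.
#'
#' @param tp_hr,tp_ct parameter values (vectors of equal length); `tp_ct`
#'   must be non-zero.
#' @param parameter,voi_name optional labels carried through.
#' @return data.frame with columns `parameter`, `voi_name`, `d`.
#' @export
resolution_dependence <- function(tp_hr, tp_ct, parameter = NA_character_,
                                  voi_name = NA_character_) {
  tp_hr <- as.numeric(tp_hr)
  tp_ct <- as.numeric(tp_ct)
  if (length(tp_hr) != length(tp_ct)) stop("equal lengths required", call. = FALSE)
  if (any(tp_ct == 0)) stop("undefined ratio: tp_ct contains zero", call. = FALSE)
  data.frame(parameter = parameter, voi_name = voi_name, d = tp_hr / tp_ct,
             stringsAsFactors = FALSE)
}

#' Two-stage summary of D ratios
#'
#' Averages the per-VOI D values within each case (the 12 trabecular VOIs;
#' cortical VOIs are excluded from D by contract), then across cases; the SD
#' is taken across the per-case means (population convention).
#'
#' @param per_case data.frame with columns `case`, `voi_name`, `parameter`,
#'   `d`. Rows whose VOI layer is `cortical` raise an error.
#' @return data.frame with one row per parameter: `parameter`, `mean_d`,
#'   `sd_d`, `n_cases`.
#' @export
d_summary <- function(per_case) {
  stopifnot(is.data.frame(per_case))
  need <- c("case", "voi_name", "parameter", "d")
  if (!all(need %in% names(per_case)))
    stop("`per_case` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  layer <- parse_voi_name(per_case$voi_name)$layer
  if (any(layer == "cortical"))
    stop("contract error: cortical VOIs must be excluded from D summaries",
         call. = FALSE)
  within <- stats::aggregate(d ~ parameter + case, data = per_case, FUN = mean)
  out <- do.call(rbind, lapply(split(within, within$parameter), function(g) {
    mu <- mean(g$d)
    data.frame(parameter = g$parameter[1], mean_d = mu,
               sd_d = sqrt(mean((g$d - mu)^2)), n_cases = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Levene/Brown-Forsythe test for homogeneity of variances of two samples:
# one-way ANOVA F on the absolute deviations from each group's center.
levene_test <- function(x, y, center = stats::median) {
  zx <- abs(x - center(x))
  zy <- abs(y - center(y))
  nx <- length(zx)
  ny <- length(zy)
  zbar <- mean(c(zx, zy))
  num <- (nx * (mean(zx) - zbar)^2 + ny * (mean(zy) - zbar)^2) / 1
  den <- (sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)) / (nx + ny - 2)
  f <- num / den
  p <- stats::pf(f, 1, nx + ny - 2, lower.tail = FALSE)
  list(statistic = f, p_value = p)
}

#' Compare D ratios between the digital models and a second sample
#'
#' Two-sample Student's t test (pooled variance by default, matching a
#' workflow that checks variance homogeneity with Levene's test first),
#' together with Shapiro-Wilk normality checks per sample and a
#' Levene/Brown-Forsythe variance-homogeneity check. The conventional 0.05
#' significance threshold is reported alongside the p-values, never applied
#' silently.
#'
#' @param model_d,cadaver_d numeric series, each of length >= 3.
#' @param var_equal pooled-variance Student's t (`TRUE`, default) or Welch.
#' @return list with `t_p`, `t_statistic`, `normal_p` (length 2), `normal_ok`,
#'   `var_p`, `var_ok`, `alpha`.
#' @export
group_comparison <- function(model_d, cadaver_d, var_equal = TRUE) {
  x <- as.numeric(model_d)
  y <- as.numeric(cadaver_d)
  if (length(x) < 3L || length(y) < 3L)
    stop("each series needs at least 3 values", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = var_equal)
  sw <- function(v) if (stats::sd(v) == 0) NA_real_ else stats::shapiro.test(v)$p.value
  np <- c(model = sw(x), cadaver = sw(y))
  lv <- levene_test(x, y)
  list(t_p = unname(tt$p.value), t_statistic = unname(tt$statistic),
       normal_p = np, normal_ok = !is.na(np) & np > 0.05,
       var_p = lv$p_value, var_ok = !is.na(lv$p_value) && lv$p_value > 0.05,
       alpha = 0.05)
}
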