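#' Fit a power law S = c * X^b by log-log least squares
#'
#' Ordinary least squares of `log10(S)` on `log10(X)`; the exponent is the
#' slope and `c = 10^intercept`. This is the convention of the
#' species-area/species-time literature (regression statistics refer to
#' the log-log fit, not nonlinear least squares). A response with zero
#' variance on the log scale yields exponent 0 with `r_squared = 0` and
#' undefined F/p.
#'
#' @param x Either an `str_curve` (spans and S are taken from its points)
#'   or a positive numeric vector of predictor values (time span, area,
#'   volume).
#' @param y Positive numeric response (richness); ignored when `x` is an
#'   `str_curve`.
#' @param unit For `str_curve` input: `"censuses"` (span = 1, 2, ... n) or
#'   `"days"` (span = mean day extent + the island's median inter-census
#'   gap, so single-census windows have positive span).
#' @param include_span1 Keep the single-census point in the fit
#'   (default TRUE).
#' @return An object of class `power_law_fit`: `coefficient_c`, `exponent`,
#'   `intercept`, `r_squared`, `f_statistic`, `df_num`, `df_den`,
#'   `p_value`, `n_points`, `degenerate` (TRUE when fewer than 3 points),
#'   plus `island_id`/`method` when fitted from a curve.
#' @export
#' @examples
#' f <- fit_power_law(1:10, 2 * (1:10)^0.5)
#' c(f$coefficient_c, f$exponent)
fit_power_law <- function(x, y = NULL, unit = c("censuses", "days"),
                          include_span1 = TRUE) {
  unit <- match.arg(unit)
  island_id <- NA_character_
  method <- NA_character_
  if (inherits(x, "str_curve")) {
    island_id <- x$island_id
    method <- x$method
    pts <- x$points
    if (!include_span1) pts <- pts[pts$span > 1L, , drop = FALSE]
    y <- pts$S
    x <- if (unit == "censuses") pts$span
         else pts$span_days_mean + stats::median(diff(pts$span_days_mean))
  }
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fitting needs strictly positive coordinates")
  fit <- ols_summary(log10(x), log10(y))
  structure(
    list(island_id = island_id, method = method,
         coefficient_c = 10^fit$intercept, exponent = fit$slope,
         intercept = fit$intercept, r_squared = fit$r_squared,
         f_statistic = fit$f_statistic, df_num = fit$df_num,
         df_den = fit$df_den, p_value = fit$p_value,
         n_points = fit$n, degenerate = fit$n < 3L),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  lab <- if (!is.na(x$method)) paste0(" [", x$island_id, ", ", x$method, "]")
         else ""
  cat(sprintf("Power-law fit%s: S = %.4g * X^%.4g\n", lab,
              x$coefficient_c, x$exponent))
  cat(sprintf("  R2 = %.3f, F(%d,%d) = %.3g, p = %.3g, n = %d%s\n",
              x$r_squared, x$df_num, x$df_den, x$f_statistic, x$p_value,
              x$n_points, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# Simple-regression summary shared by fit_power_law and regress_pairs.
# Uses stats::lm; zero-variance responses get r_squared 0 and NA F/p.
ols_summary <- function(x, y) {
  n <- length(x)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  if (is.na(slope)) slope <- 0  # constant predictor
  intercept <- unname(stats::coef(fit)[1L])
  df_den <- n - 2L
  if (isTRUE(all.equal(stats::var(y), 0))) {
    r2 <- 0; f <- NA_real_; p <- NA_real_; slope <- 0
    intercept <- mean(y)
  } else {
    # noiseless synthetic curves fit exactly; the stats remain well defined
    s <- suppressWarnings(summary(fit))
    r2 <- s$r.squared
    if (!is.null(s$fstatistic)) {
      f <- unname(s$fstatistic[1L])
      p <- stats::pf(f, 1, df_den, lower.tail = FALSE)
    } else {
      f <- NA_real_; p <- NA_real_
    }
  }
  list(slope = slope, intercept = intercept, r_squared = r2,
       f_statistic = f, df_num = 1L, df_den = df_den, p_value = p, n = n)
}

#' Compare two sets of per-island scaling exponents by one-way ANOVA
#'
#' Tests whether the mean temporal scaling exponent differs between two STR
#' construction methods across the same islands. Alongside the F test
#' (df = 1, N - 2) the group means and sample SDs are returned, and the
#' proportion of variance explained is reported as eta-squared
#' (between-group SS / total SS).
#'
#' @param w_a,w_b Numeric vectors of per-island exponents; when named, the
#'   island name sets must match.
#' @param labels Length-2 character vector naming the two groups.
#' @return Object of class `group_comparison`: `labels`, `means`, `sds`,
#'   `f_statistic`, `df_num`, `df_den`, `p_value`, `eta_squared`, `n`.
#' @export
compare_exponent_sets <- function(w_a, w_b, labels = c("A", "B")) {
  if (length(w_a) != length(w_b))
    stop("exponent sets must cover the same islands")
  if (!is.null(names(w_a)) && !is.null(names(w_b)) &&
      !setequal(names(w_a), names(w_b)))
    stop("exponent sets must cover the same islands")
  g <- factor(rep(labels, c(length(w_a), length(w_b))), levels = labels)
  v <- c(w_a, w_b)
  # zero within-group variance (fully separated groups) is legitimate here
  an <- suppressWarnings(stats::anova(stats::lm(v ~ g)))
  ssb <- an[["Sum Sq"]][1L]
  ssw <- an[["Sum Sq"]][2L]
  f <- an[["F value"]][1L]
  p <- an[["Pr(>F)"]][1L]
  if (ssb + ssw == 0) { f <- 0; p <- 1 }  # identical groups
  structure(
    list(labels = labels,
         means = stats::setNames(c(mean(w_a), mean(w_b)), labels),
         sds = stats::setNames(c(stats::sd(w_a), stats::sd(w_b)), labels),
         f_statistic = f, df_num = an$Df[1L], df_den = an$Df[2L],
         p_value = p, eta_squared = ssb / (ssb + ssw),
         n = length(v)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: mean w = %.3f +/- %.3f;  %s: mean w = %.3f +/- %.3f\n",
              x$labels[1L], x$means[1L], x$sds[1L],
              x$labels[2L], x$means[2L], x$sds[2L]))
  cat(sprintf("  one-way ANOVA F(%d,%d) = %.3g, eta2 = %.2f, p = %.3g\n",
              x$df_num, x$df_den, x$f_statistic, x$eta_squared, x$p_value))
  invisible(x)
}

#' Simple regression between per-island quantities
#'
#' OLS of `y` on `x` with optional log10 transforms of either axis. Used
#' for turnover-versus-volume, process-frequency-versus-volume,
#' cross-method exponent, and duration/depth robustness regressions.
#'
#' @param x,y Paired per-island numeric vectors.
#' @param log_x,log_y Apply log10 to the axis (requires positive values).
#' @param labels Length-2 character: predictor and response names.
#' @return Object of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `df_num`, `df_den`, `p_value`, `n`,
#'   `labels`, `degenerate`.
#' @export
regress_pairs <- function(x, y, log_x = FALSE, log_y = FALSE,
                          labels = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must be paired by island")
  if (log_x) {
    if (any(x <= 0)) stop("log_x requested but x has non-positive values")
    x <- log10(x)
  }
  if (log_y) {
    if (any(y <= 0)) stop("log_y requested but y has non-positive values")
    y <- log10(y)
  }
  fit <- ols_summary(x, y)
  structure(c(fit[c("slope", "intercept", "r_squared", "f_statistic",
                    "df_num", "df_den", "p_value", "n")],
              list(labels = labels, degenerate = fit$n < 3L)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Regression %s ~ %s: slope = %.4g, R2 = %.3f, ",
              x$labels[2L], x$labels[1L], x$slope, x$r_squared))
  cat(sprintf("F(%d,%d) = %.3g, p = %.3g, n = %d%s\n",
              x$df_num, x$df_den, x$f_statistic, x$p_value, x$n,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Per-island summary of richness and size over census time
#'
#' Mean and sample SD of per-census richness, and of island size. When the
#' metadata carries per-census size SDs they are used; a single
#' measurement has SD 0.
#'
#' @param ts A [community_ts()] object.
#' @param meta One-row data frame with `area_cm2`, `volume_ml` and
#'   optionally `area_sd`, `volume_sd`.
#' @return Data frame with `island_id`, `richness_mean`, `richness_sd`,
#'   `area_mean`, `area_sd`, `volume_mean`, `volume_sd`.
#' @export
island_size_summary <- function(ts, meta) {
  rich <- colSums(ts$presence)
  data.frame(
    island_id = ts$island_id,
    richness_mean = mean(rich),
    richness_sd = stats::sd(rich),
    area_mean = meta$area_cm2,
    area_sd = if (!is.null(meta$area_sd)) meta$area_sd else 0,
    volume_mean = meta$volume_ml,
    volume_sd = if (!is.null(meta$volume_sd)) meta$volume_sd else 0)
}
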