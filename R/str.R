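#' Enumerate contiguous windows of a time series
#'
#' All contiguous windows of `span_k` censuses in an `n_censuses`-long
#' series: there are `n_censuses - span_k + 1` of them, e.g. a 20-census
#' series has 20 single-census windows, 19 two-census windows, 18
#' three-census windows, and so on.
#'
#' @param n_censuses Series length.
#' @param span_k Window extent in censuses, `1 <= span_k <= n_censuses`.
#' @return Integer matrix with one row per window and columns
#'   `start`, `end`.
#' @export
enumerate_windows <- function(n_censuses, span_k) {
  n_censuses <- as.integer(n_censuses)
  span_k <- as.integer(span_k)
  if (n_censuses < 1L) stop("n_censuses must be >= 1")
  if (span_k < 1L || span_k > n_censuses)
    stop("invalid span: span_k must be in [1, n_censuses]")
  start <- seq_len(n_censuses - span_k + 1L)
  cbind(start = start, end = start + span_k - 1L)
}

new_str_curve <- function(ts, method, span, S, span_days_mean, n_windows,
                          window_values = NULL) {
  stopifnot(all(S > 0), !is.unsorted(span, strictly = TRUE))
  structure(
    list(island_id = ts$island_id, method = method,
         points = data.frame(span = span, span_days_mean = span_days_mean,
                             S = S, n_windows = n_windows),
         window_values = window_values),
    class = "str_curve")
}

#' @export
print.str_curve <- function(x, ...) {
  cat("STR curve (", x$method, ") for island ", x$island_id, "\n", sep = "")
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Moving-window species-time curve
#'
#' Adjoining censuses are compared pairwise along the series: the curve
#' starts at the richness of the first census and each subsequent point
#' adds the number of taxa present at that census but absent from the
#' immediately preceding one. A taxon therefore contributes again every
#' time it re-appears after a local absence, so the moving-window curve
#' incorporates repeated immigration/extinction of the same taxa.
#'
#' @param ts A [community_ts()] object.
#' @return An object of class `str_curve` with one point per span
#'   `1..n_censuses`.
#' @export
build_str_mw <- function(ts) {
  p <- ts$presence
  n <- ncol(p)
  S <- numeric(n)
  S[1L] <- sum(p[, 1L])
  if (n > 1L)
    for (t in 2:n) S[t] <- S[t - 1L] + sum(p[, t] & !p[, t - 1L])
  new_str_curve(ts, "MW", seq_len(n), S,
                span_days_mean = ts$census_days - ts$census_days[1L],
                n_windows = rep(1L, n))
}

#' Cumulative-moving-window species-time curve
#'
#' Only the first appearance of each taxon is counted: the point at span
#' `t` is the richness of the union of censuses `1..t`, so the final point
#' equals the island's total observed richness and the curve is
#' non-decreasing.
#'
#' @inheritParams build_str_mw
#' @return An `str_curve` object.
#' @export
build_str_cmw <- function(ts) {
  p <- ts$presence
  n <- ncol(p)
  seen <- t(apply(p, 1L, cumsum)) > 0
  if (nrow(p) == 1L) seen <- matrix(cumsum(p[1L, ]) > 0, nrow = 1L)
  S <- colSums(seen)
  new_str_curve(ts, "CMW", seq_len(n), S,
                span_days_mean = ts$census_days - ts$census_days[1L],
                n_windows = rep(1L, n))
}

#' Every-possible-window species-time curve
#'
#' For each span `k = 1..n` every contiguous window of `k` censuses is
#' scored: within a window, richness of the first census plus taxa new to
#' each later census relative to the cumulative earlier censuses -- which
#' for presence/absence data is the richness of the union of the window's
#' censuses. The curve records the mean over the `n - k + 1` windows of
#' each span, so the span-1 point is the mean per-census richness and the
#' span-`n` point equals the cumulative-moving-window endpoint.
#'
#' @inheritParams build_str_mw
#' @return An `str_curve` object; `$window_values` keeps the per-window
#'   richness values for audit.
#' @export
build_str_epw <- function(ts) {
  p <- ts$presence
  n <- ncol(p)
  days <- ts$census_days
  S <- numeric(n)
  dmean <- numeric(n)
  nw <- integer(n)
  audit <- vector("list", n)
  for (k in seq_len(n)) {
    w <- enumerate_windows(n, k)
    vals <- vapply(seq_len(nrow(w)), function(i) {
      cols <- w[i, 1L]:w[i, 2L]
      sum(rowSums(p[, cols, drop = FALSE]) > 0L)
    }, numeric(1))
    S[k] <- mean(vals)
    dmean[k] <- mean(days[w[, 2L]] - days[w[, 1L]])
    nw[k] <- nrow(w)
    audit[[k]] <- vals
  }
  names(audit) <- paste0("span", seq_len(n))
  new_str_curve(ts, "EPW", seq_len(n), S, dmean, nw, window_values = audit)
}

#' Build STR curves for one island or a whole archipelago
#'
#' @param x A [community_ts()] or [archipelago()] object.
#' @param methods Subset of `c("MW", "CMW", "EPW")`.
#' @return For a `community_ts`, a named list of `str_curve`s; for an
#'   `archipelago`, a list (by island) of such lists.
#' @export
build_str <- function(x, methods = c("MW", "CMW", "EPW")) {
  methods <- match.arg(methods, several.ok = TRUE)
  builders <- list(MW = build_str_mw, CMW = build_str_cmw,
                   EPW = build_str_epw)
  if (inherits(x, "community_ts"))
    return(lapply(builders[methods], function(f) f(x)))
  if (inherits(x, "archipelago"))
    return(lapply(x$islands, build_str, methods = methods))
  stop("x must be a community_ts or archipelago")
}

#' Flatten STR curves into one table
#'
#' @param curves Output of [build_str()] on an archipelago (list of lists)
#'   or a list of `str_curve`s.
#' @return Data frame with columns `island_id`, `method`, `span`,
#'   `span_days_mean`, `S`, `n_windows`.
#' @export
str_table <- function(curves) {
  flat <- list()
  walk <- function(x) {
    if (inherits(x, "str_curve")) flat[[length(flat) + 1L]] <<- x
    else lapply(x, walk)
    invisible(NULL)
  }
  walk(curves)
  do.call(rbind, lapply(flat, function(cu)
    cbind(island_id = cu$island_id, method = cu$method, cu$points)))
}
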