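# Point-pattern containers and calendar aggregation.

#' Spatio-temporal point pattern
#'
#' Events with planar coordinates and an integer period index over a polygon
#' window. Events outside the window (beyond a snap tolerance) are rejected.
#'
#' @param x,y planar event coordinates (km).
#' @param t integer period index in `1..T`.
#' @param window polygon (`n x 2` matrix).
#' @param T number of periods (default `max(t)`).
#' @param calendar optional character vector of period labels, length `T`.
#' @return object of class `lgcp_pattern` with `events` (data.frame `x,y,t`),
#'   `window`, `T`, `calendar` and per-period counts `n_t`.
#' @export
lgcp_pattern <- function(x, y, t, window, T = max(t), calendar = NULL) {
  window <- ccw(as_polygon(window))
  stopifnot(length(x) == length(y), length(x) == length(t))
  t <- as.integer(t)
  if (length(t) && (min(t) < 1L || max(t) > T))
    stop("period indices must lie in 1..T", call. = FALSE)
  if (length(x)) {
    tol <- 1e-9 * polygon_diameter(window)
    inside <- points_in_polygon(window, cbind(x, y), tol = tol)
    if (!all(inside))
      stop(sprintf("%d event(s) fall outside the window", sum(!inside)), call. = FALSE)
  }
  if (is.null(calendar)) calendar <- paste0("period_", seq_len(T))
  n_t <- tabulate(t, nbins = T)
  structure(list(events = data.frame(x = as.numeric(x), y = as.numeric(y), t = t),
                 window = window, T = as.integer(T), calendar = calendar, n_t = n_t),
            class = "lgcp_pattern")
}

#' @export
print.lgcp_pattern <- function(x, ...) {
  cat(sprintf("lgcp_pattern: %d events over %d periods, window area %.4g\n",
              nrow(x$events), x$T, polygon_area(x$window)))
  invisible(x)
}

#' Aggregate dated events into calendar periods
#'
#' Maps event dates to consecutive quarterly or monthly period indices
#' (1-based from the first period of the study range) and drops events
#' outside the window polygon, reporting the exclusion count.
#'
#' @param events data.frame with columns `x`, `y` and `date` (Date or
#'   ISO-8601 string).
#' @param window polygon.
#' @param frequency `"quarterly"` or `"monthly"`.
#' @param start,end optional period bounds (dates); events dated outside a
#'   declared range are an error.
#' @return an `lgcp_pattern`; attribute `n_excluded` counts dropped events.
#' @export
aggregate_periods <- function(events, window, frequency = c("quarterly", "monthly"),
                              start = NULL, end = NULL) {
  frequency <- match.arg(frequency)
  if (nrow(events) == 0L) stop("empty event set", call. = FALSE)
  dates <- as.Date(events$date)
  if (anyNA(dates)) stop("unparseable event dates", call. = FALSE)
  start <- if (is.null(start)) min(dates) else as.Date(start)
  end <- if (is.null(end)) max(dates) else as.Date(end)
  if (any(dates < start) || any(dates > end))
    stop("range error: event dates outside the declared study range", call. = FALSE)

  per_index <- function(d) {
    yr <- as.integer(format(d, "%Y")); mo <- as.integer(format(d, "%m"))
    if (frequency == "quarterly") yr * 4L + (mo - 1L) %/% 3L else yr * 12L + (mo - 1L)
  }
  p0 <- per_index(start)
  t <- per_index(dates) - p0 + 1L
  T <- per_index(end) - p0 + 1L
  labels <- if (frequency == "quarterly") {
    q0 <- p0 %% 4L; y0 <- p0 %/% 4L
    idx <- p0 + seq_len(T) - 1L
    sprintf("%d-Q%d", idx %/% 4L, idx %% 4L + 1L)
  } else {
    idx <- p0 + seq_len(T) - 1L
    sprintf("%d-%02d", idx %/% 12L, idx %% 12L + 1L)
  }

  window <- ccw(as_polygon(window))
  tol <- 1e-9 * polygon_diameter(window)
  inside <- points_in_polygon(window, cbind(events$x, events$y), tol = tol)
  pat <- lgcp_pattern(events$x[inside], events$y[inside], t[inside],
                      window = window, T = T, calendar = labels)
  attr(pat, "n_excluded") <- sum(!inside)
  pat
}
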