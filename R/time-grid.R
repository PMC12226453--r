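#' Discrete follow-up time grid
#'
#' The survival model discretises follow-up into equidistant one-year
#' intervals starting at year 1: interval \eqn{k} is the half-open period
#' \eqn{[k, k+1)} years since the first attack, for \eqn{k = 1, \dots, 11}.
#'
#' @param n_intervals Number of intervals (default 11).
#' @param start Left boundary of the first interval, in years (default 1).
#' @param width Interval width in years (default 1).
#' @return An object of class `time_grid` with elements `n_intervals`,
#'   `boundaries` (length `n_intervals + 1`), `start` and `width`.
#' @examples
#' g <- time_grid()
#' g$boundaries # 1, 2, ..., 12
#' @export
time_grid <- function(n_intervals = 11L, start = 1, width = 1) {
  stopifnot(n_intervals >= 1, width > 0)
  structure(
    list(n_intervals = as.integer(n_intervals),
         boundaries = start + width * (0:n_intervals),
         start = start, width = width),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("Time grid: %d intervals of %g y, [%g, %g) years\n",
              x$n_intervals, x$width, x$start,
              x$boundaries[x$n_intervals + 1L]))
  invisible(x)
}

#' Convert an event or censoring time to a discrete survival label
#'
#' Maps a continuous time (years since first attack) onto the interval grid.
#' Times before the grid are clamped to the first interval; times at or past
#' the end of the grid are clamped to the last interval. By default an event
#' observed beyond the grid is kept as an event in the last interval;
#' `late_events = "censor"` converts it to a censoring there instead.
#'
#' @param time Numeric vector of non-negative times in years.
#' @param event Logical/0-1 vector, `TRUE` for an observed event.
#' @param grid A [time_grid()].
#' @param late_events `"keep"` (default) or `"censor"`: handling of events
#'   at or beyond the right end of the grid.
#' @return A data.frame with integer column `interval` (in
#'   `1:grid$n_intervals`) and `event` (0/1).
#' @examples
#' to_discrete_label(4.2, TRUE)           # interval 4, event
#' to_discrete_label(0.8, FALSE)          # clamped to interval 1
#' to_discrete_label(12.7, FALSE)         # clamped to interval 11
#' @export
to_discrete_label <- function(time, event, grid = time_grid(),
                              late_events = c("keep", "censor")) {
  late_events <- match.arg(late_events)
  if (any(time < 0)) stop_pirasurv("negative event/censoring time",
                                   "pirasurv_bad_input")
  event <- as.integer(as.logical(event))
  stopifnot(length(event) == length(time))
  k <- floor((time - grid$start) / grid$width) + 1
  k <- pmin(pmax(k, 1L), grid$n_intervals)
  past_end <- time >= grid$boundaries[grid$n_intervals + 1L]
  if (late_events == "censor") event[past_end & event == 1L] <- 0L
  data.frame(interval = as.integer(k), event = event)
}
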