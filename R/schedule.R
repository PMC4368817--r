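#' Image-acquisition schedule for a window-chamber experiment
#'
#' An acquisition schedule is an ordered set of intervals, each sampled at its
#' own frame period, together with the tracer injection time \code{t_fd}
#' (end of the pre-injection interval) and, for pulsed experiments, the
#' electroporation time \code{t_ep}.
#'
#' The default schedule reproduces the study protocol: interval A, one frame
#' per 20 s for 5 min (injection at the end of A); B, one frame per 5 s for
#' 2 min starting 10 s after injection; C, one frame per 20 s for 10 min with
#' the pulses delivered at the end of C; D, one frame per 20 s for 10 min;
#' E, one frame per 2 min for 30 min.
#'
#' @param intervals data frame with columns \code{label}, \code{start},
#'   \code{duration}, \code{period} (all times in seconds). \code{NULL}
#'   requests the default protocol.
#' @param t_fd injection time in seconds; defaults to the end of interval A.
#' @param ep logical; if \code{FALSE} (control experiment) no pulse time is
#'   recorded.
#' @param t_ep pulse time in seconds; defaults to the end of interval C.
#' @return an object of class \code{acquisition_schedule} with elements
#'   \code{intervals}, \code{t_fd}, \code{t_ep} (\code{NA} for controls).
#' @examples
#' sch <- make_schedule()
#' length(frame_times(sch))
#' @export
make_schedule <- function(intervals = NULL, t_fd = NULL, ep = TRUE, t_ep = NULL) {
  if (is.null(intervals)) {
    intervals <- data.frame(
      label    = c("A", "B", "C", "D", "E"),
      start    = c(0, 310, 430, 1030, 1630),
      duration = c(300, 120, 600, 600, 1800),
      period   = c(20, 5, 20, 20, 120),
      stringsAsFactors = FALSE
    )
    if (is.null(t_fd)) t_fd <- 300       # end of A
    if (is.null(t_ep)) t_ep <- 1030      # end of C
  }
  req <- c("label", "start", "duration", "period")
  if (!is.data.frame(intervals) || !all(req %in% names(intervals)))
    stop("`intervals` must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(intervals) < 1L) stop("at least one interval is required")
  if (any(!is.finite(intervals$duration)) || any(intervals$duration <= 0))
    stop("interval durations must be positive")
  if (any(!is.finite(intervals$period)) || any(intervals$period <= 0))
    stop("frame periods must be positive")
  o <- order(intervals$start)
  intervals <- intervals[o, , drop = FALSE]
  ends <- intervals$start + intervals$duration
  if (nrow(intervals) > 1L &&
      any(intervals$start[-1L] < ends[-nrow(intervals)] - 1e-9))
    stop("acquisition intervals overlap")
  if (is.null(t_fd)) t_fd <- intervals$start[1L] + intervals$duration[1L]
  if (!ep) t_ep <- NA_real_
  if (ep && is.null(t_ep)) stop("`t_ep` required when ep = TRUE")
  if (ep && !(t_fd < t_ep)) stop("t_fd must precede t_ep")
  structure(
    list(intervals = intervals, t_fd = as.numeric(t_fd),
         t_ep = as.numeric(t_ep)),
    class = "acquisition_schedule"
  )
}

#' Frame timestamps of a schedule
#'
#' Frames are interval-start aligned: within each interval the first frame is
#' taken at the interval start and subsequent frames every \code{period}
#' seconds while strictly inside the half-open interval
#' \code{[start, start + duration)}.
#'
#' @param schedule an \code{acquisition_schedule}.
#' @return numeric vector of frame times in seconds, strictly increasing.
#' @export
frame_times <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  iv <- schedule$intervals
  out <- lapply(seq_len(nrow(iv)), function(i) {
    n <- ceiling(iv$duration[i] / iv$period[i] - 1e-9)
    iv$start[i] + iv$period[i] * seq.int(0L, n - 1L)
  })
  unlist(out, use.names = FALSE)
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat("Acquisition schedule:", nrow(x$intervals), "intervals,",
      length(frame_times(x)), "frames\n")
  cat("  t_fd =", x$t_fd, "s; t_ep =",
      if (is.na(x$t_ep)) "none (control)" else paste(x$t_ep, "s"), "\n")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Total time span of a schedule
#' @param schedule an \code{acquisition_schedule}.
#' @return end time of the last interval, seconds.
#' @export
schedule_end <- function(schedule) {
  iv <- schedule$intervals
  max(iv$start + iv$duration)
}
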