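#' Fluorescence trace container
#'
#' The central observable of the pipeline: the mean fluorescence intensity
#' F(t) of the microcirculatory region of interest, sampled at the schedule's
#' frame times. Samples are labelled by experimental phase: phase I before
#' tracer injection (background only), phase II between injection and pulse
#' delivery (intravascular tracer only), phase III after pulse delivery
#' (intravascular plus extravasated tracer).
#'
#' @param times sample times, seconds, strictly increasing.
#' @param values mean intensities, arbitrary units.
#' @param t_fd injection time, seconds.
#' @param t_ep pulse time, seconds, or \code{NA} for control experiments
#'   (phase III then starts at \code{t_ep} of the matched pulsed schedule if
#'   supplied, otherwise all post-injection samples are phase II).
#' @param dextran_kda tracer molecular weight, kDa (70 or 2000 in the study).
#' @return object of class \code{fluorescence_trace}: a list with
#'   \code{times}, \code{values}, \code{phase} (factor I/II/III), metadata,
#'   and a provenance list tracking processing steps.
#' @export
fluorescence_trace <- function(times, values, t_fd, t_ep = NA_real_,
                               dextran_kda = 70) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    list(times = times, values = values,
         phase = phase_labels(times, t_fd, t_ep),
         t_fd = as.numeric(t_fd), t_ep = as.numeric(t_ep),
         dextran_kda = dextran_kda,
         provenance = list()),
    class = "fluorescence_trace"
  )
}

#' Phase labels for sample times
#'
#' Phases are half-open intervals: I on \code{[0, t_fd)}, II on
#' \code{[t_fd, t_ep)}, III on \code{[t_ep, Inf)}. With \code{t_ep = NA}
#' everything from \code{t_fd} on is phase II.
#'
#' @param times numeric times, seconds.
#' @param t_fd injection time.
#' @param t_ep pulse time or NA.
#' @return factor with levels I, II, III.
#' @export
phase_labels <- function(times, t_fd, t_ep = NA_real_) {
  ph <- ifelse(times < t_fd, "I",
               ifelse(is.na(t_ep) | times < t_ep, "II", "III"))
  factor(ph, levels = c("I", "II", "III"))
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat("Fluorescence trace:", length(x$times), "samples, t in [",
      min(x$times), ",", max(x$times), "] s\n")
  cat("  phases:", paste(sprintf("%s=%d", levels(x$phase),
                                 tabulate(x$phase, 3L)), collapse = " "), "\n")
  cat("  t_fd =", x$t_fd, "s; t_ep =", x$t_ep, "s; dextran =",
      x$dextran_kda, "kDa\n")
  if (length(x$provenance))
    cat("  processing:", paste(names(x$provenance), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
as.data.frame.fluorescence_trace <- function(x, ...) {
  data.frame(time_s = x$times, intensity_au = x$values, phase = x$phase)
}

#' Subtract the pre-injection background from a trace
#'
#' The mean of all phase I samples (acquired before tracer injection) is
#' subtracted from every sample, so that the phase I mean of the result is
#' exactly zero.
#'
#' @param trace a \code{fluorescence_trace} with at least one phase I sample.
#' @return background-subtracted \code{fluorescence_trace}.
#' @export
subtract_background <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  pre <- trace$phase == "I"
  if (!any(pre)) stop("no phase I samples: background cannot be estimated")
  bg <- mean(trace$values[pre])
  trace$values <- trace$values - bg
  trace$provenance$background_subtracted <- list(background = bg)
  trace
}

#' Normalize a trace to its pre-pulse phase II maximum
#'
#' Every sample is divided by the maximum background-subtracted intensity
#' reached within phase II before pulse delivery, so that this maximum maps
#' to 1. The whole downstream fit operates on normalized traces, which makes
#' it invariant to the (unknown) fluorescence gain.
#'
#' @param trace a background-subtracted \code{fluorescence_trace}.
#' @return normalized \code{fluorescence_trace}.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  pre_ep <- trace$phase == "II" &
    (is.na(trace$t_ep) | trace$times < trace$t_ep)
  if (!any(pre_ep)) stop("no pre-pulse phase II samples to normalize by")
  mx <- max(trace$values[pre_ep])
  if (!is.finite(mx) || mx <= 0)
    stop("non-positive pre-pulse phase II maximum; subtract background first")
  trace$values <- trace$values / mx
  trace$provenance$normalized <- list(reference_max = mx)
  trace
}

#' Write a trace as two-column delimited text
#' @param trace a \code{fluorescence_trace}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(
    data.frame(time_s = trace$times, intensity_au = trace$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace from two-column delimited text
#' @param path file with columns time_s, intensity_au (header optional).
#' @param t_fd,t_ep,dextran_kda trace metadata (see
#'   \code{\link{fluorescence_trace}}).
#' @return a \code{fluorescence_trace}.
#' @export
read_trace <- function(path, t_fd, t_ep = NA_real_, dextran_kda = 70) {
  first <- readLines(path, n = 1L)
  header <- grepl("[A-Za-z]", first)
  d <- utils::read.table(path, header = header)
  fluorescence_trace(d[[1L]], d[[2L]], t_fd = t_fd, t_ep = t_ep,
                     dextran_kda = dextran_kda)
}
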