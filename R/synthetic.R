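#' Ground truth for a synthetic experiment
#'
#' Bundles everything the generator needs: the pharmacokinetic rates, the
#' wall-coefficient ramp (or \code{NULL} for a control experiment), the
#' tissue diffusivity, the constant background fluorescence, the
#' multiplicative measurement-noise level and the fluorescence gain. The
#' gain maps tracked amount to intensity; it is arbitrary because the
#' pipeline normalizes traces (fluorescence is proportional to the amount of
#' tracer in the imaged volume), and is recorded only so oracle tests can
#' undo it.
#'
#' @param pk a \code{pk_params}.
#' @param wall a \code{wall_permeability}, or \code{NULL} for a control.
#' @param d_tiss tissue diffusion coefficient, um^2/s.
#' @param background constant background intensity, a.u. (>= 0).
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise (>= 0).
#' @param gain fluorescence per unit tracked amount, a.u. (> 0).
#' @param seed integer seed governing all randomness of the dataset.
#' @return object of class \code{ground_truth}.
#' @export
ground_truth <- function(pk, wall = NULL, d_tiss = 30, background = 100,
                         noise_cv = 0.03, gain = 1, seed = 1L) {
  stopifnot(inherits(pk, "pk_params"))
  if (!is.null(wall)) stopifnot(inherits(wall, "wall_permeability"))
  if (background < 0) stop("background must be non-negative")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (gain <= 0) stop("gain must be positive")
  structure(list(pk = pk, wall = wall, d_tiss = d_tiss,
                 background = background, noise_cv = noise_cv,
                 gain = gain, seed = as.integer(seed)),
            class = "ground_truth")
}

# run fun() under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, fun) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' Simulate a fluorescence trace with known ground truth
#'
#' Samples the modeled signal at the schedule's frame times: before
#' injection the signal is the background alone; afterwards it is background
#' plus gain times the tracked amount m(t), where m(t) is the intravascular
#' amount (control) or the sum of intravascular and extravasated amounts
#' after the pulses (from the forward diffusion model). Multiplicative
#' Gaussian noise with standard deviation \code{noise_cv} times the
#' noise-free signal is then applied.
#'
#' @param schedule an \code{acquisition_schedule}.
#' @param truth a \code{ground_truth}.
#' @param geometry a \code{unit_cell_geometry}.
#' @param resolution grid resolution for the forward solve, um.
#' @return object of class \code{synthetic_dataset}: list with \code{trace}
#'   (a \code{fluorescence_trace}), \code{truth}, \code{schedule},
#'   \code{noise_free} values and, for pulsed runs, the \code{forward}
#'   solution.
#' @export
simulate_trace <- function(schedule, truth, geometry = unit_cell_geometry(),
                           resolution = 1) {
  stopifnot(inherits(schedule, "acquisition_schedule"),
            inherits(truth, "ground_truth"))
  times <- frame_times(schedule)
  t_fd <- schedule$t_fd
  grid <- build_grid(geometry, resolution)
  civ <- civ_profile(truth$pk, t_fd = t_fd)
  ep <- !is.null(truth$wall) && !is.na(schedule$t_ep)
  sol <- NULL
  if (ep) {
    if (abs(truth$wall$t_ep - schedule$t_ep) > 1e-9)
      stop("wall t_ep does not match the schedule's pulse time")
    params <- transport_params(truth$d_tiss, truth$wall)
    sol <- tryCatch(
      solve_forward(grid, params, civ, t_span = c(t_fd, schedule_end(schedule)),
                    out_times = times[times >= t_fd], t_fd = t_fd),
      error = function(e)
        stop("forward solver failed while generating the synthetic trace: ",
             conditionMessage(e), call. = FALSE))
    m <- numeric(length(times))
    m[times >= t_fd] <- sol$m_total
  } else {
    m <- civ(times) * grid$lumen_area
  }
  clean <- truth$background + truth$gain * m
  vals <- if (truth$noise_cv > 0) {
    with_seed(truth$seed, function()
      clean * (1 + truth$noise_cv * stats::rnorm(length(clean))))
  } else clean
  trace <- fluorescence_trace(times, vals, t_fd = t_fd, t_ep = schedule$t_ep)
  trace$provenance$simulated <- list(gain = truth$gain, seed = truth$seed)
  structure(list(trace = trace, truth = truth, schedule = schedule,
                 noise_free = clean, forward = sol, grid = grid),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset (",
      if (is.null(x$truth$wall)) "control" else "electroporated",
      "), seed ", x$truth$seed, "\n", sep = "")
  print(x$trace)
  invisible(x)
}

#' Vessel layout for rendered image stacks
#'
#' Describes the synthetic field of view: frame dimensions and vertical
#' large-vessel stripes (much wider than the 2-px capillary scale). The
#' remaining pixels represent the microcirculatory region of interest.
#'
#' @param width,height frame dimensions, pixels.
#' @param stripes data frame with columns \code{x0} (first column of each
#'   stripe, 1-based) and \code{width} (pixels); may have zero rows.
#' @param vessel_gain intensity per unit intravascular concentration for
#'   large-vessel pixels, a.u.
#' @return object of class \code{vessel_layout}.
#' @export
vessel_layout <- function(width = 96, height = 72,
                          stripes = data.frame(x0 = c(20, 60), width = 12),
                          vessel_gain = 400) {
  if (nrow(stripes) > 0) {
    if (any(stripes$x0 < 1) || any(stripes$width < 1) ||
        any(stripes$x0 + stripes$width - 1 > width))
      stop("vessel stripes exceed the frame dimensions")
  }
  structure(list(width = width, height = height, stripes = stripes,
                 vessel_gain = vessel_gain), class = "vessel_layout")
}

#' Render a synthetic image stack with ground-truth mask
#'
#' Produces per-frame pixel intensities at the schedule's frame times:
#' large-vessel pixels track the intravascular concentration c_iv(t), all
#' other pixels track the mean signal of the microcirculatory region
#' (background plus gain times the tracked amount, as in
#' \code{\link{simulate_trace}}). Gaussian (multiplicative, sd = noise_cv x
#' signal) or Poisson pixel noise is applied per the truth/noise arguments.
#'
#' @param schedule an \code{acquisition_schedule}.
#' @param truth a \code{ground_truth}.
#' @param layout a \code{vessel_layout}.
#' @param geometry a \code{unit_cell_geometry}.
#' @param noise one of "gaussian", "poisson", "none".
#' @param n_frames optionally render only the first \code{n_frames} frames.
#' @return object of class \code{synthetic_stack}: list with \code{stack}
#'   (an \code{image_stack}), logical ground-truth \code{mask}, the
#'   underlying \code{dataset}, and the per-frame noise-free vessel and
#'   tissue values.
#' @export
render_image_stack <- function(schedule, truth, layout = vessel_layout(),
                               geometry = unit_cell_geometry(),
                               noise = c("gaussian", "poisson", "none"),
                               n_frames = NULL) {
  noise <- match.arg(noise)
  truth_clean <- truth
  truth_clean$noise_cv <- 0
  ds <- simulate_trace(schedule, truth_clean, geometry)
  times <- ds$trace$times
  if (!is.null(n_frames)) times <- times[seq_len(min(n_frames, length(times)))]
  civ <- civ_profile(truth$pk, t_fd = schedule$t_fd)
  mask <- matrix(FALSE, layout$width, layout$height)
  if (nrow(layout$stripes) > 0)
    for (j in seq_len(nrow(layout$stripes))) {
      cols <- layout$stripes$x0[j] + seq_len(layout$stripes$width[j]) - 1L
      mask[cols, ] <- TRUE
    }
  vessel_vals <- truth$background + layout$vessel_gain * civ(times)
  tissue_vals <- ds$noise_free[seq_along(times)]
  frames <- with_seed(truth$seed, function() {
    lapply(seq_along(times), function(i) {
      f <- matrix(tissue_vals[i], layout$width, layout$height)
      f[mask] <- vessel_vals[i]
      if (noise == "gaussian" && truth$noise_cv > 0) {
        f <- f * (1 + truth$noise_cv * stats::rnorm(length(f)))
      } else if (noise == "poisson") {
        f[] <- stats::rpois(length(f), lambda = pmax(f, 0))
      }
      f
    })
  })
  structure(list(stack = image_stack(frames, times), mask = mask,
                 dataset = ds, vessel_values = vessel_vals,
                 tissue_values = tissue_vals, layout = layout),
            class = "synthetic_stack")
}
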