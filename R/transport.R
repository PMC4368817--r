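#' Time-dependent wall diffusion coefficient
#'
#' The permeabilized-wall coefficient D_wall(t) is zero until a delay time
#' \code{t_del} after the pulses, rises linearly between \code{t_del} and
#' \code{t_sat}, and stays at its saturation value \code{d_sat} thereafter
#' (the observation window ends before permeability reseals, so no return to
#' baseline is modeled).
#'
#' @param t_ep pulse time, seconds.
#' @param t_del onset of the permeability increase, seconds (>= t_ep).
#' @param t_sat time at which the coefficient saturates, seconds (> t_del).
#' @param d_sat saturated wall diffusion coefficient, um^2/s (>= 0).
#' @return object of class \code{wall_permeability}.
#' @export
wall_permeability <- function(t_ep, t_del, t_sat, d_sat) {
  if (any(!is.finite(c(t_ep, t_del, t_sat, d_sat))))
    stop("wall parameters must be finite")
  if (t_ep < 0 || t_del < t_ep) stop("need 0 <= t_ep <= t_del")
  if (t_sat <= t_del) stop("t_sat must exceed t_del")
  if (d_sat < 0) stop("d_sat must be non-negative")
  structure(list(t_ep = t_ep, t_del = t_del, t_sat = t_sat, d_sat = d_sat),
            class = "wall_permeability")
}

#' @export
print.wall_permeability <- function(x, ...) {
  cat(sprintf(paste0("Wall coefficient ramp: 0 until t = %g s, linear to",
                     " D_wall = %g um^2/s at t = %g s (t_ep = %g s)\n"),
              x$t_del, x$d_sat, x$t_sat, x$t_ep))
  invisible(x)
}

#' Evaluate the wall coefficient ramp
#' @param t times, seconds.
#' @param wall a \code{wall_permeability}.
#' @return D_wall(t), um^2/s.
#' @export
dwall_at <- function(t, wall) {
  stopifnot(inherits(wall, "wall_permeability"))
  pmax(0, pmin(1, (t - wall$t_del) / (wall$t_sat - wall$t_del))) * wall$d_sat
}

#' Transport parameters
#'
#' @param d_tiss extravascular (tissue) diffusion coefficient, um^2/s.
#'   The study used 30 for 70 kDa and 5 for 2000 kDa dextran.
#' @param wall a \code{wall_permeability}.
#' @return object of class \code{transport_params}.
#' @export
transport_params <- function(d_tiss, wall) {
  stopifnot(inherits(wall, "wall_permeability"))
  if (!is.finite(d_tiss) || d_tiss <= 0) stop("d_tiss must be positive")
  structure(list(d_tiss = d_tiss, wall = wall), class = "transport_params")
}

# build the step-time vector: from t_del to t_end, refining the linear ramp
# (>= ramp_steps sub-steps) and the early post-saturation transient (step
# <= fine_dt for 240 s after t_sat), then stepping at max_dt
.step_schedule <- function(wall, t_end, max_dt = 40, ramp_steps = 12L,
                           fine_dt = 20) {
  t0 <- wall$t_del
  if (t_end <= t0) return(c(t0, t_end))
  fine_until <- min(wall$t_sat + 240, t_end)
  seg <- sort(unique(pmin(pmax(c(t0, wall$t_sat, fine_until, t_end), t0),
                          t_end)))
  cap_for <- function(a, b) {
    if (b <= wall$t_sat) min(fine_dt, max_dt, (wall$t_sat - t0) / ramp_steps)
    else if (b <= fine_until) min(fine_dt, max_dt)
    else max_dt
  }
  out <- seg[1L]
  for (i in seq_len(length(seg) - 1L)) {
    if (seg[i + 1L] <= seg[i] + 1e-9) next
    cap <- cap_for(seg[i], seg[i + 1L])
    n <- ceiling((seg[i + 1L] - seg[i]) / cap - 1e-9)
    out <- c(out, seg[i] + (seg[i + 1L] - seg[i]) * seq_len(n) / n)
  }
  out
}

#' Solve the forward transport model
#'
#' Solves Fick's second law dc/dt = div(D grad c) on the discretized unit
#' cell, with D equal to \code{dwall_at(t)} inside the wall layer and
#' \code{d_tiss} in the tissue, the lumen held at the intravascular
#' concentration c_iv(t) (Dirichlet; plasma is well mixed), zero-flux outer
#' surfaces and mirror-symmetric side walls, and zero initial tissue
#' concentration. Time stepping is an unconditionally stable
#' Peaceman-Rachford alternating-direction-implicit (ADI) scheme; before the
#' permeability onset the field is analytically zero and no steps are taken.
#'
#' @param grid a \code{transport_grid} from \code{\link{build_grid}}.
#' @param params a \code{transport_params}.
#' @param c_iv function of time returning the intravascular concentration
#'   (e.g. from \code{\link{civ_profile}}).
#' @param t_span length-2 vector (start, end), seconds; the start is
#'   typically the injection time.
#' @param out_times times at which to report amounts; default is a uniform
#'   grid over \code{t_span}.
#' @param max_dt cap on the ADI step size, seconds.
#' @param t_fd injection time recorded in the solution (defaults to
#'   \code{t_span[1]}).
#' @return object of class \code{forward_solution}: \code{times},
#'   \code{m_iv} (c_iv times lumen area), \code{m_ev} (tissue amount),
#'   \code{m_wall}, \code{m_total = m_iv + m_ev}, the final concentration
#'   field, and the stepping provenance.
#' @export
solve_forward <- function(grid, params, c_iv, t_span,
                          out_times = NULL, max_dt = 40, t_fd = t_span[1]) {
  stopifnot(inherits(grid, "transport_grid"),
            inherits(params, "transport_params"), is.function(c_iv))
  wall <- params$wall
  if (is.null(out_times))
    out_times <- seq(t_span[1], t_span[2], length.out = 121L)
  if (any(out_times < t_span[1] - 1e-9 | out_times > t_span[2] + 1e-9))
    stop("out_times must lie within t_span")
  m_iv <- c_iv(out_times) * grid$lumen_area
  active <- wall$d_sat > 0 && wall$t_del < t_span[2]
  if (!active) {
    m_ev <- numeric(length(out_times))
    m_wall <- numeric(length(out_times))
    field <- matrix(0, grid$nx, grid$nz)
    steps <- numeric(0)
  } else {
    steps <- .step_schedule(wall, t_span[2], max_dt = max_dt)
    nst <- length(steps) - 1L
    mid <- (steps[-1L] + steps[-length(steps)]) / 2
    res <- .adi_run_cpp(grid$type, grid$fw_x, grid$ft_x, grid$code_x,
                        grid$fw_z, grid$ft_z, grid$code_z,
                        grid$h, params$d_tiss,
                        steps, dwall_at(mid, wall), c_iv(mid), c_iv(steps),
                        numeric(grid$nx * grid$nz), TRUE)
    m_ev <- stats::approx(steps, res$m_ev, xout = out_times, rule = 2,
                          yleft = 0)$y
    m_ev[out_times <= wall$t_del] <- 0
    m_wall <- stats::approx(steps, res$m_wall, xout = out_times, rule = 2,
                            yleft = 0)$y
    m_wall[out_times <= wall$t_del] <- 0
    field <- res$field
  }
  structure(
    list(times = out_times, m_iv = m_iv, m_ev = m_ev, m_wall = m_wall,
         m_total = m_iv + m_ev, field = field, params = params,
         t_fd = t_fd, t_ep = wall$t_ep,
         stepping = list(scheme = "Peaceman-Rachford ADI", max_dt = max_dt,
                         n_steps = max(length(steps) - 1L, 0L))),
    class = "forward_solution")
}

#' @export
print.forward_solution <- function(x, ...) {
  cat(sprintf("Forward solution: %d output times on [%g, %g] s (%s, %d steps)\n",
              length(x$times), min(x$times), max(x$times),
              x$stepping$scheme, x$stepping$n_steps))
  cat(sprintf("  final amounts: m_iv = %.4g, m_ev = %.4g\n",
              x$m_iv[length(x$m_iv)], x$m_ev[length(x$m_ev)]))
  invisible(x)
}

#' Modeled fluorescence signal from a forward solution
#'
#' Total tracked amount m(t): intravascular only before the pulses, the sum
#' of intravascular and extravasated amounts afterwards. The signal is
#' normalized by its maximum over the pre-pulse samples, mirroring
#' \code{\link{normalize_trace}}, so model and measured traces are directly
#' comparable.
#'
#' @param solution a \code{forward_solution}.
#' @param t_ep pulse time, seconds; defaults to the one stored in the
#'   solution's wall parameters.
#' @return a \code{fluorescence_trace} of the normalized model signal.
#' @export
signal_model <- function(solution, t_ep = solution$t_ep) {
  stopifnot(inherits(solution, "forward_solution"))
  pre <- solution$times < t_ep & solution$times >= solution$t_fd
  if (!any(pre)) stop("solution does not span the pre-pulse window")
  mx <- max(solution$m_total[pre])
  if (!is.finite(mx) || mx <= 0)
    stop("non-positive pre-pulse maximum of the modeled signal")
  fluorescence_trace(solution$times, solution$m_total / mx,
                     t_fd = solution$t_fd, t_ep = t_ep)
}

# ---------------------------------------------------------------------------
# Independent reference solver: explicit Euler on the same finite-volume
# face coefficients, used as a brute-force oracle at finer resolution.
# Deliberately simple and kept in plain R, independent of the ADI kernel.
fv_explicit_reference <- function(grid, d_tiss, dwall_fun, civ_fun,
                                  t_span, out_times, safety = 0.45) {
  nx <- grid$nx; nz <- grid$nz; h2 <- grid$h^2
  coef <- function(code, fw, ft, dw) {
    fl <- 1 - fw - ft
    denom <- ft / d_tiss + ifelse(fw > 0, fw / pmax(dw, 1e-300), 0)
    A <- 1 / (h2 * denom)
    A <- pmin(A, 2 * d_tiss / h2)      # same conductance cap as the ADI kernel
    A[code == 2L] <- 0
    A[(fw > 0 | fl > 1e-12) & dw <= 0] <- 0
    A[!is.finite(A)] <- 0
    A
  }
  lum <- grid$type == 2L
  tis <- grid$type == 0L
  # only faces whose segment crosses wall (or lumen-interface) material
  # depend on dwall
  wx <- (grid$fw_x > 0 | 1 - grid$fw_x - grid$ft_x > 1e-12) &
    grid$code_x != 2L
  wz <- (grid$fw_z > 0 | 1 - grid$fw_z - grid$ft_z > 1e-12) &
    grid$code_z != 2L
  dmax <- max(dwall_fun(seq(t_span[1], t_span[2], length.out = 200L)), 0)
  Axm <- coef(grid$code_x, grid$fw_x, grid$ft_x, dmax)
  Azm <- coef(grid$code_z, grid$fw_z, grid$ft_z, dmax)
  rate <- matrix(0, nx, nz)
  if (nx > 1) {
    rate[-nx, ] <- rate[-nx, , drop = FALSE] + Axm
    rate[-1L, ] <- rate[-1L, , drop = FALSE] + Axm
  }
  if (nz > 1) {
    rate[, -nz] <- rate[, -nz, drop = FALSE] + Azm
    rate[, -1L] <- rate[, -1L, drop = FALSE] + Azm
  }
  dt <- safety / max(rate[!lum], 1e-12)
  c_fld <- matrix(0, nx, nz)
  t <- t_span[1]
  c_fld[lum] <- civ_fun(t)
  out <- numeric(length(out_times))
  oi <- 1L
  while (oi <= length(out_times) && out_times[oi] <= t + 1e-12) {
    out[oi] <- sum(c_fld[tis]) * h2; oi <- oi + 1L
  }
  Ax <- Axm; Az <- Azm
  dw_prev <- NA_real_
  while (t < t_span[2] - 1e-12) {
    step <- min(dt, t_span[2] - t,
                if (oi <= length(out_times)) out_times[oi] - t else dt)
    dw <- dwall_fun(t + step / 2)
    if (!identical(dw, dw_prev)) {
      if (any(wx))
        Ax[wx] <- coef(grid$code_x[wx], grid$fw_x[wx], grid$ft_x[wx], dw)
      if (any(wz))
        Az[wz] <- coef(grid$code_z[wz], grid$fw_z[wz], grid$ft_z[wz], dw)
      dw_prev <- dw
    }
    lap <- matrix(0, nx, nz)
    if (nx > 1) {
      fx <- Ax * (c_fld[-1L, , drop = FALSE] - c_fld[-nx, , drop = FALSE])
      lap[-nx, ] <- lap[-nx, , drop = FALSE] + fx
      lap[-1L, ] <- lap[-1L, , drop = FALSE] - fx
    }
    if (nz > 1) {
      fz <- Az * (c_fld[, -1L, drop = FALSE] - c_fld[, -nz, drop = FALSE])
      lap[, -nz] <- lap[, -nz, drop = FALSE] + fz
      lap[, -1L] <- lap[, -1L, drop = FALSE] - fz
    }
    c_fld <- c_fld + step * lap
    t <- t + step
    c_fld[lum] <- civ_fun(t)
    while (oi <= length(out_times) && out_times[oi] <= t + 1e-12) {
      out[oi] <- sum(c_fld[tis]) * h2; oi <- oi + 1L
    }
  }
  list(times = out_times, m_ev = out, field = c_fld, dt = dt)
}
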