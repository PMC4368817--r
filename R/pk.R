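#' Two-compartment pharmacokinetic parameters
#'
#' First-order cascade describing tracer uptake from the injection site
#' (orbital sinus, compartment 1) into blood (compartment 2) and first-order
#' clearance from blood: dm_orb/dt = -k_a m_orb; dm_iv/dt = k_a m_orb -
#' k_e m_iv, with m_orb(t_fd) = dose.
#'
#' The blood volume only rescales concentration; because the pipeline
#' normalizes traces it is unidentifiable and fixed to 1 by default.
#'
#' @param k_a uptake rate, 1/s (> 0).
#' @param k_e clearance rate, 1/s (>= 0).
#' @param dose injected amount, arbitrary units (> 0).
#' @param v_blood blood volume, arbitrary units (> 0).
#' @return object of class \code{pk_params}.
#' @export
pk_params <- function(k_a, k_e, dose = 1, v_blood = 1) {
  vals <- c(k_a = k_a, k_e = k_e, dose = dose, v_blood = v_blood)
  if (any(!is.finite(vals))) stop("PK parameters must be finite")
  if (k_a <= 0) stop("k_a must be positive")
  if (k_e < 0) stop("k_e must be non-negative")
  if (dose <= 0 || v_blood <= 0) stop("dose and v_blood must be positive")
  structure(as.list(vals), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("PK params: k_a = %.4g /s, k_e = %.4g /s, dose = %.4g, v_blood = %.4g\n",
              x$k_a, x$k_e, x$dose, x$v_blood))
  invisible(x)
}

# Bateman function: intravascular amount at time tau >= 0 after injection.
# Switches to the confluent limit dose * k_a * tau * exp(-k_a tau) when
# |k_a - k_e| < conf_tol * k_a to avoid catastrophic cancellation.
bateman <- function(tau, k_a, k_e, dose = 1, conf_tol = 1e-9) {
  m <- numeric(length(tau))
  pos <- tau >= 0
  tp <- tau[pos]
  if (abs(k_a - k_e) < conf_tol * k_a) {
    m[pos] <- dose * k_a * tp * exp(-k_a * tp)
  } else {
    m[pos] <- dose * k_a / (k_e - k_a) * (exp(-k_a * tp) - exp(-k_e * tp))
  }
  m
}

#' Solve the two-compartment model on a time grid
#'
#' Closed-form (Bateman) solution of the uptake/clearance cascade. Times
#' before \code{t_fd} map to zero tracer.
#'
#' @param params a \code{pk_params}.
#' @param times evaluation times, seconds.
#' @param t_fd injection time, seconds.
#' @return object of class \code{pk_solution}: list with \code{times},
#'   \code{m_iv} (intravascular amount) and \code{c_iv = m_iv / v_blood}
#'   (intravascular concentration).
#' @export
solve_two_compartment <- function(params, times, t_fd = 0) {
  stopifnot(inherits(params, "pk_params"))
  if (any(!is.finite(times))) stop("times must be finite")
  m <- bateman(times - t_fd, params$k_a, params$k_e, params$dose)
  structure(list(times = times, m_iv = m, c_iv = m / params$v_blood,
                 params = params, t_fd = t_fd),
            class = "pk_solution")
}

#' Intravascular concentration as a function of time
#'
#' Returns a closed-form evaluator \code{function(t)} for c_iv(t), suitable
#' as the lumen boundary input of the diffusion forward model (no
#' interpolation error at any t).
#'
#' @inheritParams solve_two_compartment
#' @return function mapping times (s) to concentration (a.u.).
#' @export
civ_profile <- function(params, t_fd = 0) {
  stopifnot(inherits(params, "pk_params"))
  force(t_fd)
  k_a <- params$k_a; k_e <- params$k_e
  scale <- params$dose / params$v_blood
  function(t) bateman(t - t_fd, k_a, k_e, scale)
}

#' Time of the intravascular peak
#' @param params a \code{pk_params} with \code{k_e > 0}.
#' @return seconds after injection at which m_iv is maximal.
#' @export
pk_peak_time <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  if (params$k_e <= 0) return(Inf)
  if (abs(params$k_a - params$k_e) < 1e-9 * params$k_a) return(1 / params$k_a)
  log(params$k_a / params$k_e) / (params$k_a - params$k_e)
}

#' Fit the two-compartment model to the pre-pulse portion of a trace
#'
#' Least-squares fit of the normalized Bateman shape to a normalized,
#' background-subtracted trace restricted to phase II (and, for control
#' experiments, phase III, where the signal is still purely intravascular).
#' Normalization absorbs the fluorescence gain, so only the two rates are
#' estimated; the model prediction is normalized by its own maximum over the
#' pre-pulse sample times, mirroring \code{\link{normalize_trace}}, and a
#' free amplitude close to 1 absorbs the upward bias of normalizing noisy
#' data by their maximum sample (without it, that bias leaks into the
#' rates).
#'
#' @param trace normalized \code{fluorescence_trace}.
#' @param init starting \code{pk_params} (rates only are used).
#' @param include_phase3 also use phase III samples (valid for controls
#'   only, where phase III is still pure intravascular clearance; it pins
#'   down the clearance rate far better than the pre-pulse window alone).
#' @return fitted \code{pk_params} with attributes \code{residual_norm}
#'   (sum of squared residuals), \code{amplitude} and \code{convergence}.
#' @export
fit_pk <- function(trace, init = pk_params(0.02, 0.001),
                   include_phase3 = FALSE) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  use <- trace$phase == "II"
  if (include_phase3) use <- use | trace$phase == "III"
  t_obs <- trace$times[use]
  y_obs <- trace$values[use]
  if (length(t_obs) < 6L)
    stop("need at least 6 pre-pulse samples to fit the uptake and clearance rates")
  peak_i <- which.max(y_obs)
  if (sum(t_obs > t_obs[peak_i]) < 3L)
    stop("need at least 3 samples past the intravascular peak to identify clearance")
  t_fd <- trace$t_fd
  # normalization window: pre-pulse phase II sample times
  pre_ep <- trace$phase[use] == "II" &
    (is.na(trace$t_ep) | t_obs < trace$t_ep)
  model <- function(k_a, k_e, amp) {
    m <- bateman(t_obs - t_fd, k_a, k_e)
    amp * m / max(m[pre_ep])
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y_obs ~ model(k_a, k_e, amp),
      start = list(k_a = init$k_a, k_e = max(init$k_e, 1e-6), amp = 1),
      lower = c(1e-6, 1e-8, 0.1), upper = c(1, 0.1, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e)
      stop("pharmacokinetic fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  est <- stats::coef(fit)
  out <- pk_params(k_a = unname(est["k_a"]), k_e = unname(est["k_e"]))
  attr(out, "residual_norm") <- sum(stats::residuals(fit)^2)
  attr(out, "amplitude") <- unname(est["amp"])
  attr(out, "convergence") <- fit$convInfo$isConv
  out
}
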