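#' Convert a wall diffusion coefficient to a permeability coefficient
#'
#' P_wall = D_wall / d_wall: the diffusion coefficient of the wall layer
#' divided by its thickness, converted from um/s to cm/s. The default
#' thickness is the modeled wall layer (1 um).
#'
#' @param d_wall wall diffusion coefficient(s), um^2/s.
#' @param thickness wall thickness, um (> 0).
#' @return permeability in cm/s (1 um/s = 1e-4 cm/s).
#' @export
pwall_from_dwall <- function(d_wall, thickness = 1) {
  if (!is.finite(thickness) || thickness <= 0)
    stop("wall thickness must be positive")
  (d_wall / thickness) * 1e-4
}

#' Free-diffusion ratio implied by the Stokes-Einstein relation
#'
#' The free diffusion coefficient scales inversely with the hydrodynamic
#' radius, so the expected ratio of diffusion coefficients of a small to a
#' large tracer equals radius_large / radius_small.
#'
#' @param radius_large,radius_small hydrodynamic radii, nm (> 0).
#' @return dimensionless ratio.
#' @export
stokes_einstein_ratio <- function(radius_large, radius_small) {
  if (any(c(radius_large, radius_small) <= 0))
    stop("radii must be positive")
  radius_large / radius_small
}

#' Ratio of two diffusion (or permeability) coefficients
#' @param d_a numerator, um^2/s.
#' @param d_b denominator, um^2/s (non-zero).
#' @return d_a / d_b.
#' @export
coefficient_ratio <- function(d_a, d_b) {
  if (any(d_b == 0)) stop("denominator coefficient must be non-zero")
  d_a / d_b
}

#' Linearity of the post-pulse fluorescence rise
#'
#' Ordinary-least-squares line fitted to the phase III samples; the
#' coefficient of determination quantifies how nearly linear the post-pulse
#' accumulation is (a diagnostic of the saturated-ramp regime). A trace with
#' zero variance over phase III returns R^2 = 0 by convention.
#'
#' @param trace a \code{fluorescence_trace} with at least 3 phase III samples.
#' @return R-squared of the linear fit.
#' @export
postep_linearity <- function(trace) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  sel <- trace$phase == "III"
  if (sum(sel) < 3L) stop("need at least 3 phase III samples")
  y <- trace$values[sel]; t <- trace$times[sel]
  if (stats::var(y) <= 0) return(0)
  suppressWarnings(summary(stats::lm(y ~ t))$r.squared)
}

#' Assemble a permeability report for one tracer group
#'
#' Per-animal and median wall coefficients with the derived permeability
#' coefficients. The permeability identity P_wall = D_wall / thickness is
#' re-checked on every row when the report is written.
#'
#' @param d_wall per-animal saturated wall coefficients, um^2/s.
#' @param dextran_kda tracer molecular weight, kDa.
#' @param d_tiss tissue diffusivity used in the fits, um^2/s.
#' @param thickness wall thickness for the permeability conversion, um.
#' @param radius_nm hydrodynamic radius of the tracer, nm (optional).
#' @param labels per-animal labels.
#' @param r2_phase3 optional post-pulse linearity diagnostic.
#' @return object of class \code{permeability_report}.
#' @export
permeability_report <- function(d_wall, dextran_kda, d_tiss, thickness = 1,
                                radius_nm = NA_real_, labels = NULL,
                                r2_phase3 = NA_real_) {
  if (!length(d_wall)) stop("at least one fitted coefficient is required")
  if (is.null(labels)) labels <- paste("Mouse", seq_along(d_wall))
  structure(list(
    table = data.frame(label = labels, d_wall = d_wall,
                       p_wall = pwall_from_dwall(d_wall, thickness)),
    median_d_wall = stats::median(d_wall),
    median_p_wall = pwall_from_dwall(stats::median(d_wall), thickness),
    dextran_kda = dextran_kda, d_tiss = d_tiss, thickness = thickness,
    radius_nm = radius_nm, r2_phase3 = r2_phase3),
    class = "permeability_report")
}

#' @export
print.permeability_report <- function(x, ...) {
  cat(sprintf("Permeability report, %g kDa dextran (d_tiss = %g um^2/s):\n",
              x$dextran_kda, x$d_tiss))
  tab <- x$table
  tab$p_wall_1e7 <- tab$p_wall * 1e7
  print(tab, row.names = FALSE, digits = 4)
  cat(sprintf("  median D_wall = %.4g um^2/s; median P_wall = %.3g cm/s (%.3g x 1e-7)\n",
              x$median_d_wall, x$median_p_wall, x$median_p_wall * 1e7))
  invisible(x)
}

#' Write permeability reports to disk
#'
#' Serializes one or more group reports as a JSON file plus a delimited
#' table laid out like the study's summary table (per-animal wall
#' coefficient, group median, permeability, median permeability). The
#' permeability/thickness identity is asserted for every row before
#' writing.
#'
#' @param reports a \code{permeability_report} or list of them.
#' @param path output path without extension; writes \code{<path>.json} and
#'   \code{<path>.tsv}.
#' @return named character vector of the files written, invisibly.
#' @export
write_report <- function(reports, path) {
  if (inherits(reports, "permeability_report")) reports <- list(reports)
  if (!length(reports)) stop("no reports to write")
  for (r in reports) {
    stopifnot(inherits(r, "permeability_report"))
    if (any(abs(r$table$p_wall -
                  pwall_from_dwall(r$table$d_wall, r$thickness)) >
            1e-12 * pmax(abs(r$table$p_wall), 1e-300)))
      stop("report row violates P_wall = D_wall / thickness")
  }
  json_path <- paste0(path, ".json")
  tsv_path <- paste0(path, ".tsv")
  payload <- lapply(reports, function(r)
    list(dextran_kda = r$dextran_kda, d_tiss = r$d_tiss,
         thickness_um = r$thickness, radius_nm = r$radius_nm,
         r2_phase3 = r$r2_phase3,
         animals = r$table,
         median_d_wall = r$median_d_wall,
         median_p_wall = r$median_p_wall))
  dir.create(dirname(json_path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e)
    stop("failed to write ", json_path, ": ", conditionMessage(e),
         call. = FALSE))
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(dextran_kda = r$dextran_kda, label = r$table$label,
               d_wall_um2_s = r$table$d_wall,
               median_d_wall_um2_s = r$median_d_wall,
               p_wall_cm_s = r$table$p_wall,
               median_p_wall_cm_s = r$median_p_wall)))
  utils::write.table(tab, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

#' Read back a written permeability report
#' @param path path used in \code{\link{write_report}} (without extension).
#' @return list of \code{permeability_report} objects.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  apply_one <- function(p)
    permeability_report(p$animals$d_wall, p$dextran_kda, p$d_tiss,
                        thickness = p$thickness_um, radius_nm = p$radius_nm,
                        labels = p$animals$label, r2_phase3 = p$r2_phase3)
  if (is.data.frame(payload)) {
    lapply(seq_len(nrow(payload)), function(i)
      apply_one(lapply(payload, function(col)
        if (is.list(col)) col[[i]] else col[i])))
  } else lapply(payload, apply_one)
}

#' Electrode configuration sanity check
#'
#' Validates that the recorded pulse amplitude equals the voltage-to-
#' distance ratio times the electrode gap (the field itself is experiment
#' metadata; no spatial field is computed).
#'
#' @param voltage_to_distance_v_cm ratio, V/cm.
#' @param gap_mm electrode gap, mm.
#' @param amplitude_v recorded amplitude, V.
#' @param tol relative tolerance.
#' @return \code{TRUE} invisibly, or an error describing the mismatch.
#' @export
check_electrode_config <- function(voltage_to_distance_v_cm, gap_mm,
                                   amplitude_v, tol = 1e-6) {
  expected <- voltage_to_distance_v_cm * gap_mm / 10
  if (abs(expected - amplitude_v) > tol * max(abs(expected), 1))
    stop(sprintf("amplitude %g V inconsistent with %g V/cm x %g mm (expect %g V)",
                 amplitude_v, voltage_to_distance_v_cm, gap_mm, expected))
  invisible(TRUE)
}
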