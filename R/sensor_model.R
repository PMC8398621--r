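# Vacuum permittivity, F/m
EPSILON_0 <- 8.854e-12

#' Textile capacitive sensor geometry
#'
#' Describes a parallel-plate textile capacitive pressure sensor: electrode
#' area, dielectric thickness and the relative permittivity of the nonwoven
#' dielectric. The default geometry is the 0.03 m x 0.03 m bench-test sensor
#' with a 1 mm dielectric.
#'
#' @param electrode_area Electrode area in m^2.
#' @param dielectric_thickness Distance between the electrode plates in m.
#' @param relative_permittivity Relative permittivity of the dielectric
#'   (dimensionless). Nonwoven fabric is close to air; default 1.2.
#' @return An object of class `sensor_spec`.
#' @examples
#' spec <- sensor_spec(electrode_area = 9e-4, dielectric_thickness = 1e-3)
#' parallel_plate_capacitance(spec)
#' @export
sensor_spec <- function(electrode_area = 9e-4,
                        dielectric_thickness = 1e-3,
                        relative_permittivity = 1.2) {
  if (!is.numeric(electrode_area) || electrode_area <= 0)
    stop("invalid sensor spec: electrode_area must be > 0", call. = FALSE)
  if (!is.numeric(dielectric_thickness) || dielectric_thickness <= 0)
    stop("invalid sensor spec: dielectric_thickness must be > 0", call. = FALSE)
  if (!is.numeric(relative_permittivity) || relative_permittivity <= 0)
    stop("invalid sensor spec: relative_permittivity must be > 0", call. = FALSE)
  structure(
    list(electrode_area = electrode_area,
         dielectric_thickness = dielectric_thickness,
         relative_permittivity = relative_permittivity,
         vacuum_permittivity = EPSILON_0),
    class = "sensor_spec")
}

#' Parallel-plate capacitance of a sensor
#'
#' Computes C = eps_r * eps_0 * A / d for a `sensor_spec`.
#'
#' @param spec A [sensor_spec()].
#' @return Capacitance in farads.
#' @export
parallel_plate_capacitance <- function(spec) {
  stopifnot(inherits(spec, "sensor_spec"))
  spec$relative_permittivity * spec$vacuum_permittivity *
    spec$electrode_area / spec$dielectric_thickness
}

#' Plantar pressure from a load
#'
#' Pressure P = F / S for a force F (N) distributed over a stress area S
#' (m^2), returned in kPa. With the minimal insole stress area of a 23.5 cm
#' shoe with an 8.0 cm ball width (0.0188 m^2) and an 80 kg body weight this
#' gives 41.74 kPa, the full-support mid-stance estimate.
#'
#' @param force Applied force in newtons; must be >= 0.
#' @param stress_area Contact area in m^2; must be > 0.
#' @return Pressure in kPa.
#' @examples
#' pressure_from_force(80 * 9.81, 0.235 * 0.08) # ~41.74 kPa
#' @export
pressure_from_force <- function(force, stress_area) {
  if (!is.numeric(force) || any(force < 0))
    stop("invalid load case: force must be >= 0", call. = FALSE)
  if (!is.numeric(stress_area) || any(stress_area <= 0))
    stop("invalid load case: stress_area must be > 0", call. = FALSE)
  force / stress_area / 1000
}

#' Piecewise calibration curve of the textile sensor
#'
#' The sensor's relative capacitance change (Delta C / C0) grows linearly with
#' pressure but saturates: the measured sensitivity is 0.232 MPa^-1 below
#' 11.00 kPa and 0.070 MPa^-1 above it. The forward map is continuous at the
#' breakpoint and strictly increasing, hence invertible.
#'
#' @param base_capacitance_pF Unloaded capacitance C0 in pF. Defaults to the
#'   value implied by the default [sensor_spec()] geometry.
#' @param breakpoint_kPa Pressure at which sensitivity changes, kPa.
#' @param low_sensitivity_per_MPa Sensitivity below the breakpoint, MPa^-1.
#' @param high_sensitivity_per_MPa Sensitivity above the breakpoint, MPa^-1.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(base_capacitance_pF =
                                parallel_plate_capacitance(sensor_spec()) * 1e12,
                              breakpoint_kPa = 11.0,
                              low_sensitivity_per_MPa = 0.232,
                              high_sensitivity_per_MPa = 0.070) {
  if (low_sensitivity_per_MPa <= 0 || high_sensitivity_per_MPa <= 0)
    stop("calibration sensitivities must be > 0", call. = FALSE)
  if (low_sensitivity_per_MPa < high_sensitivity_per_MPa)
    stop("saturating curve requires low_sensitivity >= high_sensitivity",
         call. = FALSE)
  if (breakpoint_kPa <= 0)
    stop("breakpoint_kPa must be > 0", call. = FALSE)
  structure(
    list(base_capacitance_pF = base_capacitance_pF,
         breakpoint_kPa = breakpoint_kPa,
         low_sensitivity_per_MPa = low_sensitivity_per_MPa,
         high_sensitivity_per_MPa = high_sensitivity_per_MPa),
    class = "calibration_curve")
}

#' Relative capacitance change at a given pressure
#'
#' Evaluates the piecewise-linear calibration curve: sensitivity is in MPa^-1
#' and pressure in kPa, so the slope applied is `sensitivity / 1000` per kPa.
#'
#' @param pressure_kPa Pressure(s) in kPa; must be >= 0.
#' @param curve A [calibration_curve()].
#' @return Relative capacitance change Delta C / C0 (dimensionless).
#' @export
relative_capacitance_change <- function(pressure_kPa,
                                        curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(pressure_kPa < 0))
    stop("pressure must be >= 0", call. = FALSE)
  bp <- curve$breakpoint_kPa
  s_lo <- curve$low_sensitivity_per_MPa / 1000   # per kPa
  s_hi <- curve$high_sensitivity_per_MPa / 1000
  at_bp <- s_lo * bp
  ifelse(pressure_kPa <= bp,
         s_lo * pressure_kPa,
         at_bp + s_hi * (pressure_kPa - bp))
}

#' Pressure from a measured relative capacitance change
#'
#' Exact inverse of [relative_capacitance_change()] on its range; this is the
#' conversion used to turn capacitance counts into kPa.
#'
#' @param fraction Relative capacitance change(s); must be >= 0.
#' @param curve A [calibration_curve()].
#' @return Pressure in kPa.
#' @export
pressure_from_capacitance <- function(fraction, curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(fraction < 0))
    stop("capacitance fraction must be >= 0", call. = FALSE)
  bp <- curve$breakpoint_kPa
  s_lo <- curve$low_sensitivity_per_MPa / 1000
  s_hi <- curve$high_sensitivity_per_MPa / 1000
  at_bp <- s_lo * bp
  ifelse(fraction <= at_bp,
         fraction / s_lo,
         bp + (fraction - at_bp) / s_hi)
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat("Textile capacitive sensor spec\n")
  cat(sprintf("  electrode area       : %.3g m^2\n", x$electrode_area))
  cat(sprintf("  dielectric thickness : %.3g m\n", x$dielectric_thickness))
  cat(sprintf("  relative permittivity: %.3g\n", x$relative_permittivity))
  cat(sprintf("  capacitance          : %.4g pF\n",
              parallel_plate_capacitance(x) * 1e12))
  invisible(x)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Piecewise sensor calibration curve\n")
  cat(sprintf("  C0         : %.4g pF\n", x$base_capacitance_pF))
  cat(sprintf("  breakpoint : %.4g kPa\n", x$breakpoint_kPa))
  cat(sprintf("  sensitivity: %.3g MPa^-1 (low), %.3g MPa^-1 (high)\n",
              x$low_sensitivity_per_MPa, x$high_sensitivity_per_MPa))
  invisible(x)
}
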