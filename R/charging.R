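# Electrostatic charging arithmetic for the beam-irradiated spot on the
# insulating membrane: the spot is treated as a small parallel-plate
# capacitor through the film, and the dose bookkeeping asks how many of the
# electrons hitting one pixel are needed to charge it to the field-emission
# threshold.
#
# The elementary charge is deliberately q = 1.602e-19 C (not full CODATA
# precision): the method's per-pixel dose of 5,963 electrons is defined with
# this rounding.

#' Capacitor model of the irradiated spot
#'
#' Defaults describe a 3-nm-diameter beam spot (area 7.07 nm^2) across a
#' 50-nm SiN membrane of relative permittivity 7.5.
#'
#' @param relative_permittivity dimensionless dielectric constant.
#' @param area plate area, nm^2.
#' @param length plate separation (film thickness), nm.
#' @export
capacitor_model <- function(relative_permittivity = 7.5, area = 7.07,
                            length = 50) {
  vals <- c(relative_permittivity, area, length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all capacitor parameters must be positive", call. = FALSE)
  }
  structure(list(relative_permittivity = relative_permittivity,
                 area = area, length = length),
            class = "capacitor_model")
}

#' Capacitance of the irradiated-spot capacitor
#'
#' C = eps0 * eps * A / d with eps0 = 8.854e-12 F/m; A and d are given in
#' nm^2 and nm and converted internally.
#'
#' @param model a [capacitor_model()].
#' @return capacitance in farad.
#' @examples
#' capacitance(capacitor_model())  # 9.39e-21 F
#' @export
capacitance <- function(model) {
  stopifnot(inherits(model, "capacitor_model"))
  .EPSILON0 * model$relative_permittivity *
    (model$area * 1e-18) / (model$length * 1e-9)
}

#' Potential gained per trapped electron
#'
#' V = q / C.
#'
#' @param C capacitance, F.
#' @return potential in volt.
#' @export
potential_per_electron <- function(C) {
  if (any(C <= 0)) stop("C must be > 0", call. = FALSE)
  .Q_ELECTRON / C
}

#' Electrons needed to charge a capacitor to a target potential
#'
#' The smallest integer n with n q / C >= V, i.e. ceiling(V C / q).
#'
#' @param V_target target potential, V.
#' @param C capacitance, F.
#' @export
electrons_for_potential <- function(V_target, C) {
  if (any(V_target <= 0) || any(C <= 0)) {
    stop("V_target and C must be > 0", call. = FALSE)
  }
  # slack absorbs floating error when V_target is an exact multiple of q/C
  as.integer(ceiling(V_target * C / .Q_ELECTRON - 1e-9))
}

#' Electrons delivered to one scan pixel per frame
#'
#' round(current * frame_time / (q * width * height)).
#'
#' @param current beam current, pA.
#' @param frame_time frame scan time, s.
#' @param width,height scan size in pixels.
#' @export
electrons_per_pixel <- function(current, frame_time, width, height) {
  vals <- c(current, frame_time, width, height)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  as.integer(round(current * 1e-12 * frame_time /
                     (.Q_ELECTRON * width * height)))
}

#' Electric field inside the film
#'
#' V / d converted to V/cm. Field emission through the film is expected
#' above about 1e7 V/cm (10 MV/cm).
#'
#' @param V potential across the film, V.
#' @param d film thickness, nm.
#' @return field in V/cm.
#' @export
internal_field <- function(V, d) {
  if (any(d <= 0)) stop("d must be > 0 nm", call. = FALSE)
  V / (d * 1e-7)
}

#' Field-emission threshold, V/cm
#' @export
field_emission_threshold <- function() 1e7

#' Assemble the full charging report
#'
#' Combines the capacitor arithmetic with the beam's per-pixel dose:
#' capacitance, potential per trapped electron, number of electrons needed
#' to reach `V_target` on the film, electrons irradiating one pixel, and the
#' fraction of a pixel's dose spent on charging. The electron count is the
#' arithmetic value ceiling(V C / q) unless `electrons_override` supplies a
#' different (e.g. historically quoted) count; the arithmetic value is
#' always retained alongside.
#'
#' @param model a [capacitor_model()].
#' @param beam a [beam_spec()].
#' @param V_target target charging potential on the film, V.
#' @param electrons_override optional integer replacing the arithmetic
#'   electron count in the fraction (kept explicit, never silent).
#' @return a `charging_report`.
#' @export
charging_report <- function(model, beam, V_target = 400,
                            electrons_override = NULL) {
  stopifnot(inherits(model, "capacitor_model"), inherits(beam, "beam_spec"))
  C <- capacitance(model)
  vpe <- potential_per_electron(C)
  n_arith <- electrons_for_potential(V_target, C)
  n_used <- if (is.null(electrons_override)) n_arith else
    as.integer(electrons_override)
  dose <- electrons_per_pixel(beam$current, beam$frame_time,
                              beam$image_width, beam$image_height)
  structure(list(
    capacitance = C,
    volts_per_electron = vpe,
    target_potential = V_target,
    electrons_for_threshold = n_used,
    electrons_for_threshold_arithmetic = n_arith,
    electrons_per_pixel = dose,
    charging_fraction = n_used / dose,
    internal_field = internal_field(V_target, model$length),
    above_field_emission_threshold =
      internal_field(V_target, model$length) >= field_emission_threshold()
  ), class = "charging_report")
}

#' @export
print.charging_report <- function(x, ...) {
  cat("<charging_report>\n")
  cat(sprintf("  capacitance            %.3g F\n", x$capacitance))
  cat(sprintf("  potential per electron %.4g V\n", x$volts_per_electron))
  cat(sprintf("  electrons to reach %g V: %d (arithmetic %d)\n",
              x$target_potential, x$electrons_for_threshold,
              x$electrons_for_threshold_arithmetic))
  cat(sprintf("  electrons per pixel    %d\n", x$electrons_per_pixel))
  cat(sprintf("  charging fraction      %.2f%%\n",
              100 * x$charging_fraction))
  cat(sprintf("  internal field         %.3g V/cm (%s threshold)\n",
              x$internal_field,
              if (x$above_field_emission_threshold) "above" else "below"))
  invisible(x)
}
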