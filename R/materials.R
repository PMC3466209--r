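# Material and beam data model + per-material electron physics.
# Units: energy keV, length nm, density g/cm^3, cross-section cm^2.

# minimal element table (Z, atomic mass g/mol) for the materials users of a
# thin-film SEM model realistically ask for
.ELEMENTS <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "Na", "Mg", "Al", "Si", "P", "S", "Cl",
             "K", "Ca", "Ti", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ge",
             "Mo", "Pd", "Ag", "Sn", "Ta", "W", "Pt", "Au", "Pb"),
  Z = c(1L, 5L, 6L, 7L, 8L, 11L, 12L, 13L, 14L, 15L, 16L, 17L, 19L, 20L,
        22L, 24L, 25L, 26L, 27L, 28L, 29L, 30L, 32L, 42L, 46L, 47L, 50L,
        73L, 74L, 78L, 79L, 82L),
  atomic_mass = c(1.008, 10.81, 12.011, 14.007, 15.999, 22.990, 24.305,
                  26.982, 28.085, 30.974, 32.06, 35.45, 39.098, 40.078,
                  47.867, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546,
                  65.38, 72.63, 95.95, 106.42, 107.87, 118.71, 180.95,
                  183.84, 195.08, 196.97, 207.2),
  stringsAsFactors = FALSE
)

#' Look up or construct a chemical element
#'
#' @param symbol element symbol, e.g. `"Au"`.
#' @param Z atomic number; looked up from the built-in table when `NULL`.
#' @param atomic_mass atomic mass in g/mol; looked up when `NULL`.
#' @return an object of class `element` with fields `symbol`, `Z`,
#'   `atomic_mass`.
#' @examples
#' element("Si")
#' element("X", Z = 40, atomic_mass = 91.2)
#' @export
element <- function(symbol, Z = NULL, atomic_mass = NULL) {
  if (is.null(Z) || is.null(atomic_mass)) {
    row <- .ELEMENTS[.ELEMENTS$symbol == symbol, ]
    if (nrow(row) != 1L) {
      stop("unknown element symbol '", symbol,
           "'; supply Z and atomic_mass explicitly", call. = FALSE)
    }
    if (is.null(Z)) Z <- row$Z
    if (is.null(atomic_mass)) atomic_mass <- row$atomic_mass
  }
  Z <- as.integer(Z)
  if (is.na(Z) || Z < 1L) stop("Z must be a positive integer", call. = FALSE)
  if (!is.numeric(atomic_mass) || atomic_mass <= Z * 0.9) {
    stop("atomic_mass must exceed 0.9*Z (g/mol)", call. = FALSE)
  }
  structure(list(symbol = symbol, Z = Z, atomic_mass = atomic_mass),
            class = "element")
}

#' Define a material as a density plus element weight fractions
#'
#' @param name material name.
#' @param density mass density in g/cm^3.
#' @param composition named numeric vector of weight fractions (names are
#'   element symbols), or a list of `element`/fraction pairs. Fractions must
#'   lie in (0, 1] and sum to 1 within 1e-9.
#' @return an object of class `material`.
#' @examples
#' material("SiN", 3.12, c(Si = 0.6006, N = 0.3994))
#' @export
material <- function(name, density, composition) {
  if (!is.numeric(density) || density <= 0) {
    stop("density must be > 0 g/cm^3", call. = FALSE)
  }
  if (is.numeric(composition)) {
    syms <- names(composition)
    if (is.null(syms)) stop("composition vector must be named", call. = FALSE)
    elements <- lapply(syms, element)
    fractions <- as.numeric(composition)
  } else {
    elements <- lapply(composition, `[[`, "element")
    fractions <- vapply(composition, `[[`, numeric(1), "fraction")
  }
  if (any(fractions <= 0) || any(fractions > 1)) {
    stop("weight fractions must lie in (0, 1]", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("weight fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  structure(list(name = name, density = density, elements = elements,
                 fractions = fractions),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  comp <- paste(sprintf("%s %.4f", vapply(x$elements, `[[`, "", "symbol"),
                        x$fractions), collapse = ", ")
  cat(sprintf("<material> %s  rho = %.3g g/cm^3  [%s]\n",
              x$name, x$density, comp))
  invisible(x)
}

#' A single film layer
#'
#' @param material a [material()].
#' @param thickness layer thickness in nm (> 0).
#' @export
layer <- function(material, thickness) {
  stopifnot(inherits(material, "material"))
  if (!is.numeric(thickness) || thickness <= 0) {
    stop("layer thickness must be > 0 nm", call. = FALSE)
  }
  structure(list(material = material, thickness = thickness), class = "layer")
}

#' An ordered stack of film layers
#'
#' Layers are listed from the beam-entry side downward.
#'
#' @param ... `layer` objects (or a single list of them).
#' @return object of class `film_stack` with a derived `total_thickness`.
#' @export
film_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "layer")) {
    layers <- layers[[1L]]
  }
  if (length(layers) < 1L) stop("a film stack needs >= 1 layer", call. = FALSE)
  ok <- vapply(layers, inherits, logical(1), "layer")
  if (!all(ok)) stop("all stack entries must be layer objects", call. = FALSE)
  thick <- vapply(layers, `[[`, numeric(1), "thickness")
  structure(list(layers = layers, total_thickness = sum(thick)),
            class = "film_stack")
}

#' @export
print.film_stack <- function(x, ...) {
  cat(sprintf("<film_stack> %d layer(s), total %.4g nm\n",
              length(x$layers), x$total_thickness))
  for (l in x$layers) {
    cat(sprintf("  %-6s %6.4g nm  (%.3g g/cm^3)\n",
                l$material$name, l$thickness, l$material$density))
  }
  invisible(x)
}

#' Electron-beam and scan description
#'
#' Defaults follow the imaging conditions of the method this package models:
#' 31.3 pA beam current, 3 nm spot, 1280 x 1024 scan, 40 s frame time.
#'
#' @param voltage accelerating voltage in kV (0.1-30; the physics model is
#'   not validated above 30 kV).
#' @param spot_diameter beam spot diameter (FWHM for a Gaussian profile), nm.
#' @param current beam current, pA.
#' @param image_width,image_height scan size in pixels.
#' @param frame_time scan time for a full frame, s.
#' @export
beam_spec <- function(voltage, spot_diameter = 3, current = 31.3,
                      image_width = 1280, image_height = 1024,
                      frame_time = 40) {
  vals <- c(voltage, spot_diameter, current, image_width, image_height,
            frame_time)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all beam parameters must be positive and finite", call. = FALSE)
  }
  if (voltage < 0.1 || voltage > 30) {
    stop("voltage must lie in [0.1, 30] kV", call. = FALSE)
  }
  structure(list(voltage = voltage, spot_diameter = spot_diameter,
                 current = current, image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 frame_time = frame_time),
            class = "beam_spec")
}

#' Built-in material library
#'
#' SiN (Si3N4 stoichiometry, 3.12 g/cm^3), Ni (8.9 g/cm^3) and
#' Au (19.3 g/cm^3), the components of the metal-coated membrane.
#'
#' @return named list of [material()] objects.
#' @export
material_library <- function() {
  list(
    SiN = material("SiN", 3.12, c(Si = 0.6006, N = 0.3994)),
    Ni = material("Ni", 8.9, c(Ni = 1)),
    Au = material("Au", 19.3, c(Au = 1))
  )
}

#' The metal-coated SiN film stack
#'
#' SiN membrane coated with 15 nm Ni and 10 nm Au, beam entering on the SiN
#' side. The membrane thickness is configurable: 60 nm is the transport
#' default, 50 nm the nominal membrane used for imaging and for the
#' charging capacitor.
#'
#' @param sin_thickness SiN membrane thickness, nm.
#' @param ni_thickness,au_thickness metal layer thicknesses, nm.
#' @export
metal_coated_sin_stack <- function(sin_thickness = 60, ni_thickness = 15,
                                   au_thickness = 10) {
  lib <- material_library()
  film_stack(layer(lib$SiN, sin_thickness),
             layer(lib$Ni, ni_thickness),
             layer(lib$Au, au_thickness))
}

#' Berger-Seltzer mean ionization potential
#'
#' J = (9.76 Z + 58.5 Z^-0.19) * 1e-3 keV for Z >= 13, and
#' J = 11.5 Z * 1e-3 keV below.
#'
#' @param Z atomic number(s), positive integer.
#' @return mean ionization potential in keV.
#' @export
mean_ionization_potential <- function(Z) {
  if (any(!is.finite(Z)) || any(Z < 1) || any(Z != round(Z))) {
    stop("Z must be a positive integer", call. = FALSE)
  }
  ifelse(Z < 13, 11.5 * Z * 1e-3,
         (9.76 * Z + 58.5 * Z^(-0.19)) * 1e-3)
}

#' Screening parameter of the screened-Rutherford cross-section
#'
#' alpha = 3.4e-3 Z^0.67 / E with E in keV.
#'
#' @param Z atomic number.
#' @param E electron energy, keV.
#' @export
screening_parameter <- function(Z, E) {
  3.4e-3 * Z^0.67 / E
}

#' Total screened-Rutherford elastic cross-section
#'
#' sigma(Z, E) = 5.21e-21 (Z^2/E^2) (4 pi / (alpha (1 + alpha)))
#' ((E + 511)/(E + 1024))^2 cm^2, with the screening parameter of
#' [screening_parameter()] and the relativistic factor constant 1024
#' (Joy's convention; pinned so all tests share one convention).
#'
#' @param Z atomic number.
#' @param E electron energy in keV; must exceed the 0.05 keV validity floor.
#' @return cross-section in cm^2.
#' @export
elastic_cross_section <- function(Z, E) {
  if (any(E <= 0.05)) stop("E must be > 0.05 keV", call. = FALSE)
  a <- screening_parameter(Z, E)
  rel <- (E + 511) / (E + 1024)
  5.21e-21 * (Z^2 / E^2) * (4 * pi / (a * (1 + a))) * rel^2
}

#' Elastic mean free path in a material
#'
#' 1/lambda = sum_i N_A rho w_i / A_i * sigma(Z_i, E), returned in nm.
#'
#' @param material a [material()].
#' @param E electron energy, keV (> 0.05).
#' @export
elastic_mfp <- function(material, E) {
  stopifnot(inherits(material, "material"))
  inv <- 0
  for (i in seq_along(material$elements)) {
    el <- material$elements[[i]]
    n_i <- .AVOGADRO * material$density * material$fractions[i] / el$atomic_mass
    inv <- inv + n_i * elastic_cross_section(el$Z, E)
  }
  1e7 / inv  # cm -> nm
}

#' Joy-Luo stopping power
#'
#' dE/ds = 7.85e4 (rho/E) sum_i (w_i Z_i / A_i)
#' ln(1.166 (E + k_i J_i) / J_i) keV/cm with k_i = 0.731 + 0.0688 log10 Z_i,
#' converted to keV/nm. The k_i J_i offset keeps the formula positive down to
#' the 0.05 keV transport cutoff.
#'
#' @param material a [material()].
#' @param E electron energy, keV, in (0.05, 30].
#' @return energy loss per unit path, keV/nm.
#' @export
stopping_power <- function(material, E) {
  stopifnot(inherits(material, "material"))
  if (any(E <= 0.05) || any(E > 30)) {
    stop("E must lie in (0.05, 30] keV", call. = FALSE)
  }
  s <- 0
  for (i in seq_along(material$elements)) {
    el <- material$elements[[i]]
    k_i <- 0.731 + 0.0688 * log10(el$Z)
    J_i <- mean_ionization_potential(el$Z)
    s <- s + material$fractions[i] * el$Z / el$atomic_mass *
      log(1.166 * (E + k_i * J_i) / J_i)
  }
  7.85e4 * (material$density / E) * s * 1e-7
}

# flatten a film_stack into the argument set the C++ engine takes
.stack_tables <- function(stack) {
  stopifnot(inherits(stack, "film_stack"))
  thick <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  list(
    bounds = c(0, cumsum(thick)),
    layers = lapply(stack$layers, function(l) {
      m <- l$material
      list(density = m$density,
           Z = vapply(m$elements, `[[`, integer(1), "Z"),
           A = vapply(m$elements, `[[`, numeric(1), "atomic_mass"),
           w = m$fractions)
    })
  )
}
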