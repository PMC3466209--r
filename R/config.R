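# Run configuration: a flat YAML schema whose defaults are the reference
# operating point of the method (metal-coated SiN stack, 31.3 pA, 40 s
# frame, 1280 x 1024 scan, 3 nm spot).

.default_config <- function() {
  list(
    stack = list(list(material = "SiN", thickness = 60),
                 list(material = "Ni", thickness = 15),
                 list(material = "Au", thickness = 10)),
    materials = list(),
    beam = list(voltage = 4.0, spot_diameter = 3, current = 31.3,
                image_width = 1280, image_height = 1024, frame_time = 40),
    transport = list(n_electrons = 100000, cutoff_energy = 0.05,
                     max_steps = 10000, beam_profile = "gaussian"),
    capacitor = list(relative_permittivity = 7.5, area = 7.07, length = 50),
    pipeline = list(filter_size = 9, filter_sigma = 1, iterations = 12,
                    psf_size = 241, sigma_narrow = 12, sigma_wide = 60,
                    weight_wide = 1 / 3),
    seed = 1,
    output_dir = "."
  )
}

.check_keys <- function(user, ref, path) {
  allowed <- if (is.character(ref)) ref else names(ref)
  unknown <- setdiff(names(user), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key: '",
         paste0(path, unknown[1L], collapse = ""), "'", call. = FALSE)
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills unset keys with the package defaults, rejects
#' unknown keys by name, and constructs the validated component objects.
#' An empty (or missing-content) file yields the full default
#' configuration. Custom materials may be declared under `materials:` as
#' entries with `name`, `density` and a `composition` list of
#' `{symbol, fraction}` pairs, and referenced by name in `stack:`.
#'
#' @param path path to a YAML configuration file.
#' @return a `run_config`: validated `stack`, `beam`, `transport`,
#'   `capacitor`, `pipeline`, `seed`, `output_dir`, plus the merged raw
#'   list in `$raw`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  ref <- .default_config()
  .check_keys(user, ref, "")
  merged <- ref
  for (nm in names(user)) {
    if (nm %in% c("stack", "materials")) {
      merged[[nm]] <- user[[nm]]
    } else if (is.list(ref[[nm]])) {
      .check_keys(user[[nm]], ref[[nm]], paste0(nm, "."))
      merged[[nm]] <- utils::modifyList(ref[[nm]], user[[nm]])
    } else {
      merged[[nm]] <- user[[nm]]
    }
  }

  lib <- material_library()
  for (m in merged$materials) {
    .check_keys(m, c("name", "density", "composition"), "materials.")
    comp <- vapply(m$composition, `[[`, numeric(1), "fraction")
    names(comp) <- vapply(m$composition, `[[`, character(1), "symbol")
    lib[[m$name]] <- material(m$name, m$density, comp)
  }
  layers <- lapply(merged$stack, function(l) {
    .check_keys(l, c("material", "thickness"), "stack.")
    if (is.null(lib[[l$material]])) {
      stop("unknown material '", l$material, "' in stack", call. = FALSE)
    }
    layer(lib[[l$material]], l$thickness)
  })

  b <- merged$beam
  beam <- beam_spec(b$voltage, b$spot_diameter, b$current, b$image_width,
                    b$image_height, b$frame_time)
  tr <- merged$transport
  transport <- transport_config(tr$n_electrons, tr$cutoff_energy,
                                tr$max_steps, merged$seed, tr$beam_profile)
  cp <- merged$capacitor
  structure(list(
    stack = film_stack(layers),
    beam = beam,
    transport = transport,
    capacitor = capacitor_model(cp$relative_permittivity, cp$area,
                                cp$length),
    pipeline = merged$pipeline,
    seed = merged$seed,
    output_dir = merged$output_dir,
    raw = merged
  ), class = "run_config")
}

#' Write a configuration back to YAML
#'
#' Serializes the merged raw configuration so that
#' `load_config(dump_config(cfg, f))` reproduces `cfg`.
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path, precision = 15)
  invisible(path)
}
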