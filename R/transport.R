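# Monte Carlo electron transport: R-level API over the compiled engine, plus
# the elementary sampling/stepping operations used by diagnostic and
# oracle-style tests.

#' Transport run configuration
#'
#' @param n_electrons number of primary electrons to launch (>= 1).
#' @param cutoff_energy energy (keV) below which an electron counts as
#'   absorbed; residual energy is booked as deposited at its last position.
#' @param max_steps per-electron step budget.
#' @param rng_seed integer seed; per-electron substreams are derived from it
#'   by stable splitting, so trajectories do not reshuffle when
#'   `n_electrons` changes.
#' @param beam_profile `"gaussian"` (FWHM = spot diameter) or `"disk"`
#'   (uniform top-hat of that diameter).
#' @export
transport_config <- function(n_electrons, cutoff_energy = 0.05,
                             max_steps = 10000L, rng_seed = 1L,
                             beam_profile = c("gaussian", "disk")) {
  beam_profile <- match.arg(beam_profile)
  if (!is.numeric(n_electrons) || n_electrons < 1) {
    stop("n_electrons must be >= 1", call. = FALSE)
  }
  if (cutoff_energy <= 0) stop("cutoff_energy must be > 0", call. = FALSE)
  structure(list(n_electrons = as.integer(n_electrons),
                 cutoff_energy = cutoff_energy,
                 max_steps = as.integer(max_steps),
                 rng_seed = as.integer(rng_seed),
                 beam_profile = beam_profile),
            class = "transport_config")
}

#' Sample an exponential free path
#'
#' s = -mfp * log(u) for u in (0, 1].
#'
#' @param mfp mean free path, nm.
#' @param u uniform variate(s) in (0, 1].
#' @export
sample_free_path <- function(mfp, u) {
  if (any(mfp <= 0)) stop("mfp must be > 0", call. = FALSE)
  if (any(u <= 0) || any(u > 1)) stop("u must lie in (0, 1]", call. = FALSE)
  -mfp * log(u)
}

#' Sample the polar scattering angle of a screened-Rutherford event
#'
#' Inverse-CDF form: cos(theta) = 1 - 2 alpha u / (1 + alpha - u).
#'
#' @param alpha screening parameter (see [screening_parameter()]).
#' @param u uniform variate(s) in \[0, 1\].
#' @return cosine of the polar deflection angle, in \[-1, 1\].
#' @export
sample_polar_angle <- function(alpha, u) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  if (any(u < 0) || any(u > 1)) stop("u must lie in [0, 1]", call. = FALSE)
  ct <- 1 - 2 * alpha * u / (1 + alpha - u)
  pmin(1, pmax(-1, ct))
}

#' Rotate a unit direction by polar angle theta and azimuth phi
#'
#' @param direction unit 3-vector.
#' @param theta polar deflection, rad.
#' @param phi azimuth about the incoming direction, rad.
#' @return unit 3-vector.
#' @export
rotate_direction <- function(direction, theta, phi) {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-12) {
    stop("direction must have nonzero norm", call. = FALSE)
  }
  if (abs(nrm - 1) > 1e-9) stop("direction must be a unit vector", call. = FALSE)
  u <- direction
  ct <- cos(theta); st <- sin(theta)
  cf <- cos(phi); sf <- sin(phi)
  if (abs(u[3]) > 0.999999) {
    out <- c(st * cf, st * sf, sign(u[3]) * ct)
  } else {
    dd <- sqrt(1 - u[3]^2)
    out <- c(u[1] * ct + st * (u[1] * u[3] * cf - u[2] * sf) / dd,
             u[2] * ct + st * (u[2] * u[3] * cf + u[1] * sf) / dd,
             u[3] * ct - dd * st * cf)
  }
  out / sqrt(sum(out^2))
}

#' Electron state for step-by-step transport
#'
#' @param position (x, y, z) in nm; z = 0 is the beam-entry surface, z
#'   increases into the film.
#' @param direction unit 3-vector of travel.
#' @param energy kinetic energy, keV.
#' @param status `"in-flight"`, `"transmitted"`, `"backscattered"` or
#'   `"absorbed"`.
#' @export
electron_state <- function(position = c(0, 0, 0), direction = c(0, 0, 1),
                           energy, status = "in-flight") {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9) {
    stop("direction must be a unit vector", call. = FALSE)
  }
  if (energy < 0) stop("energy must be >= 0", call. = FALSE)
  structure(list(position = position, direction = direction, energy = energy,
                 status = status, deposited = 0),
            class = "electron_state")
}

# which layer contains depth z
.layer_index <- function(bounds, z) {
  i <- findInterval(z, bounds, rightmost.closed = TRUE)
  min(max(i, 1L), length(bounds) - 1L)
}

#' Advance an electron by one free-flight + scattering event
#'
#' Reference (pure R) implementation of the transport step used by the
#' compiled engine: exponential free path in the current layer, truncation
#' at layer interfaces (advance 1e-6 nm into the next medium and resample
#' there), continuous slowing down at the Joy-Luo rate, screened-Rutherford
#' angular deflection. Draws from R's global RNG. Fates: crossing z = 0
#' upward is backscattering, crossing the bottom is transmission, dropping
#' to the cutoff is absorption (residual energy booked as deposited).
#'
#' @param state an [electron_state()].
#' @param stack a [film_stack()].
#' @param cutoff_energy absorption cutoff, keV.
#' @param mfp_fn,stopping_fn physics overrides for diagnostics; defaults are
#'   [elastic_mfp()] and [stopping_power()].
#' @return the updated `electron_state`; `$deposited` accumulates the energy
#'   left in the film so that initial energy = deposited + exit kinetic
#'   energy at the end of a trajectory.
#' @export
step_electron <- function(state, stack, cutoff_energy = 0.05,
                          mfp_fn = elastic_mfp, stopping_fn = stopping_power) {
  stopifnot(inherits(state, "electron_state"), inherits(stack, "film_stack"))
  if (state$status != "in-flight") return(state)
  tab <- .stack_tables(stack)
  bounds <- tab$bounds
  li <- .layer_index(bounds, state$position[3])
  mat <- stack$layers[[li]]$material
  lambda <- mfp_fn(mat, state$energy)
  sp <- stopping_fn(mat, state$energy)
  s_free <- sample_free_path(lambda, stats::runif(1, min = 1e-12, max = 1))

  u <- state$direction
  z <- state$position[3]
  t_bound <- Inf
  if (u[3] > 1e-12) t_bound <- (bounds[li + 1] - z) / u[3]
  if (u[3] < -1e-12) t_bound <- (bounds[li] - z) / u[3]

  scatter <- s_free < t_bound
  step_len <- if (scatter) s_free else t_bound + 1e-6
  de <- min(sp * step_len, state$energy)
  state$position <- state$position + u * step_len
  state$energy <- state$energy - de
  state$deposited <- state$deposited + de

  znew <- state$position[3]
  if (!scatter && znew <= 0) {
    state$status <- "backscattered"
  } else if (!scatter && znew >= stack$total_thickness) {
    state$status <- "transmitted"
  } else if (state$energy <= cutoff_energy) {
    state$deposited <- state$deposited + state$energy
    state$energy <- 0
    state$status <- "absorbed"
  } else if (scatter) {
    # element chosen with probability ~ n_i sigma_i
    n_sig <- vapply(seq_along(mat$elements), function(i) {
      el <- mat$elements[[i]]
      .AVOGADRO * mat$density * mat$fractions[i] / el$atomic_mass *
        elastic_cross_section(el$Z, state$energy)
    }, numeric(1))
    zi <- mat$elements[[sample.int(length(n_sig), 1L,
                                   prob = n_sig / sum(n_sig))]]$Z
    a <- screening_parameter(zi, state$energy)
    ct <- sample_polar_angle(a, stats::runif(1))
    state$direction <- rotate_direction(u, acos(ct),
                                        stats::runif(1, 0, 2 * pi))
  }
  state
}

#' Run a Monte Carlo transport simulation
#'
#' Launches `config$n_electrons` electrons at z = 0 travelling straight
#' down, entry (x, y) drawn from the beam profile, and follows each through
#' the stack with single elastic scattering and continuous slowing down.
#' Deterministic given `config$rng_seed`.
#'
#' @param stack a [film_stack()].
#' @param beam a [beam_spec()]; its voltage sets the initial energy in keV.
#' @param config a [transport_config()].
#' @param bin_width histogram bin width for the exit-position summaries, nm.
#' @return a `transport_summary`: fate counts and fractions, the lateral
#'   (x-marginal) exit profile and radial exit histogram of transmitted
#'   electrons, per-electron deposited/exit energies, and the run inputs.
#' @export
run_transport <- function(stack, beam, config, bin_width = 2) {
  stopifnot(inherits(stack, "film_stack"), inherits(beam, "beam_spec"),
            inherits(config, "transport_config"))
  if (length(stack$layers) < 1L) stop("stack has no layers", call. = FALSE)
  tab <- .stack_tables(stack)
  res <- .cpp_run_transport(
    tab$bounds, tab$layers, beam$voltage, beam$spot_diameter,
    if (config$beam_profile == "gaussian") 0L else 1L,
    config$n_electrons, config$cutoff_energy, config$max_steps,
    as.double(config$rng_seed %% 2^31)
  )
  n <- config$n_electrons
  n_t <- sum(res$fate == 0L)
  n_b <- sum(res$fate == 1L)
  n_a <- sum(res$fate == 2L)
  tx <- res$exit_x[res$fate == 0L]
  ty <- res$exit_y[res$fate == 0L]

  lateral <- .bin_counts(tx, bin_width)
  radial <- .bin_counts(sqrt(tx^2 + ty^2), bin_width, radial = TRUE)

  structure(list(
    n_electrons = n,
    n_transmitted = n_t, n_backscattered = n_b, n_absorbed = n_a,
    fractions = c(transmitted = n_t / n, backscattered = n_b / n,
                  absorbed = n_a / n),
    exit_x = tx, exit_y = ty,
    exit_lateral_profile = lateral,
    exit_radial_histogram = radial,
    bin_width = bin_width,
    deposited = res$deposited,
    exit_energy = res$exit_energy,
    fate = res$fate,
    n_steps = res$n_steps,
    voltage = beam$voltage,
    seed = config$rng_seed
  ), class = "transport_summary")
}

# symmetric binning about 0 (lateral) or from 0 upward (radial)
.bin_counts <- function(x, bin_width, radial = FALSE) {
  if (length(x) == 0L) {
    return(data.frame(bin_center = numeric(0), count = integer(0)))
  }
  if (radial) {
    edges <- seq(0, max(x) + bin_width, by = bin_width)
  } else {
    m <- max(abs(x)) + bin_width
    k <- ceiling(m / bin_width)
    edges <- seq(-k * bin_width, k * bin_width, by = bin_width)
  }
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_center = (edges[-length(edges)] + edges[-1L]) / 2,
             count = counts)
}

#' @export
print.transport_summary <- function(x, ...) {
  cat(sprintf("<transport_summary> %g electrons at %.3g kV (seed %d)\n",
              x$n_electrons, x$voltage, x$seed))
  f <- x$fractions * 100
  cat(sprintf("  transmitted   %8d  (%5.2f%%)\n", x$n_transmitted,
              f[["transmitted"]]))
  cat(sprintf("  backscattered %8d  (%5.2f%%)\n", x$n_backscattered,
              f[["backscattered"]]))
  cat(sprintf("  absorbed      %8d  (%5.2f%%)\n", x$n_absorbed,
              f[["absorbed"]]))
  if (x$n_transmitted > 0) {
    w <- tryCatch(half_intensity_width(x$exit_lateral_profile),
                  error = function(e) NA_real_)
    cat(sprintf("  lateral exit FWHM: %.3g nm\n", w))
  }
  invisible(x)
}

#' Full width at half maximum of a binned profile
#'
#' Finds the peak bin and the half-maximum crossings on both flanks by
#' linear interpolation between bin centres.
#'
#' @param profile either a data frame with columns `bin_center` and `count`
#'   (as in a `transport_summary`), or a plain numeric vector of counts.
#' @param bin_width bin width in nm; required when `profile` is a bare
#'   vector, ignored otherwise.
#' @return width in nm.
#' @export
half_intensity_width <- function(profile, bin_width = NULL) {
  if (is.data.frame(profile)) {
    pos <- profile$bin_center
    cts <- profile$count
  } else {
    if (is.null(bin_width)) {
      stop("bin_width is required for a bare count vector", call. = FALSE)
    }
    cts <- as.numeric(profile)
    pos <- (seq_along(cts) - 1) * bin_width
  }
  if (length(cts) == 0L || all(cts <= 0)) {
    stop("profile has no positive mass", call. = FALSE)
  }
  bw <- if (length(pos) > 1L) pos[2L] - pos[1L] else
    if (!is.null(bin_width)) bin_width else 1
  ip <- which.max(cts)
  half <- cts[ip] / 2

  cross <- function(idx_seq, fallback) {
    prev <- ip
    for (i in idx_seq) {
      if (cts[i] < half) {
        # linear interpolation between bin centres i and prev
        frac <- (cts[prev] - half) / (cts[prev] - cts[i])
        return(pos[prev] + frac * (pos[i] - pos[prev]))
      }
      prev <- i
    }
    fallback  # flank never drops below half: outer bin edge
  }
  left <- if (ip > 1L) cross(seq(ip - 1L, 1L), pos[1L] - bw / 2) else
    pos[1L] - bw / 2
  right <- if (ip < length(cts)) {
    cross(seq(ip + 1L, length(cts)), pos[length(cts)] + bw / 2)
  } else {
    pos[length(cts)] + bw / 2
  }
  right - left
}

#' Transmission fraction versus accelerating voltage
#'
#' Runs one transport simulation per voltage with seeds `rng_seed + index - 1`.
#'
#' @param stack a [film_stack()].
#' @param voltages accelerating voltages, kV.
#' @param beam a [beam_spec()] supplying the non-voltage beam parameters.
#' @param config a [transport_config()].
#' @return data frame with one row per voltage: `voltage_kV` and the three
#'   fate fractions.
#' @export
transmission_curve <- function(stack, voltages,
                               beam = beam_spec(voltage = voltages[1L]),
                               config = transport_config(10000L)) {
  rows <- lapply(seq_along(voltages), function(i) {
    b <- beam
    b$voltage <- voltages[i]
    cfg <- config
    cfg$rng_seed <- config$rng_seed + i - 1L
    s <- run_transport(stack, b, cfg)
    data.frame(voltage_kV = voltages[i],
               transmitted = s$fractions[["transmitted"]],
               backscattered = s$fractions[["backscattered"]],
               absorbed = s$fractions[["absorbed"]])
  })
  do.call(rbind, rows)
}
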