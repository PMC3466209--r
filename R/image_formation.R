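# Forward micrograph simulation: beam-spread PSF from the transport run,
# attenuation contrast, Poisson shot noise.

#' Normalized 2D point-spread-function kernel
#'
#' @param values non-negative matrix with odd dimensions; normalized to sum
#'   to 1 on construction.
#' @param pixel_size nm/px.
#' @export
psf_kernel <- function(values, pixel_size) {
  if (!is.matrix(values) || any(values < 0) || any(!is.finite(values))) {
    stop("PSF values must be a finite non-negative matrix", call. = FALSE)
  }
  if (nrow(values) %% 2 == 0 || ncol(values) %% 2 == 0) {
    stop("PSF dimensions must be odd (centred kernel)", call. = FALSE)
  }
  s <- sum(values)
  if (s <= 0) stop("PSF must have positive mass", call. = FALSE)
  structure(list(values = values / s, pixel_size = pixel_size),
            class = "psf_kernel")
}

#' @export
print.psf_kernel <- function(x, ...) {
  cat(sprintf("<psf_kernel> %d x %d px at %.3g nm/px\n",
              nrow(x$values), ncol(x$values), x$pixel_size))
  invisible(x)
}

#' Beam-spread PSF from a transport run
#'
#' Converts the radial histogram of bottom-exit positions into a radially
#' symmetric 2D kernel: annulus counts become an areal density (counts per
#' nm^2), which is linearly interpolated at each pixel's radius and
#' normalized.
#'
#' @param summary a `transport_summary` with transmitted electrons.
#' @param pixel_size kernel pixel size, nm/px.
#' @param max_radius kernel half-extent in nm; defaults to the largest
#'   populated radial bin.
#' @return a [psf_kernel()].
#' @export
psf_from_exit_distribution <- function(summary, pixel_size,
                                       max_radius = NULL) {
  stopifnot(inherits(summary, "transport_summary"))
  rad <- summary$exit_radial_histogram
  if (summary$n_transmitted == 0L || nrow(rad) == 0L) {
    stop("no transmitted electrons to build a PSF from", call. = FALSE)
  }
  bw <- summary$bin_width
  r_lo <- rad$bin_center - bw / 2
  r_hi <- rad$bin_center + bw / 2
  dens <- rad$count / (pi * (r_hi^2 - r_lo^2))
  if (is.null(max_radius)) max_radius <- max(r_hi[rad$count > 0])
  half <- ceiling(max_radius / pixel_size)
  idx <- (-half):half
  coords <- idx * pixel_size
  r_pix <- sqrt(outer(coords^2, coords^2, `+`))
  # density at r = 0 extrapolated flat from the first bin centre
  vals <- approx(x = c(0, rad$bin_center), y = c(dens[1L], dens),
                 xout = pmin(r_pix, max(rad$bin_center)),
                 rule = 2)$y
  vals[r_pix > max_radius] <- 0
  psf_kernel(matrix(vals, nrow = length(idx)), pixel_size)
}

#' Isotropic Gaussian PSF
#'
#' @param sigma standard deviation in px.
#' @param size odd kernel side length in px; defaults to an extent of about
#'   6 sigma.
#' @param pixel_size nm/px.
#' @export
gaussian_psf <- function(sigma, size = NULL, pixel_size = 1) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  if (size %% 2 == 0) stop("size must be odd", call. = FALSE)
  half <- (size - 1) / 2
  g <- dnorm((-half):half, sd = sigma)
  psf_kernel(outer(g, g), pixel_size)
}

#' Expected (noise-free) micrograph signal
#'
#' N(x, y) = dose * (psf conv exp(-mu t(x, y))): the specimen attenuates the
#' locally injected signal, then the beam-spread kernel blurs it.
#' Attenuate-first/blur-second ordering is part of the model contract.
#'
#' @param phantom mass-thickness [image_grid()] (nm).
#' @param psf a [psf_kernel()] on the same pixel size.
#' @param dose_per_pixel mean electrons per pixel.
#' @param mu attenuation per nm of specimen thickness.
#' @return matrix of expected counts.
#' @export
micrograph_expectation <- function(phantom, psf, dose_per_pixel = 5963,
                                   mu = 0.02) {
  stopifnot(inherits(phantom, "image_grid"), inherits(psf, "psf_kernel"))
  if (abs(phantom$pixel_size - psf$pixel_size) >
      1e-6 * phantom$pixel_size) {
    stop("phantom and PSF pixel sizes differ", call. = FALSE)
  }
  if (dose_per_pixel <= 0) stop("dose must be > 0", call. = FALSE)
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  dose_per_pixel * conv2_reflect(exp(-mu * phantom$values), psf$values)
}

#' Simulate a detected micrograph
#'
#' Draws each pixel from a Poisson law with the mean of
#' [micrograph_expectation()]: thicker specimen regions transmit less
#' signal, giving the characteristic dark ("black contrast") particle
#' against a bright background. Deterministic given `rng_seed`.
#'
#' @inheritParams micrograph_expectation
#' @param rng_seed integer seed for the shot noise.
#' @return an [image_grid()] of Poisson counts.
#' @export
simulate_micrograph <- function(phantom, psf, dose_per_pixel = 5963,
                                mu = 0.02, rng_seed = 1L) {
  lambda <- micrograph_expectation(phantom, psf, dose_per_pixel, mu)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(rng_seed)
  counts <- matrix(rpois(length(lambda), lambda), nrow = nrow(lambda))
  image_grid(counts + 0.0, phantom$pixel_size)
}
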