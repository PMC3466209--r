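# Monte Carlo transport: elementary sampling operations, the stepping
# mechanics, and whole-run invariants.

test_that("free-path sampling inverts the exponential law", {
  expect_equal(sample_free_path(5, 1), 0)
  expect_equal(sample_free_path(5, exp(-1)), 5)
  expect_error(sample_free_path(5, 0), "0, 1")
  expect_error(sample_free_path(5, 1.5), "0, 1")
  expect_error(sample_free_path(-1, 0.5), "mfp")
  # law of large numbers: sample mean -> mfp
  set.seed(11)
  s <- sample_free_path(7, runif(1e6))
  expect_equal(mean(s), 7, tolerance = 0.005)
})

test_that("polar-angle sampling matches the screened-Rutherford density", {
  expect_equal(sample_polar_angle(0.01, 0), 1)
  expect_equal(sample_polar_angle(0.01, 1), -1)
  expect_error(sample_polar_angle(0, 0.5), "alpha")
  expect_error(sample_polar_angle(0.01, -0.1), "0, 1")
  # empirical mean of cos(theta) against quadrature of the angular density
  for (a in c(0.005, 0.016, 0.1)) {
    num <- integrate(function(mu) mu * sr_angular_density(mu, a), -1, 1,
                     rel.tol = 1e-10)$value
    den <- integrate(function(mu) sr_angular_density(mu, a), -1, 1,
                     rel.tol = 1e-10)$value
    set.seed(101)
    ct <- sample_polar_angle(a, runif(1e6))
    expect_equal(mean(ct), num / den, tolerance = 0.005)
  }
})

test_that("direction rotation preserves norm and matches a rotation-matrix oracle", {
  d <- c(0, 0, 1)
  expect_equal(rotate_direction(d, 0, 1.3), d, tolerance = 1e-12)
  expect_error(rotate_direction(c(0, 0, 0), 1, 1), "norm")
  expect_error(rotate_direction(c(0, 0, 2), 1, 1), "unit")

  # oracle: build the orthonormal frame of the documented azimuth
  # convention explicitly (Gram-Schmidt of -ez against u, cross product for
  # the second axis) and assemble the rotated vector as a matrix product
  set.seed(21)
  worst <- 0
  for (i in 1:100) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    th <- runif(1, 0, pi); ph <- runif(1, 0, 2 * pi)
    got <- rotate_direction(u, th, ph)
    expect_equal(sum(got^2), 1, tolerance = 1e-12)
    expect_equal(sum(got * u), cos(th), tolerance = 1e-9)
    if (abs(u[3]) < 0.999) {
      ez <- c(0, 0, 1)
      e1 <- -(ez - u[3] * u)
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2],
              u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      R <- cbind(e1, e2, u)
      ref <- as.numeric(R %*% c(sin(th) * cos(ph), sin(th) * sin(ph),
                                cos(th)))
      worst <- max(worst, max(abs(got - ref)))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("stepping dissipates energy and books it exactly", {
  stack <- methods_stack()
  set.seed(5)
  st <- electron_state(energy = 4)
  for (i in 1:50) {
    e_before <- st$energy
    st <- step_electron(st, stack)
    expect_lte(st$energy, e_before)
    if (st$status != "in-flight") break
  }
  # bookkeeping closes: initial = deposited + exit kinetic energy
  set.seed(42)
  for (rep in 1:5) {
    st <- electron_state(energy = 3.6)
    while (st$status == "in-flight") st <- step_electron(st, stack)
    expect_equal(st$deposited + st$energy, 3.6, tolerance = 1e-9)
  }
})

test_that("with scattering and stopping switched off the electron flies straight", {
  stack <- thin_stack(500)
  set.seed(1)
  st <- electron_state(direction = c(0.6, 0, 0.8), energy = 4)
  no_loss <- function(material, E) 0
  huge_mfp <- function(material, E) 1e12
  st2 <- step_electron(st, stack, mfp_fn = huge_mfp, stopping_fn = no_loss)
  # one step reaches the bottom boundary along the initial direction
  expect_equal(st2$status, "transmitted")
  expect_equal(st2$energy, 4)
  expect_equal(st2$position[1] / st2$position[3], 0.6 / 0.8,
               tolerance = 1e-9)
})

test_that("compiled engine closes the per-trajectory energy budget", {
  s <- run_transport(methods_stack(), beam_spec(4),
                     transport_config(5000, rng_seed = 9))
  residual <- abs(4 - (s$deposited + s$exit_energy))
  expect_lt(max(residual), 1e-9)
  # absorbed electrons carry no kinetic energy out
  expect_true(all(s$exit_energy[s$fate == 2L] == 0))
  # exiting electrons keep positive energy
  expect_true(all(s$exit_energy[s$fate != 2L] > 0))
})

test_that("electron fates partition every run", {
  for (v in c(3, 4.6)) {
    s <- run_transport(methods_stack(), beam_spec(v),
                       transport_config(3000, rng_seed = 2))
    expect_identical(s$n_transmitted + s$n_backscattered + s$n_absorbed,
                     s$n_electrons)
    expect_equal(sum(s$fractions), 1, tolerance = 1e-12)
    expect_identical(length(s$exit_x), s$n_transmitted)
    expect_identical(sum(s$exit_lateral_profile$count), s$n_transmitted)
    expect_identical(sum(s$exit_radial_histogram$count), s$n_transmitted)
  }
})

test_that("degenerate stacks transmit everything or nothing", {
  s <- run_transport(thin_stack(1e-3), beam_spec(4),
                     transport_config(2000, rng_seed = 1))
  expect_gt(s$fractions[["transmitted"]], 0.99)
  blocker <- film_stack(layer(material_library()$Au, 1000))
  s2 <- run_transport(blocker, beam_spec(4),
                      transport_config(2000, rng_seed = 1))
  expect_identical(s2$n_transmitted, 0L)
})

test_that("identical seeds give bit-identical summaries, different seeds agree statistically", {
  cfg <- transport_config(20000, rng_seed = 33)
  a <- run_transport(methods_stack(), beam_spec(4.6), cfg)
  b <- run_transport(methods_stack(), beam_spec(4.6), cfg)
  expect_identical(a$fractions, b$fractions)
  expect_identical(a$exit_x, b$exit_x)
  expect_identical(a$deposited, b$deposited)

  # repeated runs with fresh seeds: transmitted fractions within 4 sigma
  fr <- vapply(1:3, function(k) {
    run_transport(methods_stack(), beam_spec(4.6),
                  transport_config(20000, rng_seed = 100 + k)
    )$fractions[["transmitted"]]
  }, numeric(1))
  p <- mean(fr)
  se <- sqrt(p * (1 - p) / 20000)
  expect_lt(max(abs(fr - p)), 4 * se + 1e-12)
})

test_that("transmission drops as the stack thickens", {
  cfg <- transport_config(20000, rng_seed = 8)
  fr <- vapply(c(40, 60, 80), function(t_sin) {
    run_transport(metal_coated_sin_stack(t_sin), beam_spec(4.6),
                  cfg)$fractions[["transmitted"]]
  }, numeric(1))
  se <- sqrt(max(fr) * (1 - max(fr)) / 20000)
  expect_lt(fr[2], fr[1] + 3 * se)
  expect_lt(fr[3], fr[2] + 3 * se)
})

test_that("half-intensity width interpolates the half-maximum crossings", {
  # single-bin spike
  expect_lte(half_intensity_width(c(0, 0, 9, 0, 0), bin_width = 2), 2)
  # discretized Gaussian: FWHM = 2.3548 sigma
  centers <- seq(-60, 60, by = 2)
  prof <- data.frame(bin_center = centers,
                     count = dnorm(centers, sd = 10))
  expect_equal(half_intensity_width(prof), 2 * sqrt(2 * log(2)) * 10,
               tolerance = 0.02)
  expect_error(half_intensity_width(c(0, 0, 0), bin_width = 1),
               "positive mass")
})

test_that("transmission curve is deterministic and rises with voltage", {
  stack <- methods_stack()
  cfg <- transport_config(10000, rng_seed = 55)
  tab <- transmission_curve(stack, c(3.8, 4.4, 5.0), beam_spec(4), cfg)
  tab2 <- transmission_curve(stack, c(3.8, 4.4, 5.0), beam_spec(4), cfg)
  expect_identical(tab, tab2)
  expect_true(all(tab$transmitted >= 0 & tab$transmitted <= 1))
  expect_true(all(diff(tab$transmitted) >= 0))
  # near-empty film transmits everything at every voltage
  empty <- transmission_curve(thin_stack(1e-3), c(3, 4, 5), beam_spec(4),
                              transport_config(1000, rng_seed = 3))
  expect_true(all(empty$transmitted > 0.99))
})
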