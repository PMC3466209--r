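# Material data model and per-material electron physics.

test_that("element and material constructors validate their invariants", {
  au <- element("Au")
  expect_equal(au$Z, 79L)
  expect_gt(au$atomic_mass, 79 * 0.9)
  expect_error(element("Zz"), "unknown element")
  expect_error(element("X", Z = 0, atomic_mass = 1), "positive integer")
  expect_error(element("X", Z = 10, atomic_mass = 5), "atomic_mass")

  expect_error(material("m", -1, c(Au = 1)), "density")
  expect_error(material("m", 1, c(Au = 0.5, Ni = 0.6)), "sum to 1")
  expect_error(material("m", 1, c(Au = 1.2, Ni = -0.2)), "0, 1")
  m <- material("m", 2, c(Si = 0.6006, N = 0.3994))
  expect_equal(sum(m$fractions), 1, tolerance = 1e-12)

  expect_error(layer(m, 0), "thickness")
  st <- film_stack(layer(m, 10), layer(m, 5))
  expect_equal(st$total_thickness, 15)
  expect_error(film_stack(), ">= 1 layer")
})

test_that("built-in library carries the coated-membrane materials", {
  lib <- material_library()
  expect_equal(lib$SiN$density, 3.12)
  expect_equal(lib$Ni$density, 8.9)
  expect_equal(lib$Au$density, 19.3)
  st <- metal_coated_sin_stack()
  expect_equal(st$total_thickness, 85)
  expect_equal(metal_coated_sin_stack(50)$total_thickness, 75)
})

test_that("mean ionization potential follows both branches and is monotone", {
  # low-Z branch, exact
  expect_equal(mean_ionization_potential(7), 11.5 * 7 * 1e-3)
  # high-Z branch against independent inline arithmetic
  expect_equal(mean_ionization_potential(79),
               (9.76 * 79 + 58.5 * 79^(-0.19)) * 1e-3,
               tolerance = 1e-12)
  J <- mean_ionization_potential(1:92)
  expect_true(all(diff(J) > 0))
  expect_true(all(J > 0))
  expect_error(mean_ionization_potential(0), "positive integer")
  expect_error(mean_ionization_potential(2.5), "positive integer")
})

test_that("elastic cross-section matches quadrature of its differential form", {
  # oracle: integrate the screened-Rutherford differential cross-section
  # d(sigma)/d(Omega) = 5.21e-21 (Z^2/E^2) rel^2 * 4 / (1 - mu + 2 alpha)^2
  # over the full solid angle (2 pi d(mu))
  for (Z in c(7, 14, 28, 79)) {
    for (E in c(0.5, 4, 20)) {
      a <- screening_parameter(Z, E)
      rel <- (E + 511) / (E + 1024)
      pref <- 5.21e-21 * Z^2 / E^2 * rel^2 * 4
      quad <- integrate(function(mu) 2 * pi * pref / (1 - mu + 2 * a)^2,
                        -1, 1, rel.tol = 1e-10)$value
      expect_equal(elastic_cross_section(Z, E), quad, tolerance = 1e-6)
    }
  }
})

test_that("cross-section decreases with energy and vanishes at strong screening", {
  E <- seq(1, 10, by = 0.5)
  s <- elastic_cross_section(79, E)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0))
  # the angular factor 4 pi / (alpha (1 + alpha)) kills sigma as alpha grows
  f <- function(a) 4 * pi / (a * (1 + a))
  expect_true(f(1e3) < f(1) && f(1e6) < f(1e3))
  expect_lt(f(1e8), 1e-14)
  expect_error(elastic_cross_section(79, 0.04), "0.05")
})

test_that("elastic mean free path follows the mixture rule", {
  au1 <- material("Au", 19.3, c(Au = 1))
  au2 <- material("Au2", 38.6, c(Au = 1))
  expect_equal(elastic_mfp(au1, 4) / elastic_mfp(au2, 4), 2,
               tolerance = 1e-12)
  # single element: closed form A / (N_A rho sigma), in nm
  sig <- elastic_cross_section(79, 4)
  closed <- 196.97 / (6.02214076e23 * 19.3 * sig) * 1e7
  expect_equal(elastic_mfp(au1, 4), closed, tolerance = 1e-12)
  # Si3N4 additivity against a brute-force two-term sum
  sin_ <- material_library()$SiN
  inv <- 6.02214076e23 * 3.12 * 0.6006 / 28.085 *
    elastic_cross_section(14, 4) +
    6.02214076e23 * 3.12 * 0.3994 / 14.007 * elastic_cross_section(7, 4)
  expect_equal(elastic_mfp(sin_, 4), 1e7 / inv, tolerance = 1e-12)
})

test_that("Joy-Luo stopping power is positive and matches hand arithmetic", {
  lib <- material_library()
  for (m in lib) {
    for (E in c(0.1, 0.5, 1, 4, 10)) {
      expect_gt(stopping_power(m, E), 0)
    }
  }
  # Au at 4 keV, written out term by term
  J <- (9.76 * 79 + 58.5 * 79^(-0.19)) * 1e-3
  k <- 0.731 + 0.0688 * log10(79)
  hand <- 7.85e4 * (19.3 / 4) * (79 / 196.97) *
    log(1.166 * (4 + k * J) / J) * 1e-7
  expect_equal(stopping_power(lib$Au, 4), hand, tolerance = 1e-12)
  # E * dE/ds varies only logarithmically with E
  r <- (8 * stopping_power(lib$Au, 8)) / (4 * stopping_power(lib$Au, 4))
  expect_gt(r, 1)
  expect_lt(r, 1.5)
  expect_error(stopping_power(lib$Au, 0.04), "keV")
  expect_error(stopping_power(lib$Au, 31), "keV")
})

test_that("R-level physics and the compiled engine agree exactly", {
  lib <- material_library()
  for (E in c(0.2, 1, 4, 12)) {
    expect_equal(elastic_cross_section(79, E),
                 semfilm:::.cpp_sigma_elastic(79L, E), tolerance = 1e-12)
    expect_equal(stopping_power(lib$SiN, E),
                 semfilm:::.cpp_stopping_power(3.12, c(14L, 7L),
                                               c(28.085, 14.007),
                                               c(0.6006, 0.3994), E),
                 tolerance = 1e-12)
    expect_equal(elastic_mfp(lib$SiN, E),
                 semfilm:::.cpp_elastic_mfp(3.12, c(14L, 7L),
                                            c(28.085, 14.007),
                                            c(0.6006, 0.3994), E),
                 tolerance = 1e-12)
  }
  expect_equal(mean_ionization_potential(79),
               semfilm:::.cpp_ionization_J(79L), tolerance = 1e-12)
  expect_equal(mean_ionization_potential(7),
               semfilm:::.cpp_ionization_J(7L), tolerance = 1e-12)
})
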