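# Synthetic specimen phantoms: geometry, symmetry, determinism.

test_that("rod virion phantom has the requested footprint and internal disks", {
  ph <- rod_virus_phantom(length = 250, diameter = 80, n_disks = 6,
                          pixel_size = 2)
  V <- ph$values
  support <- V > 0
  cols <- range(which(colSums(support) > 0))
  rows <- range(which(rowSums(support) > 0))
  expect_equal((cols[2] - cols[1] + 1) * ph$pixel_size, 250,
               tolerance = 2 * ph$pixel_size)
  expect_equal((rows[2] - rows[1] + 1) * ph$pixel_size, 80,
               tolerance = 2 * ph$pixel_size)
  # six disjoint top-tier disks along the axis
  disk_tier <- V > (55 + 80) / 2  # above the core level, into disk level
  expect_identical(count_components(disk_tier), 6L)
  # deterministic
  expect_identical(ph$values,
                   rod_virus_phantom(length = 250, diameter = 80,
                                     n_disks = 6, pixel_size = 2)$values)
})

test_that("rod phantom validates its geometry", {
  expect_error(rod_virus_phantom(length = 150), "200-350")
  expect_silent(rod_virus_phantom(length = 150, n_disks = 2,
                                  check_range = FALSE))
  # 8 disks of 30 nm cannot sit disjointly on a 250-nm rod core
  expect_error(rod_virus_phantom(n_disks = 8), "do not fit")
  expect_error(rod_virus_phantom(disk_diameter = 90), "radially")
})

test_that("star pentamer has five-fold symmetry and the stated footprint", {
  ph <- star_pentamer_phantom(pixel_size = 0.5)
  V <- ph$values
  # raster rotation by 72 degrees: interpolation smears the sharp tier
  # edges, so compare in the mean, not pointwise
  rot <- rotate_bilinear(V, 2 * pi / 5)
  ok <- !is.na(rot)
  expect_lt(mean(abs(rot[ok] - V[ok])), 0.02 * max(V))
  # the rendered field itself is invariant under a 72-degree phase shift
  ph2 <- star_pentamer_phantom(pixel_size = 0.5, phase = pi / 2 + 2 * pi / 5)
  expect_equal(ph2$values, V, tolerance = 1e-9)
  # support radius = outer_diameter / 2 within a pixel
  idx <- which(V > 0, arr.ind = TRUE)
  cy <- (nrow(V) + 1) / 2; cx <- (ncol(V) + 1) / 2
  rmax <- max(sqrt((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2)) * ph$pixel_size
  expect_equal(rmax, 22.5, tolerance = 1)
  # dense 20-nm centre sits above the arm tier
  expect_gt(V[round(cy), round(cx)], max(V) * 0.9)
  expect_error(star_pentamer_phantom(centre_diameter = 50), "smaller")
})

test_that("a one-armed star degenerates gracefully", {
  ph <- star_pentamer_phantom(n_arms = 1, pixel_size = 1)
  expect_gt(sum(ph$values > 0), 0)
})

test_that("dumbbell phantom is mirror-symmetric with caps flanking the core", {
  ph <- dumbbell_phantom(total_length = 52, pixel_size = 0.5)
  V <- ph$values
  # axial extent 52 nm within a pixel
  cols <- range(which(colSums(V) > 0))
  expect_equal((cols[2] - cols[1] + 1) * ph$pixel_size, 52,
               tolerance = 2 * ph$pixel_size)
  # exact mirror symmetry about the transverse midline (analytic rendering)
  expect_lt(max(abs(V - V[, rev(seq_len(ncol(V)))])), 1e-9)
  # axial profile: two cap maxima flanking a lower core plateau
  prof <- V[round((nrow(V) + 1) / 2), ]
  mid <- prof[round((length(prof) + 1) / 2)]
  expect_equal(max(prof), 24)
  expect_equal(mid, 14, tolerance = 1e-9)
  expect_error(dumbbell_phantom(cap_diameter = 10, core_diameter = 12),
               "exceed")
})

test_that("edge phantom is an exact binary step", {
  ph <- edge_phantom(edge_position = 40, thickness = 50,
                     canvas = c(128, 64))
  V <- ph$values
  expect_true(all(V[, 1:39] == 0))
  expect_true(all(V[, 40:128] == 50))
  expect_identical(min(which(colSums(V) > 0)), 40L)
  expect_true(all(edge_phantom(10, thickness = 0)$values == 0))
  expect_error(edge_phantom(200, canvas = c(128, 64)), "inside")
})

test_that("physical support area is invariant under pixel-size changes", {
  a1 <- sum(dumbbell_phantom(pixel_size = 1)$values > 0) * 1^2
  a2 <- sum(dumbbell_phantom(pixel_size = 0.5)$values > 0) * 0.5^2
  expect_equal(a1, a2, tolerance = 0.06 * a1)
})
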