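r0_65 <- tube_dimensions(nanotube_spec(6, 5))$radius

test_that("parametric renders obey the geometric envelope", {
  hp <- helix_param(tube_radius = r0_65, backbone_radius = r0_65 + 0.33,
                    pitch = 3.3, n_coils = 3, strand_radius = 0.25)
  topo <- render_surface(hp, size = c(14, 8), pixel = 0.05)
  expect_true(all(is.finite(topo$height)))
  expect_true(isTRUE(topo$meta$synthetic))
  expect_equal(topo$meta$true_pitch, 3.3)
  # substrate is the zero level
  expect_equal(min(topo$height), 0)
  # maximum height: strand top at r0 + backbone_radius + strand_radius
  expect_close(max(topo$height), r0_65 + (r0_65 + 0.33) + 0.25, 0.01,
               "strand crest height")
  # ridge modulation depth between DNA crossings and bare-tube points
  # matches the analytic envelope: (R_bb + r_strand) - R_tube
  mid_row <- round(4 / topo$pixel)
  ridge <- topo$height[mid_row, ]
  crossings <- max(ridge)
  bare <- min(ridge[ridge > 2 * r0_65 - 0.02])
  expect_close(crossings - bare, (r0_65 + 0.33) + 0.25 - r0_65, 0.02,
               "modulation depth")
})

test_that("a bare tube renders to its diameter and pitch misfits error", {
  tube <- build_nanotube(nanotube_spec(6, 5, n_units = 2))
  topo <- render_surface(tube, size = c(10, 8), pixel = 0.05)
  # apparent crest: tube diameter plus two carbon van der Waals radii
  expect_close(max(topo$height), 2 * r0_65 + 2 * 0.17, 0.02, "atomistic crest")
  hp_bad <- helix_param(tube_radius = r0_65, backbone_radius = 1.05,
                        pitch = 5, n_coils = 3)
  expect_error(render_surface(hp_bad, size = c(10, 10)), "coils")
  expect_error(helix_param(r0_65, pitch = -2), "positive")
  expect_warning(render_surface(helix_param(r0_65, pitch = 3.3, n_coils = 2),
                                size = c(10, 10), pixel = 0.2), "coarse")
})

test_that("tip dilation is extensive, monotone and translation-equivariant", {
  tip <- tip_model("cone", 2, 30)
  set.seed(11)
  h1 <- matrix(0, 60, 60)
  h1[20:30, 15:40] <- matrix(runif(11 * 26, 0, 0.5), 11)
  t1 <- topography(h1, 0.1)
  d1 <- tip_dilate(t1, tip)
  expect_true(all(d1$height >= h1 - 1e-12))          # extensive
  h2 <- h1; h2[25, 25] <- h2[25, 25] + 0.4           # pointwise larger input
  d2 <- tip_dilate(topography(h2, 0.1), tip)
  expect_true(all(d2$height >= d1$height - 1e-12))   # monotone
  # translation equivariance (integer pixel shift, away from borders)
  h3 <- matrix(0, 60, 60); h3[28:32, 28:32] <- 0.6
  h4 <- matrix(0, 60, 60); h4[33:37, 30:34] <- 0.6
  d3 <- tip_dilate(topography(h3, 0.1), tip)$height
  d4 <- tip_dilate(topography(h4, 0.1), tip)$height
  expect_lt(max(abs(d3[10:45, 10:45] - d4[15:50, 12:47])), 1e-12)
})

test_that("flat planes are fixed points and spikes imprint the tip apex", {
  tip <- tip_model("sphere", 1.5)
  flat <- topography(matrix(0.3, 40, 40), 0.05)
  expect_equal(tip_dilate(flat, tip)$height, flat$height)
  spike <- matrix(0, 81, 81); spike[41, 41] <- 1
  d <- tip_dilate(topography(spike, 0.05), tip)$height
  # imprint of the inverted spherical apex around the spike
  for (off in c(5, 10, 20)) {
    s <- off * 0.05
    expect_close(d[41, 41 + off], 1 - (1.5 - sqrt(1.5^2 - s^2)), 1e-6,
                 paste("apex imprint at offset", s))
  }
})

test_that("tip broadening reproduces the apparent-width relation", {
  tube <- build_nanotube(nanotube_spec(6, 5, n_units = 3))
  topo <- render_surface(tube, size = c(10, 8), pixel = 0.05)
  d <- tip_dilate(topo, tip_model("cone", 2, 30))
  mid <- d$height[, round(5 / d$pixel)]
  measured <- sum(mid > 1e-9) * d$pixel
  # circle-tangency oracle: a spherical apex of radius R_t touching both the
  # substrate and a resting cylinder of effective (vdW-padded) radius r_c
  # reaches lateral distance 2 sqrt(R_t r_c) from the axis
  r_c <- r0_65 + 0.17
  w_oracle <- 4 * sqrt(2 * r_c)
  expect_close(measured, w_oracle, 0.25, "tip-broadened width")
  expect_gt(measured, 4); expect_lt(measured, 7)
})

test_that("noise is seeded, has the requested amplitude, and rms 0 is identity", {
  topo <- topography(matrix(0.5, 256, 256), 0.05)
  n1 <- add_noise(topo, 0.02, seed = 9)
  n2 <- add_noise(topo, 0.02, seed = 9)
  n3 <- add_noise(topo, 0.02, seed = 10)
  expect_identical(n1$height, n2$height)
  expect_false(identical(n1$height, n3$height))
  expect_close(stats::sd(n1$height - topo$height), 0.02, 0.001, "empirical rms")
  expect_identical(add_noise(topo, 0, seed = 1)$height, topo$height)
})

test_that("tip deconvolution undoes blunting of coarse features", {
  tip <- tip_model("cone", 2, 30)
  hp <- helix_param(tube_radius = r0_65, backbone_radius = 1.05,
                    pitch = 3.3, n_coils = 3)
  pre <- render_surface(hp, size = c(16, 10), pixel = 0.05)
  dil <- tip_dilate(pre, tip)
  rec <- tip_deconvolve(dil, tip)
  # reconstruction is an opening: sandwiched between original and dilated,
  # and strictly closer to the original than the raw dilated image
  expect_true(all(rec$height >= pre$height - 1e-9))
  expect_true(all(rec$height <= dil$height + 1e-9))
  expect_lt(mean(rec$height - pre$height), mean(dil$height - pre$height))
})

test_that("topography round trips through text and TIFF", {
  hp <- helix_param(tube_radius = r0_65, backbone_radius = 1.05, pitch = 3.3,
                    n_coils = 2)
  topo <- render_surface(hp, size = c(8, 6), pixel = 0.1)
  tf <- tempfile(fileext = ".txt")
  write_topography(topo, tf, "text")
  back <- read_topography(tf, "text")
  expect_lt(max(abs(back$height - topo$height)), 1e-8)
  expect_equal(back$pixel, topo$pixel)
  expect_equal(back$meta$true_pitch, topo$meta$true_pitch)
  tfi <- tempfile(fileext = ".tif")
  write_topography(topo, tfi, "tiff")
  back2 <- read_topography(tfi, "tiff")
  expect_lt(max(abs(back2$height - topo$height)), 1e-5)
  expect_equal(back2$pixel, topo$pixel)
})
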