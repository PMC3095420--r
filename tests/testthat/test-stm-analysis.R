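r0_65 <- tube_dimensions(nanotube_spec(6, 5))$radius

make_sine_profile <- function(lambda = 3.3, n_periods = 3, n = 300,
                              offset = 0, amp = 1) {
  span <- lambda * n_periods
  dx <- span / (n - 1)
  list(heights = offset + amp * sin(2 * pi * seq(0, n_periods, length.out = n)),
       spacing = dx)
}

test_that("profiles are extracted by bilinear interpolation", {
  h <- outer(seq_len(40), seq_len(50), function(i, j) 0.01 * j)
  topo <- topography(h, 0.1)
  # a 0-degree section along a pixel-centre row reproduces the row values
  prof <- extract_profile(topo, anchor = c(0.05, 1.05), orientation = 0,
                          length = 3.9)
  at_centres <- prof$heights[seq(1, prof$n, by = 2)]
  expect_lt(max(abs(at_centres - h[11, 1:length(at_centres)])), 1e-12)
  # flat region gives a constant profile
  flat <- topography(matrix(0.7, 30, 30), 0.1)
  p2 <- extract_profile(flat, c(0.3, 0.3), 33, 2)
  expect_lt(diff(range(p2$heights)), 1e-12)
  # leaving the image truncates with a warning
  expect_warning(extract_profile(topo, c(3, 2), 0, 10), "truncated")
})

test_that("a longitudinal section of a three-coil hybrid shows three peaks", {
  # underside start phase: the three coils cross the visible crest three
  # times inside the imaged window
  hp <- helix_param(tube_radius = r0_65, backbone_radius = 1.05, pitch = 3.3,
                    n_coils = 3, phase = pi)
  topo <- render_surface(hp, size = c(14, 8), pixel = 0.05)
  prof <- ridge_profile(topo)
  h <- prof$heights
  peaks <- which(diff(sign(diff(h))) == -2) + 1
  tall <- peaks[h[peaks] > min(h) + 0.5 * (max(h) - min(h))]
  # merge plateau duplicates closer than half a pitch
  tall <- tall[c(TRUE, diff(tall) * prof$spacing > 1.6)]
  expect_equal(length(tall), 3L)
})

test_that("the dominant period inverts the spectral peak frequency", {
  p <- dominant_period(make_sine_profile())
  expect_false(p$no_periodicity)
  # the printed-value period lies inside the 90%-of-peak band
  expect_gte(3.3, p$band90[1]); expect_lte(3.3, p$band90[2])
  expect_close(p$period, 3.3, 0.06, "period of a 3-cycle sine")
  # invariance to offset and uniform scaling
  p_off <- dominant_period(make_sine_profile(offset = 5, amp = 4))
  expect_equal(p$period, p_off$period)
  # no periodicity on constant input
  flat <- list(heights = rep(1, 64), spacing = 0.1)
  expect_true(dominant_period(flat)$no_periodicity)
})

test_that("spectral widths scale as the sine-window relations predict", {
  p3 <- dominant_period(make_sine_profile(n_periods = 3))
  # zero-level (null-to-null) width ~ 2 lambda / N
  expect_lt(abs(p3$zero_width - 2 * p3$period / p3$n_periods),
            0.25 * 2 * p3$period / p3$n_periods)
  # 90%-band spread is of order 0.12 lambda (within a factor of two)
  expect_gt(p3$band90_spread, 0.12 * p3$period / 2)
  expect_lt(p3$band90_spread, 0.12 * p3$period * 2)
  # longer windows shrink the uncertainty
  p6 <- dominant_period(make_sine_profile(n_periods = 6, n = 600))
  expect_lt(p6$band90_spread, p3$band90_spread)
  expect_lt(p6$zero_width, p3$zero_width)
})

test_that("period histograms count, add and locate the mode", {
  one <- dominant_period(make_sine_profile())
  h1 <- period_histogram(list(one))
  expect_equal(sum(h1$counts), 1L)
  h2 <- period_histogram(list(one, one))
  expect_equal(sum(h2$counts), 2L)
  expect_equal(h2$counts[h2$counts > 0], 2L)
  flat <- dominant_period(list(heights = rep(1, 64), spacing = 0.1))
  expect_warning(h0 <- period_histogram(list(flat)), "no spectra")
  expect_true(is.na(h0$modal_period))
})

test_that("an ensemble of noisy synthetic hybrids has modal period 3.3 nm", {
  hp <- helix_param(tube_radius = r0_65, backbone_radius = 1.05,
                    pitch = 3.3, n_coils = 3)
  pre <- render_surface(hp, size = c(16, 9), pixel = 0.07)
  tip <- tip_model("cone", 2, 30)
  dil <- tip_dilate(pre, tip)
  spectra <- lapply(1:20, function(s) {
    dominant_period(ridge_profile(add_noise(dil, 0.02, seed = s)))
  })
  hist <- period_histogram(spectra, bin_width = 0.3)
  expect_close(hist$modal_period, 3.3, 0.151, "modal period bin")
})

test_that("strand orientation is recovered on exact renders", {
  hp <- helix_param(tube_radius = r0_65, backbone_radius = 1.05,
                    angle_from_axis = 63.0, n_coils = 3)
  pre <- render_surface(hp, size = c(21, 21), pixel = 0.05)
  so <- strand_orientation(pre, band_halfwidth = 0.5)
  expect_close(so$angle_from_axis, 63.0, 2, "noise-free recovery")
  # rotating the image by a quarter turn rotates the recovered axis but
  # leaves the relative angle unchanged
  rot <- topography(t(pre$height)[ncol(pre$height):1, ], pre$pixel)
  so_r <- strand_orientation(rot, band_halfwidth = 0.5)
  expect_lt(abs(so_r$angle_from_axis - so$angle_from_axis), 0.5)
  ax_diff <- (so_r$axis_angle - so$axis_angle) %% 180
  expect_lt(min(ax_diff, 180 - ax_diff - 90, abs(ax_diff - 90)), 1)
  # no ridge periodicity on a smooth bare cylinder
  px <- 0.07
  xs <- (seq_len(round(14 / px)) - 0.5) * px
  ys <- (seq_len(round(8 / px)) - 0.5) * px
  dperp <- matrix(ys, length(ys), length(xs)) - 4
  cyl <- ifelse(abs(dperp) < r0_65, r0_65 + sqrt(pmax(r0_65^2 - dperp^2, 0)), 0)
  bare <- topography(cyl, px)
  expect_true(strand_orientation(bare)$no_periodicity)
})
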