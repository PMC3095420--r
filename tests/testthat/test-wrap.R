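tube65_3u <- build_nanotube(nanotube_spec(6, 5, n_units = 3))
R0_65 <- tube65_3u$meta$tube_radius

test_that("nucleotide templates satisfy their structural invariants", {
  tpls <- lapply(stats::setNames(nm = c("A", "C", "G", "T")), nucleotide_template)
  for (b in names(tpls)) {
    at <- tpls[[b]]$atoms
    expect_equal(sum(at$name == "P"), 1L, info = b)          # one phosphate
    expect_true(all(c("C1'", "C2'", "C3'", "C4'", "O4'") %in% at$name),
                info = paste(b, "sugar ring"))
    ring <- at$name %in% c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
    expect_gte(sum(ring), 6)                                  # one ring system
    expect_gt(tpls[[b]]$span, 0)
    expect_close(sqrt(sum(tpls[[b]]$normal^2)), 1, 1e-12, "unit normal")
    # base plane is flat: all base-ring atoms at z = 0
    expect_lt(max(abs(at$z[ring])), 1e-9)
  }
  expect_gt(nrow(tpls$G$atoms), nrow(tpls$C$atoms))  # purine > pyrimidine
  expect_gt(nrow(tpls$A$atoms), nrow(tpls$T$atoms) - 3)
})

test_that("initial unit placement puts the base flat on the helix radius", {
  tpl <- nucleotide_template("C")
  u0 <- place_initial_unit(tpl, tube65_3u, alpha = 40, delta = 0.33, seed = 5)
  a <- u0$atoms
  ring <- a$name %in% c("N1", "C2", "N3", "C4", "C5", "C6")
  cen <- c(mean(a$x[ring]), mean(a$y[ring]), mean(a$z[ring]))
  expect_close(sqrt(cen[1]^2 + cen[2]^2), R0_65 + 0.33, 1e-6,
               "base centroid at helix radius R0 + delta = 0.703 nm")
  # base-plane normal is radial: fit the ring plane and compare with the
  # radial direction at the centroid
  xyz <- sweep(as.matrix(a[ring, c("x", "y", "z")]), 2, cen)
  normal <- svd(xyz)$v[, 3]
  radial <- c(cen[1], cen[2], 0) / sqrt(cen[1]^2 + cen[2]^2)
  expect_close(abs(sum(normal * radial)), 1, 1e-3, "normal parallel to radial")
})

test_that("helix replication follows the axial-shift / rotation formulas", {
  cfg <- wrap_config(strrep("C", 12), alpha = 63, R0 = R0_65, delta = 0.33, L = 0.5)
  u0 <- place_initial_unit(nucleotide_template("C"), tube65_3u, 63, seed = 2)
  strand <- replicate_helix(u0, cfg)
  a <- strand$atoms
  dz_expect <- 0.5 * sin(63 * pi / 180)
  p_atoms <- a[a$name == "P", ]
  expect_lt(max(abs(diff(p_atoms$z) - dz_expect)), 1e-9)
  # consecutive units advance by (chord-shortened) L along the helix,
  # measured at the base centroids which sit exactly on the helix radius
  cen <- cntdna:::base_centroids(strand)$xyz
  d <- sqrt(rowSums(diff(cen)^2))
  expect_true(all(abs(d - 0.5) / 0.5 < 0.01))
  # accumulated rotation reaches 2 pi at z advance 2 pi R tan(alpha):
  # equivalently the per-unit azimuth step is dz / (R tan alpha)
  R <- u0$meta$R
  dphi <- diff(atan2(p_atoms$y, p_atoms$x))
  dphi <- ((dphi + pi) %% (2 * pi)) - pi
  expect_lt(max(abs(dphi - dz_expect / (R * tan(63 * pi / 180)))), 1e-9)
})

test_that("bases per coil follow the coil-closure relation", {
  # R = 0.73 nm, L = 0.63 nm, alpha = 63 deg -> 2 pi R / (L cos alpha) = 16.0
  delta <- 0.73 - R0_65
  cfg <- wrap_config(strrep("C", 4), alpha = 63, R0 = R0_65, delta = delta, L = 0.63)
  u0 <- place_initial_unit(nucleotide_template("C"), tube65_3u, 63,
                           delta = delta, seed = 2)
  strand <- replicate_helix(u0, cfg)
  p_atoms <- strand$atoms[strand$atoms$name == "P", ]
  dphi <- atan2(p_atoms$y[2], p_atoms$x[2]) - atan2(p_atoms$y[1], p_atoms$x[1])
  dphi <- ((dphi + pi) %% (2 * pi)) - pi
  expect_close(2 * pi / abs(dphi), 16.0, 0.1, "bases per full coil")
})

test_that("replication is equivariant under rotation of the initial unit", {
  cfg <- wrap_config(strrep("C", 6), alpha = 40, R0 = R0_65)
  tpl <- nucleotide_template("C")
  u0 <- place_initial_unit(tpl, tube65_3u, 40, seed = 3)
  u0b <- u0
  beta <- 0.7
  rot <- cbind(c(cos(beta), sin(beta), 0), c(-sin(beta), cos(beta), 0), c(0, 0, 1))
  atom_coords(u0b) <- atom_coords(u0) %*% t(rot)
  u0b$meta$theta0 <- u0$meta$theta0 + beta
  s1 <- replicate_helix(u0, cfg)
  s2 <- replicate_helix(u0b, cfg)
  expect_lt(max(abs(atom_coords(s1) %*% t(rot) - atom_coords(s2))), 1e-9)
})

test_that("build then measure recovers the construction angle exactly", {
  for (alpha in c(30, 63)) {
    cfgs <- generate_initial_configs(strrep("C", 20), tube65_3u, alpha,
                                     L = 0.5, seed = 1)
    m <- measure_wrapping(cfgs[[1]])
    expect_close(m$mean_angle, alpha, 0.1, paste("round trip at", alpha))
    expect_lt(m$sd_angle, 0.1)
    expect_close(m$mean_angle_from_axis, 90 - alpha, 0.1, "complement emitted")
  }
})

test_that("measured period matches the helix pitch relation", {
  # helix of radius 1.05 nm at 63.4 deg from the axis: period
  # 2 pi R tan(90 - 63.4) = 3.3 nm; synthetic centroid track
  R <- 1.05; beta <- 63.4
  t <- seq(0, 4 * pi, by = 0.25)
  z <- R * tan((90 - beta) * pi / 180) * t
  atoms <- data.frame(element = "N", name = "N1",
                      x = R * cos(t), y = R * sin(t), z = z,
                      role = "DNA", unit = seq_along(t) - 1L, base = "C",
                      frozen = FALSE)
  m <- measure_wrapping(new_structure(atoms), R0 = 0.37)
  expect_close(m$period, 3.3, 0.05, "pitch from robust fit")
  expect_close(m$mean_angle_from_axis, 63.4, 0.2, "from-axis angle")
})

test_that("degenerate straight strands are flagged", {
  atoms <- data.frame(element = "N", name = "N1",
                      x = 0.7, y = 0, z = seq(0, 5, by = 0.5),
                      role = "DNA", unit = 0:10, base = "C", frozen = FALSE)
  m <- measure_wrapping(new_structure(atoms), R0 = 0.37)
  expect_false(m$period_defined)
  expect_close(m$mean_angle, 90, 1e-6, "axial strand angle")
  expect_error(measure_wrapping(new_structure(atoms[1:2, ])), "at least 3")
})

test_that("angle grids generate one hybrid per feasible angle", {
  hyb <- generate_initial_configs("GAGAAGAGAGCAGAAGGAGA", tube65_3u,
                                  seq(10, 80, by = 10), seed = 1)
  expect_length(hyb, 8)
  a <- hyb[[3]]$atoms
  dna <- a[a$role == "DNA", ]
  expect_equal(length(unique(dna$unit)), 20L)
  # sequence order preserved
  seq_built <- vapply(0:19, function(u) dna$base[dna$unit == u][1], "")
  expect_equal(paste(seq_built, collapse = ""), "GAGAAGAGAGCAGAAGGAGA")
  # no steric contact between DNA heavy atoms and the tube
  tube_xyz <- atom_coords(tube65_3u)
  for (h in hyb[c(1, 8)]) {
    d <- h$atoms[h$atoms$role == "DNA" & h$atoms$element != "H", ]
    dmin <- sqrt(cntdna:::min_cross_dist2(as.matrix(d[, c("x", "y", "z")]), tube_xyz))
    expect_gte(dmin, 0.25)
  }
})

test_that("infeasible angles are skipped with a warning, never built", {
  expect_warning(
    hyb <- generate_initial_configs(strrep("C", 25), tube65_3u,
                                    c(30, 80), seed = 1, L = 0.55),
    "skipped")
  expect_length(hyb, 1)
  # a C-42-mer fits a 4-unit tube at 60 degrees with a suitably compact step
  tube4 <- build_nanotube(nanotube_spec(6, 5, n_units = 4))
  hyb42 <- generate_initial_configs(strrep("C", 42), tube4, 60, L = 0.40, seed = 1)
  expect_length(hyb42, 1)
  zr <- range(hyb42[[1]]$atoms$z[hyb42[[1]]$atoms$role == "DNA"])
  expect_gt(zr[1], 0.1)
  expect_lt(zr[2], tube4$meta$tube_length - 0.1)
})

test_that("wrap configuration rejects invalid inputs", {
  expect_error(wrap_config("CCX", 40, 0.37), "alphabet")
  expect_error(wrap_config("CC", 0, 0.37), "strictly between")
  expect_error(wrap_config("CC", 95, 0.37), "strictly between")
  expect_error(wrap_config("CC", 40, 0.37, delta = -0.1), "positive")
  expect_error(wrap_config("", 40, 0.37), "length")
})
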