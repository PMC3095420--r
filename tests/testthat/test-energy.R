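params_default <- ff_params()

test_that("parameter validation and config round trip", {
  expect_error(ff_params(cutoff = 0.2), "cutoff")
  expect_error(ff_params(r_on = 1.3, cutoff = 1.2), "r_on")
  bad <- default_lj <- cntdna:::default_lj_table()
  bad$eps[1] <- -1
  expect_error(ff_params(lj = bad), "well depths")
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(scale = 2, cutoff = 1.4, k_intra = 10),
                       cfg, auto_unbox = TRUE)
  p <- read_ff_config(cfg)
  expect_equal(p$scale, 2)
  expect_equal(p$cutoff, 1.4)
  expect_equal(p$k_intra, 10)
})

test_that("an LJ dimer at the well minimum scores exactly -epsilon", {
  r_min <- 2^(1 / 6) * 0.355
  s <- free_atom_structure(rbind(c(0, 0, 0), c(r_min, 0, 0)))
  e <- total_energy(s, params_default)
  expect_close(e$total, -params_default$scale * 0.07, 1e-12, "LJ well depth")
  expect_equal(e$total, e$cnt_dna + e$dna_dna + e$bonded)
})

test_that("unknown elements and non-finite coordinates are rejected", {
  s <- free_atom_structure(rbind(c(0, 0, 0), c(0.5, 0, 0)), element = "Xx")
  expect_error(total_energy(s, params_default), "unknown element")
  s2 <- free_atom_structure(rbind(c(0, 0, 0), c(0.5, 0, 0)))
  s2$atoms$x[1] <- NA
  expect_error(total_energy(s2, params_default), "finite")
})

test_that("cutoff-free energies match the naive double-loop oracle", {
  p <- ff_params(cutoff = Inf)
  set.seed(42)
  for (n in c(20, 120, 400)) {
    xyz <- matrix(runif(3 * n, 0, 3), ncol = 3)
    # spread atoms to avoid singular overlaps
    xyz <- xyz[order(xyz[, 1]), ]
    xyz[, 1] <- xyz[, 1] + seq(0, 0.3 * (n - 1), by = 0.3)
    el <- sample(c("C", "N", "O", "H"), n, replace = TRUE)
    s <- free_atom_structure(xyz, element = "C")
    s$atoms$element <- el
    s$atoms$role[seq_len(n %/% 3)] <- "CNT"
    s$atoms$unit[seq_len(n %/% 3)] <- NA_integer_
    s$atoms$unit[-seq_len(n %/% 3)] <- seq_len(n - n %/% 3) - 1L
    e <- total_energy(s, p)
    lj <- cntdna:::atom_lj(el, p)
    group <- ifelse(s$atoms$role == "CNT", -1L, s$atoms$unit)
    e_oracle <- oracle_nb_energy(xyz, group, lj$eps, lj$sigma, p$scale)
    expect_lt(abs(e$total - e_oracle) / abs(e_oracle), 1e-10)
  }
})

test_that("energy is invariant under rigid motion and charge terms match", {
  p <- ff_params(cutoff = Inf, use_charges = TRUE,
                 charge_set = c("C" = 0.2))
  set.seed(7)
  xyz <- matrix(rnorm(3 * 30, sd = 1.5), ncol = 3)
  xyz[, 1] <- xyz[, 1] + 3 * seq_len(30)   # keep pairs apart
  s <- free_atom_structure(xyz)
  e1 <- total_energy(s, p)
  s2 <- s
  atom_coords(s2) <- xyz + matrix(rep(c(5, -3, 2), each = 30), ncol = 3)
  e2 <- total_energy(s2, p)
  expect_lt(abs(e1$total - e2$total), 1e-10 * max(1, abs(e1$total)))
  lj <- cntdna:::atom_lj(s$atoms$element, p)
  e_oracle <- oracle_nb_energy(xyz, s$atoms$unit, lj$eps, lj$sigma, p$scale,
                               charge = rep(0.2, 30))
  expect_lt(abs(e1$total - e_oracle) / abs(e_oracle), 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  tube <- build_nanotube(nanotube_spec(5, 0))
  u0 <- place_initial_unit(nucleotide_template("C"), tube, 45, seed = 1)
  hyb <- combine_structures(tube, u0)
  hyb$meta$L <- 0.5
  p <- params_default
  a <- hyb$atoms
  lj <- cntdna:::atom_lj(a$element, p)
  topo <- cntdna:::build_topology(hyb, p)
  co <- atom_coords(hyb)
  g <- cntdna:::eval_ff(co, a, lj, topo, p, want_grad = TRUE)$grad
  free <- which(a$role == "DNA")[c(1, 8, 17)]
  h <- 1e-6
  for (i in free) for (d in 1:3) {
    cp <- co; cp[i, d] <- cp[i, d] + h
    cm <- co; cm[i, d] <- cm[i, d] - h
    num <- (cntdna:::eval_ff(cp, a, lj, topo, p)$total -
            cntdna:::eval_ff(cm, a, lj, topo, p)$total) / (2 * h)
    expect_close(g[i, d], num, 1e-3 * max(1, abs(num)), "gradient component")
  }
})

test_that("minimization: fixed points, frozen atoms, monotone trace", {
  r_min <- 2^(1 / 6) * 0.355
  dimer <- free_atom_structure(rbind(c(0, 0, 0), c(r_min, 0, 0)))
  res <- minimize(dimer, params_default)
  expect_true(res$converged)
  expect_lt(max(abs(atom_coords(res$structure) - atom_coords(dimer))), 1e-6)

  # stretched dimer relaxes to the well minimum; trace is non-increasing
  far <- free_atom_structure(rbind(c(0, 0, 0), c(0.5, 0, 0)))
  res2 <- minimize(far, params_default, chunk = 5L)
  expect_true(res2$converged)
  d_final <- sqrt(sum(diff(atom_coords(res2$structure))^2))
  expect_close(d_final, r_min, 1e-4, "relaxed pair distance")
  expect_true(all(diff(res2$trace) <= 1e-8))

  # frozen atoms are bit-exact after minimization
  tube <- build_nanotube(nanotube_spec(5, 0))
  u0 <- place_initial_unit(nucleotide_template("C"), tube, 45, seed = 1)
  hyb <- combine_structures(tube, u0)
  hyb$meta$L <- 0.5
  res3 <- minimize(hyb, params_default, max_iter = 300)
  frozen_before <- atom_coords(hyb)[hyb$atoms$frozen, ]
  frozen_after <- atom_coords(res3$structure)[res3$structure$atoms$frozen, ]
  expect_identical(frozen_before, frozen_after)
  expect_true(all(diff(res3$trace) <= 1e-8))
})

test_that("a single cytosine unit relaxes into the pi-stacking geometry", {
  tube <- build_nanotube(nanotube_spec(6, 5, n_units = 2))
  u0 <- place_initial_unit(nucleotide_template("C"), tube, 60, seed = 3)
  hyb <- combine_structures(tube, u0)
  hyb$meta$L <- 0.5
  opt <- minimize(hyb, params_default, max_iter = 2000)
  a <- opt$structure$atoms
  ring <- a$role == "DNA" & a$name %in% c("N1", "C2", "N3", "C4", "C5", "C6")
  clearance <- min(sqrt(a$x[ring]^2 + a$y[ring]^2)) - tube$meta$tube_radius
  expect_gt(clearance, 0.28)
  expect_lt(clearance, 0.38)
  # adsorption energy anchor of the calibrated potential
  dna <- cntdna:::strip_cnt(opt$structure)
  e_ads <- (opt$energy - minimize(dna, params_default, max_iter = 500)$energy) /
    KCAL_PER_EV
  expect_gt(-e_ads, 0.5)
  expect_lt(-e_ads, 0.75)
})

test_that("binding vanishes beyond the cutoff and is negative when stacked", {
  tube <- build_nanotube(nanotube_spec(6, 5, n_units = 2))
  u0 <- place_initial_unit(nucleotide_template("C"), tube, 50, seed = 2)
  cfg <- wrap_config("CCCCC", 50, R0 = tube$meta$tube_radius, L = 0.5)
  strand <- replicate_helix(u0, cfg)
  far <- strand
  xyz <- atom_coords(far)
  xyz[, 1] <- xyz[, 1] + 5
  atom_coords(far) <- xyz
  hyb_far <- combine_structures(tube, far)
  e_far <- total_energy(hyb_far, params_default)
  expect_lt(abs(e_far$cnt_dna) / KCAL_PER_EV, 0.001)

  hyb <- combine_structures(tube, strand)
  be <- binding_energy(hyb, params_default, fixed_ends = FALSE, max_iter = 800)
  expect_lt(be$binding_ev, 0)
})

test_that("the isolated-DNA reference improves on the stripped geometry", {
  tube <- build_nanotube(nanotube_spec(6, 5, n_units = 2))
  u0 <- place_initial_unit(nucleotide_template("C"), tube, 50, seed = 2)
  cfg <- wrap_config("CCCC", 50, R0 = tube$meta$tube_radius, L = 0.5)
  hyb <- combine_structures(tube, replicate_helix(u0, cfg))
  opt <- minimize(set_end_constraints(hyb, FALSE), params_default, max_iter = 600)
  ref <- isolated_dna_reference(opt$structure, params_default, max_iter = 600)
  stripped <- total_energy(cntdna:::strip_cnt(opt$structure), params_default)
  expect_lte(ref$energy, stripped$total + 1e-9)
  # k = 1 multi-start equals the single-start result
  ref1 <- isolated_dna_reference(opt$structure, params_default,
                                 n_starts = 1L, max_iter = 600)
  expect_equal(ref$energy, ref1$energy)
})

test_that("the reference is independent of the tube's rigid-body frame", {
  tube <- build_nanotube(nanotube_spec(6, 5, n_units = 2))
  u0 <- place_initial_unit(nucleotide_template("C"), tube, 50, seed = 4)
  cfg <- wrap_config("CCC", 50, R0 = tube$meta$tube_radius, L = 0.5)
  hyb <- combine_structures(tube, replicate_helix(u0, cfg))
  rotq <- function(s) { xyz <- atom_coords(s); atom_coords(s) <- cbind(-xyz[, 2], xyz[, 1], xyz[, 3]); s }
  # the energy itself is exactly frame-invariant
  e1 <- total_energy(cntdna:::strip_cnt(hyb), params_default)$total
  e2 <- total_energy(cntdna:::strip_cnt(rotq(hyb)), params_default)$total
  expect_lt(abs(e1 - e2), 1e-9 * max(1, abs(e1)))
  # optimized references agree to within the local-minimum scatter that
  # rounding-order differences can induce in a chaotic descent path
  r1 <- isolated_dna_reference(hyb, params_default, max_iter = 400)
  r2 <- isolated_dna_reference(rotq(hyb), params_default, max_iter = 400)
  expect_close(r1$energy, r2$energy, 0.5, "frame independence")
})
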