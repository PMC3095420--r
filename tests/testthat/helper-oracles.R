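# Independent oracles used by the unit tests. These deliberately take naive
# routes (floating-point lattice enumeration, O(N^2) double loops in plain R)
# so that they share no code with the implementation they check.

# Brute-force graphene roll-up: enumerate lattice sites of an oversized
# graphene patch in real space, project onto the chiral / translation
# vectors, and keep the sites falling inside one translational cell.
oracle_tube_cell <- function(n, m, a = 0.246) {
  a1 <- a * c(sqrt(3) / 2, 1 / 2)
  a2 <- a * c(sqrt(3) / 2, -1 / 2)
  ch <- n * a1 + m * a2
  dr <- function(x, y) { while (y != 0) { t <- y; y <- x %% y; x <- t }; x }
  d_R <- dr(2 * n + m, 2 * m + n)
  t1 <- (2 * m + n) / d_R; t2 <- -(2 * n + m) / d_R
  tv <- t1 * a1 + t2 * a2
  rng <- -(abs(n) + abs(m) + abs(t1) + abs(t2) + 2)
  pts <- list(); k <- 1
  basis <- rbind(c(0, 0), (a1 + a2) / 3)
  M <- cbind(ch, tv)
  Minv <- solve(M)
  eps <- 1e-9
  for (i in rng:(-rng)) for (j in rng:(-rng)) for (b in 1:2) {
    p <- i * a1 + j * a2 + basis[b, ]
    fr <- Minv %*% p
    fr <- fr - floor(fr + eps)
    pts[[k]] <- c(round(fr[1], 7), round(fr[2], 7), b)
    k <- k + 1
  }
  u <- unique(do.call(rbind, pts))
  list(count = nrow(u), frac = u)
}

# chiral angle from explicit 2-D vector geometry (angle between the chiral
# vector and the zigzag direction a1)
oracle_chiral_angle <- function(n, m, a = 0.246) {
  a1 <- a * c(sqrt(3) / 2, 1 / 2)
  a2 <- a * c(sqrt(3) / 2, -1 / 2)
  ch <- n * a1 + m * a2
  cosang <- sum(ch * a1) / sqrt(sum(ch^2)) / sqrt(sum(a1^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

# Naive non-bonded energy: plain R double loop, no cutoff, same physics
# (Lennard-Jones with Lorentz-Berthelot combination over inter-group pairs,
# optional Coulomb), written independently of the C++ kernel.
oracle_nb_energy <- function(coords, group, eps, sigma, scale,
                             charge = NULL, excl = NULL) {
  n <- nrow(coords)
  if (is.null(charge)) charge <- numeric(n)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (group[i] == group[j]) next
      if (!is.null(excl) && any(excl[, 1] == i & excl[, 2] == j)) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      sig <- (sigma[i] + sigma[j]) / 2
      ee <- scale * sqrt(eps[i] * eps[j])
      e <- e + 4 * ee * ((sig / r)^12 - (sig / r)^6)
      if (charge[i] != 0 && charge[j] != 0) {
        e <- e + 33.20636 * charge[i] * charge[j] / r
      }
    }
  }
  e
}

# structure with bare atoms (one per unit, no template topology)
free_atom_structure <- function(xyz, element = "C", role = "DNA") {
  n <- nrow(xyz)
  new_structure(data.frame(
    element = element, name = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    role = role, unit = if (role == "DNA") seq_len(n) - 1L else NA_integer_,
    base = NA_character_, frozen = FALSE, stringsAsFactors = FALSE
  ))
}

expect_close <- function(actual, expected, tol, label = NULL) {
  expect_true(abs(actual - expected) <= tol,
              info = paste0(label, ": got ", actual, ", expected ", expected,
                            " +/- ", tol))
}
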