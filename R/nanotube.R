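#' Specification of a single-walled carbon nanotube
#'
#' Captures the chiral indices (n, m) of a single-walled carbon nanotube and
#' the graphene lattice constant, together with the number of translational
#' repeat units to generate. Derived scalar geometry (diameter, chiral angle,
#' repeat length, atoms per unit) is available through [chiral_angle()] and
#' [tube_dimensions()].
#'
#' @param n,m integer chiral indices with `0 <= m <= n`, not both zero.
#' @param a_lattice graphene lattice constant in nm (default 0.246,
#'   corresponding to a C-C bond of 0.142 nm).
#' @param n_units positive integer number of translational repeat units.
#' @return An object of class `nanotube_spec`.
#' @examples
#' spec <- nanotube_spec(6, 5, n_units = 3)
#' chiral_angle(spec)
#' tube_dimensions(spec)
#' @export
nanotube_spec <- function(n, m, a_lattice = 0.246, n_units = 1L) {
  if (length(n) != 1 || length(m) != 1 || n %% 1 != 0 || m %% 1 != 0) {
    stop("chiral indices n and m must be single integers")
  }
  n <- as.integer(n); m <- as.integer(m)
  if (n < 0 || m < 0) stop("chiral indices must be non-negative, got (", n, ",", m, ")")
  if (m > n) stop("chiral index m must satisfy m <= n, got (", n, ",", m, ")")
  if (n == 0 && m == 0) stop("chiral indices must not both be zero")
  if (!is.numeric(a_lattice) || a_lattice <= 0) {
    stop("a_lattice must be a positive lattice constant in nm")
  }
  if (n_units %% 1 != 0 || n_units < 1) stop("n_units must be a positive integer")
  structure(list(n = n, m = m, a_lattice = a_lattice, n_units = as.integer(n_units)),
            class = "nanotube_spec")
}

#' @export
print.nanotube_spec <- function(x, ...) {
  dims <- tube_dimensions(x)
  cat(sprintf("<(%d,%d) nanotube: d = %.3f nm, theta = %.1f deg, %d unit(s), length %.2f nm>\n",
              x$n, x$m, dims$diameter, chiral_angle(x), x$n_units, dims$length))
  invisible(x)
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Chiral angle of a nanotube
#'
#' The angle between the chiral (roll-up) vector and the zigzag lattice
#' direction, `atan(sqrt(3) m / (2 n + m))`, in degrees. It lies in
#' `[0, 30]`: 0 for zigzag `(n, 0)` tubes and 30 for armchair `(n, n)`.
#'
#' @param spec a [nanotube_spec()].
#' @return chiral angle in degrees.
#' @examples
#' chiral_angle(nanotube_spec(6, 5)) # 27.0
#' @export
chiral_angle <- function(spec) {
  stopifnot(inherits(spec, "nanotube_spec"))
  atan2(sqrt(3) * spec$m, 2 * spec$n + spec$m) * 180 / pi
}

#' Derived scalar tube geometry
#'
#' @param spec a [nanotube_spec()].
#' @return list with `diameter` (nm), `radius` (nm), `repeat_length` (nm, the
#'   translational period T), `atoms_per_unit`, `n_atoms` (for all units) and
#'   `length` (nm, `n_units * T`).
#' @export
tube_dimensions <- function(spec) {
  stopifnot(inherits(spec, "nanotube_spec"))
  n <- spec$n; m <- spec$m; a <- spec$a_lattice
  q <- n^2 + n * m + m^2
  d <- a * sqrt(q) / pi
  d_R <- gcd2(2 * n + m, 2 * m + n)
  T_len <- sqrt(3) * pi * d / d_R
  apu <- 4 * q / d_R
  list(diameter = d, radius = d / 2, repeat_length = T_len,
       atoms_per_unit = as.integer(apu), n_atoms = as.integer(apu * spec$n_units),
       length = spec$n_units * T_len)
}

# Exact enumeration of graphene lattice sites inside one translational cell
# of the rolled-up tube, in fractional (p, q) coordinates along the chiral
# vector Ch = n a1 + m a2 and translation vector T = t1 a1 + t2 a2. All
# arithmetic is integer (numerators scaled by 3 for the two-atom basis), so
# the cell membership test is exact and the atom count comes out at exactly
# 4 (n^2 + n m + m^2) / d_R.
tube_unit_cell_fractions <- function(n, m) {
  d_R <- gcd2(2 * n + m, 2 * m + n)
  t1 <- (2 * m + n) / d_R
  t2 <- -(2 * n + m) / d_R
  D <- n * t2 - m * t1            # = -2 (n^2 + n m + m^2) / d_R, non-zero
  Dden <- 3L * as.integer(D)
  s <- sign(Dden)
  i_rng <- range(c(0, n, t1, n + t1)); j_rng <- range(c(0, m, t2, m + t2))
  grid <- expand.grid(i = seq(i_rng[1] - 2L, i_rng[2] + 2L),
                      j = seq(j_rng[1] - 2L, j_rng[2] + 2L),
                      b = c(0L, 1L))
  I <- 3L * grid$i + grid$b
  J <- 3L * grid$j + grid$b
  Np <- (I * t2 - J * t1) * s
  Nq <- (J * n - I * m) * s
  den <- abs(Dden)
  pm <- ((Np %% den) + den) %% den
  qm <- ((Nq %% den) + den) %% den
  keep <- !duplicated(paste(pm, qm, grid$b))
  data.frame(p = pm[keep] / den, q = qm[keep] / den, basis = grid$b[keep])
}

#' Build the atomistic coordinates of a nanotube
#'
#' Rolls the graphene lattice onto the cylinder of radius `d/2`: every carbon
#' of the translational repeat cell is placed at azimuth `2 pi p` and height
#' `q T`, where `(p, q)` are its exact fractional coordinates along the chiral
#' and translation vectors. The tube axis is the z axis, one open edge sits at
#' `z = 0`, and the cell is stacked `n_units` times. Ends are left open
#' (no capping); nearest-neighbour distances are chord-shortened on the
#' cylinder by curvature but stay within 2 percent of 0.142 nm.
#'
#' @param spec a [nanotube_spec()].
#' @return a [new_structure()] of carbon atoms with `role = "CNT"`, all frozen
#'   (the tube is treated as a rigid substrate by the energy model).
#' @examples
#' tube <- build_nanotube(nanotube_spec(6, 5, n_units = 1))
#' n_atoms(tube) # 364
#' @export
build_nanotube <- function(spec) {
  stopifnot(inherits(spec, "nanotube_spec"))
  dims <- tube_dimensions(spec)
  frac <- tube_unit_cell_fractions(spec$n, spec$m)
  if (nrow(frac) != dims$atoms_per_unit) {
    stop("internal error: lattice enumeration yielded ", nrow(frac),
         " atoms, expected ", dims$atoms_per_unit)
  }
  R <- dims$radius
  reps <- seq_len(spec$n_units) - 1L
  p <- rep(frac$p, times = spec$n_units)
  z <- rep(frac$q, times = spec$n_units) * dims$repeat_length +
    rep(reps, each = nrow(frac)) * dims$repeat_length
  atoms <- data.frame(
    element = "C",
    name = "C",
    x = R * cos(2 * pi * p),
    y = R * sin(2 * pi * p),
    z = z,
    role = "CNT",
    unit = NA_integer_,
    base = NA_character_,
    frozen = TRUE,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, meta = list(
    spec = spec, tube_radius = R, tube_length = dims$length,
    repeat_length = dims$repeat_length
  ))
}
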