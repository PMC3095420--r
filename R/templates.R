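# Idealized nucleotide-unit geometry.
#
# A unit is one DNA base attached to a phosphate-deoxyribose backbone
# fragment. Geometry is built from standard idealized internal coordinates:
# aromatic rings as regular polygons with 0.139 nm bonds, C-O/C-N exocyclic
# bonds of 0.123/0.134 nm, a deoxyribose five-ring with ~0.15 nm bonds and a
# tetrahedral-ish phosphate. Coordinates are in the unit's local frame:
#   x = strand (head-to-tail) direction, z = base-plane normal (points away
#   from the tube on placement), base ring in the z = 0 plane with its
#   centroid at the origin, backbone on the +z side.
# Hydrogens are included; their positions are approximate in-plane /
# tetrahedral offsets, which is adequate because each unit is held
# near-rigid by intra-unit distance restraints during optimization.

ring_hexagon <- function(names, radius = 0.139, center = c(0, 0), start_deg = -90) {
  ang <- (start_deg + 60 * (seq_along(names) - 1)) * pi / 180
  data.frame(name = names, element = substr(names, 1, 1),
             x = center[1] + radius * cos(ang),
             y = center[2] + radius * sin(ang), z = 0,
             part = "base", stringsAsFactors = FALSE)
}

# backbone fragment shared by all four bases; attachment nitrogen sits at
# (0, -0.139, 0) in the local frame
backbone_atoms <- function() {
  tab <- rbind(
    c("C1'", "C",  0.000, -0.200, 0.130),
    c("C2'", "C",  0.130, -0.250, 0.210),
    c("C3'", "C",  0.075, -0.360, 0.300),
    c("C4'", "C", -0.065, -0.380, 0.270),
    c("O4'", "O", -0.110, -0.280, 0.190),
    c("C5'", "C", -0.175, -0.430, 0.380),
    c("O5'", "O", -0.270, -0.360, 0.440),
    c("O3'", "O",  0.150, -0.350, 0.430),
    c("P",   "P", -0.155, -0.300, 0.540),
    c("O1P", "O", -0.245, -0.390, 0.630),
    c("O2P", "O", -0.075, -0.390, 0.600),
    c("H1'", "H",  0.085, -0.175, 0.060),
    c("H2'", "H",  0.215, -0.270, 0.255),
    c("H2''","H",  0.155, -0.165, 0.155),
    c("H3'", "H",  0.090, -0.295, 0.385),
    c("H4'", "H", -0.125, -0.435, 0.205),
    c("H5'", "H", -0.115, -0.505, 0.440),
    c("H5''","H", -0.250, -0.480, 0.320)
  )
  out <- data.frame(name = tab[, 1], element = tab[, 2],
                    x = as.numeric(tab[, 3]), y = as.numeric(tab[, 4]),
                    z = as.numeric(tab[, 5]), stringsAsFactors = FALSE)
  out$part <- ifelse(out$name %in% c("P", "O1P", "O2P"), "phosphate", "sugar")
  out
}

base_atoms_pyrimidine <- function(base) {
  ring <- ring_hexagon(c("N1", "C2", "N3", "C4", "C5", "C6"))
  add <- function(name, element, x, y) {
    data.frame(name = name, element = element, x = x, y = y, z = 0,
               part = "base", stringsAsFactors = FALSE)
  }
  extra <- if (base == "C") rbind(
    add("O2", "O", 0.227, -0.131),
    add("N4", "N", 0.000,  0.272),
    add("H41", "H", 0.087, 0.323),
    add("H42", "H", -0.087, 0.323),
    add("H5", "H", -0.214, 0.124),
    add("H6", "H", -0.214, -0.124)
  ) else rbind(                      # thymine
    add("O2", "O", 0.227, -0.131),
    add("H3", "H", 0.207, 0.120),
    add("O4", "O", 0.000, 0.262),
    add("C7", "C", -0.251, 0.146),
    add("H71", "H", -0.310, 0.230),
    add("H72", "H", -0.330, 0.085),
    add("H73", "H", -0.270, 0.200),
    add("H6", "H", -0.214, -0.124)
  )
  if (base == "T") extra$z[extra$name %in% c("H71", "H72", "H73")] <- c(0.06, -0.06, -0.09)
  rbind(ring, extra)
}

base_atoms_purine <- function(base) {
  hex <- ring_hexagon(c("C4", "C5", "C6", "N1", "C2", "N3"),
                      center = c(0, 0.10), start_deg = -90)
  pen <- rbind(
    data.frame(name = "N7", element = "N", x = 0.2232, y = -0.0622, z = 0, part = "base"),
    data.frame(name = "C8", element = "C", x = 0.1670, y = -0.1890, z = 0, part = "base"),
    data.frame(name = "N9", element = "N", x = 0.0289, y = -0.1747, z = 0, part = "base")
  )
  add <- function(name, element, x, y) {
    data.frame(name = name, element = element, x = x, y = y, z = 0,
               part = "base", stringsAsFactors = FALSE)
  }
  extra <- if (base == "G") rbind(
    add("O6", "O", 0.226, 0.231),
    add("H1", "H", 0.000, 0.340),
    add("N2", "N", -0.236, 0.237),
    add("H21", "H", -0.336, 0.247),
    add("H22", "H", -0.271, 0.331),
    add("H8", "H", 0.221, -0.283)
  ) else rbind(                      # adenine
    add("N6", "N", 0.226, 0.231),
    add("H61", "H", 0.314, 0.282),
    add("H62", "H", 0.226, 0.332),
    add("H2", "H", -0.207, 0.220),
    add("H8", "H", 0.221, -0.283)
  )
  at <- rbind(hex, pen, extra)
  # shift so the glycosidic nitrogen N9 coincides with the pyrimidine N1
  # location used by the shared backbone fragment
  n9 <- at[at$name == "N9", c("x", "y")]
  at$x <- at$x - n9$x + 0
  at$y <- at$y - n9$y - 0.139
  at
}

# Rotate the base in its plane about the glycosidic attachment point
# (0, -0.139) to minimize the base's extent along the local x (strand)
# direction. The chi angle is free in ssDNA; the narrow-side-forward
# orientation is what lets flat-lying bases pack at sub-base-width steps.
rotate_base_chi <- function(at) {
  ax <- 0; ay <- -0.139
  best_t <- 0; best_span <- Inf
  for (t_deg in seq(-90, 90, by = 1)) {
    t <- t_deg * pi / 180
    xr <- (at$x - ax) * cos(t) - (at$y - ay) * sin(t) + ax
    span <- max(xr) - min(xr)
    if (span < best_span) { best_span <- span; best_t <- t }
  }
  xr <- (at$x - ax) * cos(best_t) - (at$y - ay) * sin(best_t) + ax
  yr <- (at$x - ax) * sin(best_t) + (at$y - ay) * cos(best_t) + ay
  at$x <- xr; at$y <- yr
  at
}

#' Idealized template of one nucleotide unit
#'
#' Returns the local-frame geometry of a single DNA unit (base plus
#' phosphate-deoxyribose fragment) used to seed the helical wrap
#' construction. The unit's local frame has the base ring in the `z = 0`
#' plane with its centroid at the origin, the base-plane normal along `+z`,
#' and the strand (head-to-tail) direction along `+x`. The designated head
#' attachment atom is the phosphorus `P`, the tail is `O3'`; consecutive
#' units in a strand are linked by an `O3'`-`P` harmonic bond.
#'
#' @param base one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @return list of class `nucleotide_template` with elements `base`,
#'   `atoms` (data.frame: name, element, x, y, z in nm, part), `head`,
#'   `tail`, `normal` (unit base-plane normal) and `span` (nm, the
#'   head-to-tail atom distance).
#' @examples
#' tpl <- nucleotide_template("C")
#' nrow(tpl$atoms)
#' @export
nucleotide_template <- function(base = c("A", "C", "G", "T")) {
  base <- match.arg(base)
  at <- if (base %in% c("C", "T")) base_atoms_pyrimidine(base) else base_atoms_purine(base)
  # glycosidic (chi-like) in-plane rotation about the attachment nitrogen:
  # orient the base so its narrow dimension lies along the strand direction,
  # which is how flat-stacked bases accommodate a compact per-residue step
  at <- rotate_base_chi(at)
  at <- rbind(at, backbone_atoms())
  # re-centre: base ring-system heavy-atom centroid at the local origin
  ring_names <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
  ring <- at[at$name %in% ring_names, ]
  at$x <- at$x - mean(ring$x)
  at$y <- at$y - mean(ring$y)
  head_i <- which(at$name == "P")
  tail_i <- which(at$name == "O3'")
  span <- sqrt(sum((at[head_i, c("x", "y", "z")] - at[tail_i, c("x", "y", "z")])^2))
  structure(list(base = base, atoms = at, head = "P", tail = "O3'",
                 normal = c(0, 0, 1), span = span),
            class = "nucleotide_template")
}

#' @export
print.nucleotide_template <- function(x, ...) {
  cat(sprintf("<nucleotide template %s: %d atoms (%d heavy), head %s, tail %s>\n",
              x$base, nrow(x$atoms), sum(x$atoms$element != "H"), x$head, x$tail))
  invisible(x)
}
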