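#' Helical wrap configuration
#'
#' Parameters of the helix-on-cylinder construction that places one
#' nucleotide unit per sequence letter on the tube surface. The construction
#' angle `alpha` enters the coordinate formulas as the helix angle measured
#' from the circumferential (chiral-vector) direction: the per-unit axial
#' increment is `dz = L sin(alpha)` and the per-unit azimuthal rotation is
#' `dz / (R tan(alpha))`. Because the two angle conventions (from the
#' circumference vs. from the tube axis) are easily conflated in this field,
#' every measurement report emits both `alpha` and its complement
#' `90 - alpha`.
#'
#' @param sequence DNA sequence string over A, C, G, T (5' to 3').
#' @param alpha construction helix angle in degrees, strictly between 0
#'   and 90.
#' @param R0 tube radius in nm.
#' @param delta base-stacking clearance in nm between the tube surface and
#'   the base plane (default 0.33, the typical pi-stacking distance). The
#'   helix radius is `R = R0 + delta`.
#' @param L per-residue step along the strand in nm (default 0.50; chosen so
#'   that the oligomers studied here stay shorter than the tube across the
#'   whole construction-angle grid, see the methods vignette).
#' @param fixed_ends logical; whether terminal units are frozen during
#'   optimization.
#' @param seed integer seed for the random placement azimuth.
#' @return list of class `wrap_config`.
#' @export
wrap_config <- function(sequence, alpha, R0, delta = 0.33, L = 0.50,
                        fixed_ends = TRUE, seed = 1L) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) stop("sequence must have length >= 1")
  letters_ <- strsplit(sequence, "")[[1]]
  if (!all(letters_ %in% c("A", "C", "G", "T"))) {
    stop("sequence must be over the alphabet {A, C, G, T}")
  }
  if (!(alpha > 0 && alpha < 90)) stop("alpha must lie strictly between 0 and 90 degrees")
  if (delta <= 0) stop("delta must be positive")
  if (L <= 0) stop("L must be positive")
  if (R0 <= 0) stop("R0 must be positive")
  structure(list(sequence = sequence, bases = letters_, alpha = alpha,
                 R0 = R0, delta = delta, L = L, R = R0 + delta,
                 fixed_ends = isTRUE(fixed_ends), seed = as.integer(seed)),
            class = "wrap_config")
}

# local->global placement of a template into the tube frame at azimuth
# theta0, strand angle alpha (degrees, from the circumferential direction),
# base centroid at radius R and axial position z0
place_template <- function(template, alpha, R, theta0, z0 = 0) {
  a <- alpha * pi / 180
  e_r <- c(cos(theta0), sin(theta0), 0)
  e_phi <- c(-sin(theta0), cos(theta0), 0)
  e_z <- c(0, 0, 1)
  t_hat <- cos(a) * e_phi + sin(a) * e_z
  u_hat <- c(e_r[2] * t_hat[3] - e_r[3] * t_hat[2],
             e_r[3] * t_hat[1] - e_r[1] * t_hat[3],
             e_r[1] * t_hat[2] - e_r[2] * t_hat[1])
  loc <- as.matrix(template$atoms[, c("x", "y", "z")])
  glob <- loc[, 1, drop = FALSE] %*% t_hat + loc[, 2, drop = FALSE] %*% u_hat +
    loc[, 3, drop = FALSE] %*% e_r
  glob <- sweep(glob, 2, R * e_r + z0 * e_z, "+")
  colnames(glob) <- c("x", "y", "z")
  glob
}

unit_as_structure <- function(template, glob, unit_index) {
  new_structure(data.frame(
    element = template$atoms$element,
    name = template$atoms$name,
    x = glob[, 1], y = glob[, 2], z = glob[, 3],
    role = "DNA", unit = as.integer(unit_index), base = template$base,
    frozen = FALSE, stringsAsFactors = FALSE
  ))
}

#' Place the initial nucleotide unit on the tube surface
#'
#' Positions unit `n = 0` with its base centroid at radial distance
#' `R = R0 + delta` from the tube axis, the base-plane normal along the
#' radial direction (flat pi-stacking on the surface), and the head-tail
#' axis at angle `alpha` from the circumferential direction in the local
#' tangent plane. The placement azimuth is drawn from a seeded generator;
#' a placement that brings any DNA heavy atom within 0.15 nm of a tube atom
#' is rejected and retried with a perturbed azimuth.
#'
#' @param template a [nucleotide_template()].
#' @param tube a tube structure from [build_nanotube()].
#' @param alpha construction helix angle in degrees.
#' @param delta stacking clearance in nm (default 0.33).
#' @param seed integer seed for the azimuth draw.
#' @param max_retry maximum number of perturbed retries on steric overlap.
#' @return a `cnt_structure` fragment holding unit 0, with placement
#'   parameters in its `meta`.
#' @export
place_initial_unit <- function(template, tube, alpha, delta = 0.33, seed = 1L,
                               max_retry = 32L) {
  stopifnot(inherits(template, "nucleotide_template"), inherits(tube, "cnt_structure"))
  R0 <- tube$meta$tube_radius
  if (is.null(R0)) stop("tube structure has no tube_radius metadata")
  R <- R0 + delta
  rng <- make_rng(seed)
  tube_xyz <- atom_coords(tube)
  z_mid <- tube$meta$tube_length / 2
  theta0 <- rng$runif(1, 0, 2 * pi)
  for (try in seq_len(max_retry)) {
    glob <- place_template(template, alpha, R, theta0, z0 = z_mid)
    heavy <- template$atoms$element != "H"
    d2min <- min_cross_dist2(glob[heavy, , drop = FALSE], tube_xyz)
    if (sqrt(d2min) >= 0.15) {
      out <- unit_as_structure(template, glob, 0L)
      out$meta <- list(alpha = alpha, R = R, R0 = R0, delta = delta,
                       theta0 = theta0, z0 = z_mid)
      return(out)
    }
    theta0 <- rng$runif(1, 0, 2 * pi)
  }
  stop("could not place initial unit without steric overlap after ",
       max_retry, " retries")
}

min_cross_dist2 <- function(A, B) {
  # smallest squared distance between row sets of two coordinate matrices
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    best <- min(best, min(d2))
  }
  best
}

#' Replicate a placed unit along the wrapping helix
#'
#' Unit `n` is the replica of the initial unit shifted along the axis by
#' `n dz` with `dz = L sin(alpha)` and rotated about the axis through the
#' accumulated helix angle `n dz / (R tan(alpha))` (the rotation applied
#' through the standard 2x2 rotation matrix in the x-y plane). For
#' heterogeneous sequences each unit's base is taken from the template of
#' its sequence letter, placed in the identical local backbone frame before
#' replication.
#'
#' @param unit0 output of [place_initial_unit()].
#' @param config a [wrap_config()].
#' @param n_bases number of units; defaults to the config sequence length.
#' @param templates optional named list of [nucleotide_template()] objects
#'   (defaults to the four standard templates).
#' @param tube_length optional tube length in nm; when supplied, a strand
#'   whose axial extent exceeds it is rejected.
#' @return a `cnt_structure` holding the full strand.
#' @export
replicate_helix <- function(unit0, config, n_bases = length(config$bases),
                            templates = NULL, tube_length = NULL) {
  stopifnot(inherits(unit0, "cnt_structure"), inherits(config, "wrap_config"))
  alpha <- unit0$meta$alpha * pi / 180
  R <- unit0$meta$R
  L <- config$L
  dz <- L * sin(alpha)
  if (!is.null(tube_length) && (n_bases - 1) * dz > tube_length) {
    stop("strand axial extent ", round((n_bases - 1) * dz, 2),
         " nm exceeds tube length ", round(tube_length, 2), " nm")
  }
  if (is.null(templates)) {
    templates <- lapply(stats::setNames(nm = unique(config$bases)), nucleotide_template)
  }
  placed <- lapply(templates, function(tpl) {
    place_template(tpl, unit0$meta$alpha, R, unit0$meta$theta0, z0 = unit0$meta$z0)
  })
  units <- vector("list", n_bases)
  for (n in seq_len(n_bases) - 1L) {
    b <- config$bases[n + 1L]
    g <- placed[[b]]
    phi <- n * dz / (R * tan(alpha))
    rot <- cbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
    xy <- g[, 1:2] %*% t(rot)
    gn <- cbind(xy, g[, 3] + n * dz)
    colnames(gn) <- c("x", "y", "z")
    # combine_structures renumbers units contiguously in order
    units[[n + 1L]] <- unit_as_structure(templates[[b]], gn, 0L)
  }
  strand <- do.call(combine_structures, units)
  # As-constructed distances across each junction become the rest lengths of
  # the inter-unit bonds, so a freshly built helix is strain-free. The
  # junction is modelled by the O3'-P bond plus two 1-3 distance restraints
  # (C3'-P and O3'-O5') that carry the bond-angle stiffness of the
  # phosphodiester linkage.
  links <- NULL
  if (n_bases > 1) {
    a <- strand$atoms
    pair_names <- link_pair_names()
    rows <- list()
    for (n in seq_len(n_bases - 1) - 1L) {
      for (p in seq_len(nrow(pair_names))) {
        ia <- which(a$unit == n & a$name == pair_names$tail[p])
        ib <- which(a$unit == n + 1L & a$name == pair_names$head[p])
        rows[[length(rows) + 1L]] <- data.frame(
          unit = n, tail = pair_names$tail[p], head = pair_names$head[p],
          kind = pair_names$kind[p],
          rest = sqrt((a$x[ib] - a$x[ia])^2 + (a$y[ib] - a$y[ia])^2 +
                      (a$z[ib] - a$z[ia])^2))
      }
    }
    links <- do.call(rbind, rows)
  }
  strand$meta <- utils::modifyList(unit0$meta, list(
    L = L, dz = dz, n_bases = n_bases, links = links,
    sequence = paste(config$bases[seq_len(n_bases)], collapse = "")
  ))
  strand
}

# inter-unit junction restraints: the covalent O3'-P bond and the two 1-3
# pairs that encode the bond angles at the phosphodiester linkage
link_pair_names <- function() {
  data.frame(tail = c("O3'", "C3'", "O3'"),
             head = c("P", "P", "O5'"),
             kind = c("bond", "angle", "angle"),
             stringsAsFactors = FALSE)
}

#' Generate initial hybrid configurations over an angle grid
#'
#' Builds one CNT-DNA hybrid per construction angle, with the strand centred
#' along the tube so that it stays clear of the open ends. Angles at which
#' the strand would overrun the tube (axial extent closer than `edge_margin`
#' to either edge) are skipped with a warning. Deterministic for a given
#' seed.
#'
#' @param sequence DNA sequence string.
#' @param tube a tube structure from [build_nanotube()].
#' @param angle_grid construction angles in degrees (default 10 to 80 in
#'   steps of 10).
#' @param delta,L,seed,fixed_ends see [wrap_config()].
#' @param edge_margin minimum clearance in nm between the strand and each
#'   tube edge (default 0.15).
#' @return named list of hybrid `cnt_structure` objects (names `"a<angle>"`),
#'   each carrying its construction parameters in `meta`.
#' @export
generate_initial_configs <- function(sequence, tube,
                                     angle_grid = seq(10, 80, by = 10),
                                     delta = 0.33, L = 0.50, seed = 1L,
                                     fixed_ends = TRUE, edge_margin = 0.15) {
  stopifnot(inherits(tube, "cnt_structure"))
  if (length(angle_grid) < 1) stop("angle_grid must be non-empty")
  if (any(angle_grid <= 0 | angle_grid >= 90)) {
    stop("angle_grid must lie strictly inside (0, 90) degrees")
  }
  tube_len <- tube$meta$tube_length
  templates <- lapply(stats::setNames(nm = c("A", "C", "G", "T")), nucleotide_template)
  out <- list()
  for (alpha in angle_grid) {
    config <- wrap_config(sequence, alpha, R0 = tube$meta$tube_radius,
                          delta = delta, L = L, fixed_ends = fixed_ends, seed = seed)
    unit0 <- place_initial_unit(templates[[config$bases[1]]], tube, alpha,
                                delta = delta, seed = seed)
    strand <- replicate_helix(unit0, config, templates = templates)
    zr <- range(strand$atoms$z)
    if (diff(zr) > tube_len - 2 * edge_margin) {
      warning(sprintf("angle %g deg skipped: strand extent %.2f nm does not fit tube length %.2f nm with %.2f nm edge margin",
                      alpha, diff(zr), tube_len, edge_margin))
      next
    }
    # centre the strand along the tube
    shift <- (tube_len - diff(zr)) / 2 - zr[1]
    xyz <- atom_coords(strand)
    xyz[, 3] <- xyz[, 3] + shift
    atom_coords(strand) <- xyz
    hybrid <- combine_structures(tube, strand)
    hybrid$meta <- utils::modifyList(hybrid$meta, list(
      alpha_construction = alpha, alpha_from_axis = 90 - alpha,
      delta = delta, L = L, sequence = sequence, seed = seed,
      fixed_ends = fixed_ends, helix_radius = config$R
    ))
    out[[paste0("a", alpha)]] <- hybrid
  }
  if (length(out) == 0) stop("no feasible angles in angle_grid")
  out
}

# small counter-based RNG wrapper so package randomness never touches the
# global .Random.seed
make_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  run <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    runif = function(n, min = 0, max = 1) run(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(stats::rnorm(n, mean, sd))
  )
}
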