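#' @useDynLib cntdna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Conversion constant: kcal/mol per eV
#' @format single numeric value, 23.0605.
#' @export
KCAL_PER_EV <- 23.0605

# Per-element Lennard-Jones parameters (well depth kcal/mol, size sigma nm),
# a standard sp2-carbon / organic-element set of the CHARMM family.
default_lj_table <- function() {
  data.frame(
    element = c("C", "N", "O", "P", "H"),
    eps = c(0.070, 0.170, 0.120, 0.585, 0.022),
    sigma = c(0.355, 0.325, 0.302, 0.383, 0.245),
    stringsAsFactors = FALSE
  )
}

#' Simplified force-field parameters
#'
#' The potential used throughout the package: pairwise Lennard-Jones
#' interactions (geometric-mean well depths, arithmetic-mean sizes) between
#' atoms of different groups, stiff harmonic distance restraints that hold
#' each nucleotide unit near its idealized template geometry, and a harmonic
#' head-tail (O3'-P) bond linking consecutive units. Optional point charges
#' (default zero: neutralized phosphates in vacuo; binding is attributed to
#' pi-stacking dispersion). A single global well-depth scale factor
#' calibrates the energy scale once against single-base adsorption and is
#' then frozen for all experiments (see the methods vignette).
#'
#' @param lj data.frame with columns `element`, `eps` (kcal/mol), `sigma`
#'   (nm).
#' @param scale global multiplier on all well depths (calibrated default).
#' @param cutoff non-bonded cutoff in nm; a switching function is applied
#'   between `r_on` and `cutoff`. Use `Inf` for no cutoff.
#' @param r_on switching onset in nm.
#' @param k_intra intra-unit restraint constant, kcal/mol/A^2.
#' @param k_link inter-unit O3'-P bond constant, kcal/mol/A^2.
#' @param k_angle constant of the two 1-3 distance restraints across each
#'   junction (C3'-P and O3'-O5'), which carry the bond-angle stiffness of
#'   the phosphodiester linkage, kcal/mol/A^2.
#' @param use_charges logical; enable the optional Coulomb term (default
#'   FALSE: neutralized phosphates in vacuo, binding attributed to
#'   pi-stacking dispersion).
#' @param charge_set named numeric vector of point charges (e) assigned by
#'   atom name to DNA atoms when `use_charges = TRUE`; the default places a
#'   net -1 e on each phosphodiester group. The tube is neutral, so the
#'   CNT-DNA term remains purely dispersive either way.
#' @param tol convergence tolerance on the gradient infinity norm,
#'   kcal/(A mol).
#' @param max_iter default iteration cap for [minimize()].
#' @return list of class `ff_params`.
#' @export
ff_params <- function(lj = default_lj_table(), scale = 1.3, cutoff = 1.2,
                      r_on = 1.0, k_intra = 40, k_link = 300, k_angle = 250,
                      use_charges = FALSE,
                      charge_set = c("P" = 1.1, "O1P" = -0.8, "O2P" = -0.8,
                                     "O5'" = -0.25, "O3'" = -0.25),
                      tol = 0.001, max_iter = 5000L) {
  stopifnot(all(c("element", "eps", "sigma") %in% names(lj)))
  if (any(lj$eps < 0)) stop("well depths must be >= 0")
  if (is.finite(cutoff) && cutoff <= max(lj$sigma)) {
    stop("cutoff must exceed the largest LJ size")
  }
  if (is.finite(cutoff) && r_on >= cutoff) stop("r_on must be smaller than cutoff")
  structure(list(lj = lj, scale = scale, cutoff = cutoff, r_on = r_on,
                 k_intra = k_intra, k_link = k_link, k_angle = k_angle,
                 use_charges = isTRUE(use_charges), charge_set = charge_set,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "ff_params")
}

#' Read force-field parameters from a JSON config file
#' @param path JSON file with any subset of the [ff_params()] fields
#'   (`lj` as a record of element/eps/sigma arrays).
#' @return an `ff_params` object.
#' @export
read_ff_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  args <- list()
  for (f in c("scale", "cutoff", "r_on", "k_intra", "k_link", "k_angle",
              "use_charges", "tol", "max_iter")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  if (!is.null(cfg$lj)) args$lj <- as.data.frame(cfg$lj)
  do.call(ff_params, args)
}

# per-atom point charges from the parameter charge set (DNA atoms by name;
# the tube and unlisted atoms are neutral)
atom_charges <- function(a, params) {
  q <- numeric(nrow(a))
  if (isTRUE(params$use_charges) && length(params$charge_set) > 0) {
    idx <- match(a$name, names(params$charge_set))
    hit <- !is.na(idx) & a$role == "DNA"
    q[hit] <- unname(params$charge_set[idx[hit]])
  }
  q
}

# per-atom LJ parameter lookup
atom_lj <- function(elements, params) {
  idx <- match(elements, params$lj$element)
  if (anyNA(idx)) {
    stop("unknown element(s): ", paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  list(eps = params$lj$eps[idx], sigma = params$lj$sigma[idx])
}

# Build the bonded topology of a structure: intra-unit distance restraints to
# the template geometry of each unit's base, and inter-unit O3'-P link bonds
# with rest length taken from the straight template layout at step L.
build_topology <- function(structure, params) {
  a <- structure$atoms
  is_dna <- a$role == "DNA"
  pi <- integer(0); pj <- integer(0); r0 <- numeric(0); kk <- numeric(0)
  excl_i <- integer(0); excl_j <- integer(0)
  if (any(is_dna)) {
    units <- sort(unique(a$unit[is_dna]))
    tpl_cache <- list()
    get_tpl <- function(b) {
      if (is.null(tpl_cache[[b]])) tpl_cache[[b]] <<- nucleotide_template(b)
      tpl_cache[[b]]
    }
    k_intra_nm <- params$k_intra * 100  # kcal/mol/A^2 -> kcal/mol/nm^2
    k_link_nm <- params$k_link * 100
    k_angle_nm <- params$k_angle * 100
    L <- structure$meta$L
    if (is.null(L)) L <- 0.50
    idx_of <- vector("list", length(units))
    for (u in units) {
      rows <- which(is_dna & a$unit == u)
      idx_of[[u + 1L]] <- rows
      # units without a base label (bare atom groups in tests / ad-hoc
      # structures) carry no template topology
      if (is.na(a$base[rows[1]])) next
      tpl <- get_tpl(a$base[rows[1]])
      # match template atoms by name
      m <- match(a$name[rows], tpl$atoms$name)
      if (anyNA(m)) stop("unit ", u, " atoms do not match template ", a$base[rows[1]])
      loc <- as.matrix(tpl$atoms[m, c("x", "y", "z")])
      np <- length(rows)
      cmb <- utils::combn(np, 2)
      d0 <- sqrt(rowSums((loc[cmb[1, ], , drop = FALSE] - loc[cmb[2, ], , drop = FALSE])^2))
      pi <- c(pi, rows[cmb[1, ]]); pj <- c(pj, rows[cmb[2, ]])
      r0 <- c(r0, d0); kk <- c(kk, rep(k_intra_nm, length(d0)))
    }
    if (length(units) > 1) {
      links <- structure$meta$links
      pair_names <- link_pair_names()
      for (u in units[-length(units)]) {
        rows_a <- idx_of[[u + 1L]]; rows_b <- idx_of[[u + 2L]]
        if (is.na(a$base[rows_a[1]]) || is.na(a$base[rows_b[1]])) next
        for (p in seq_len(nrow(pair_names))) {
          ia <- rows_a[a$name[rows_a] == pair_names$tail[p]]
          ib <- rows_b[a$name[rows_b] == pair_names$head[p]]
          hit <- if (!is.null(links)) {
            which(links$unit == u & links$tail == pair_names$tail[p] &
                  links$head == pair_names$head[p])
          } else integer(0)
          if (length(hit) == 1) {
            # rest length recorded by the helix construction (strain-free
            # initial strand)
            rest <- links$rest[hit]
          } else {
            tpl_a <- get_tpl(a$base[rows_a[1]]); tpl_b <- get_tpl(a$base[rows_b[1]])
            tail_loc <- unlist(tpl_a$atoms[tpl_a$atoms$name == pair_names$tail[p],
                                           c("x", "y", "z")])
            head_loc <- unlist(tpl_b$atoms[tpl_b$atoms$name == pair_names$head[p],
                                           c("x", "y", "z")])
            rest <- sqrt(sum((head_loc + c(L, 0, 0) - tail_loc)^2))
          }
          kp <- if (pair_names$kind[p] == "bond") k_link_nm else k_angle_nm
          pi <- c(pi, ia); pj <- c(pj, ib)
          r0 <- c(r0, rest); kk <- c(kk, kp)
          excl_i <- c(excl_i, ia); excl_j <- c(excl_j, ib)
        }
      }
    }
  }
  list(pi = pi - 1L, pj = pj - 1L, r0 = r0, k = kk,
       excl_i = excl_i - 1L, excl_j = excl_j - 1L)
}

# raw energy + gradient evaluation shared by total_energy and minimize;
# `pairs` (from .nb_pairs) switches to the Verlet-list fast path
eval_ff <- function(coords, a, lj, topo, params, want_grad = FALSE,
                    charges = NULL, pairs = NULL) {
  group <- ifelse(a$role == "CNT", -1L, as.integer(a$unit))
  if (is.null(charges)) charges <- numeric(nrow(a))
  nb <- if (is.null(pairs)) {
    .nb_energy(coords, group, lj$eps, lj$sigma, charges,
               params$scale, params$cutoff, params$r_on,
               topo$excl_i, topo$excl_j, want_grad)
  } else {
    .nb_energy_pairs(coords, group, lj$eps, lj$sigma, charges,
                     params$scale, params$cutoff, params$r_on,
                     pairs$i, pairs$j, want_grad)
  }
  rs <- .restraint_energy(coords, topo$pi, topo$pj, topo$r0, topo$k, want_grad)
  out <- list(cnt_dna = nb$cnt_dna, dna_dna = nb$dna_dna, bonded = rs$energy,
              total = nb$cnt_dna + nb$dna_dna + rs$energy)
  if (want_grad) out$grad <- nb$grad + rs$grad
  out
}
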