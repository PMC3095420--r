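#' Atomistic structure container
#'
#' A `cnt_structure` holds a typed atom table in a shared cylindrical frame:
#' the tube axis is the z axis and passes through the origin, coordinates are
#' in nanometres. Atoms are partitioned into groups by the `role` / `unit`
#' columns: carbon-nanotube atoms carry `role = "CNT"` and `unit = NA`; DNA
#' atoms carry `role = "DNA"` and a 0-based contiguous nucleotide index in
#' `unit`.
#'
#' @param atoms data.frame with columns `element` (symbol), `name` (atom
#'   name), `x`, `y`, `z` (nm), `role` ("CNT" or "DNA"), `unit` (integer or
#'   NA), `base` (A/C/G/T or NA), `frozen` (logical).
#' @param meta named list of frame metadata (tube spec, radii, lengths, ...).
#' @return An object of class `cnt_structure`.
#' @export
new_structure <- function(atoms, meta = list()) {
  required <- c("element", "name", "x", "y", "z", "role", "unit", "base", "frozen")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) || any(!is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  units <- sort(unique(atoms$unit[atoms$role == "DNA"]))
  if (length(units) > 0 && !identical(as.integer(units), seq(0L, length(units) - 1L))) {
    stop("DNA nucleotide indices must be contiguous from 0")
  }
  structure(list(atoms = atoms, meta = meta), class = "cnt_structure")
}

#' @export
print.cnt_structure <- function(x, ...) {
  n_cnt <- sum(x$atoms$role == "CNT")
  n_dna <- sum(x$atoms$role == "DNA")
  n_units <- length(unique(x$atoms$unit[x$atoms$role == "DNA"]))
  cat(sprintf("<cnt_structure: %d atoms (%d CNT, %d DNA in %d nucleotides)>\n",
              nrow(x$atoms), n_cnt, n_dna, n_units))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x a `cnt_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Extract the coordinate matrix (nm)
#' @param x a `cnt_structure`.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
atom_coords <- function(x) {
  as.matrix(x$atoms[, c("x", "y", "z")])
}

#' Replace the coordinate matrix
#' @param x a `cnt_structure`.
#' @param value numeric matrix, same shape as `atom_coords(x)`.
#' @return the modified structure.
#' @export
`atom_coords<-` <- function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x$atoms), ncol(value) == 3)
  x$atoms$x <- value[, 1]
  x$atoms$y <- value[, 2]
  x$atoms$z <- value[, 3]
  x
}

#' Concatenate structures into one frame
#'
#' DNA nucleotide indices are re-numbered to stay contiguous from 0 in the
#' order the structures are given. Metadata lists are merged left to right.
#'
#' @param ... `cnt_structure` objects.
#' @return a single `cnt_structure`.
#' @export
combine_structures <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1)
  offset <- 0L
  tabs <- lapply(parts, function(p) {
    a <- p$atoms
    is_dna <- a$role == "DNA"
    if (any(is_dna)) {
      k <- length(unique(a$unit[is_dna]))
      a$unit[is_dna] <- a$unit[is_dna] + offset
      offset <<- offset + k
    }
    a
  })
  meta <- Reduce(utils::modifyList, lapply(parts, function(p) p$meta))
  new_structure(do.call(rbind, tabs), meta)
}

#' Cylindrical radius of every atom
#' @param x a `cnt_structure` (or coordinate matrix).
#' @return numeric vector of radial distances from the z axis (nm).
#' @export
radial_distance <- function(x) {
  xy <- if (inherits(x, "cnt_structure")) atom_coords(x)[, 1:2, drop = FALSE] else x[, 1:2, drop = FALSE]
  sqrt(xy[, 1]^2 + xy[, 2]^2)
}

#' Subset the DNA atoms of one nucleotide
#' @param x a `cnt_structure`.
#' @param unit 0-based nucleotide index.
#' @return data.frame of the unit's atom records.
#' @export
nucleotide_atoms <- function(x, unit) {
  x$atoms[x$atoms$role == "DNA" & x$atoms$unit == unit, , drop = FALSE]
}

#' Write a structure as an XYZ file
#'
#' Coordinates are converted from nm to Angstrom on output, following the
#' usual XYZ convention.
#'
#' @param x a `cnt_structure`.
#' @param path output file path.
#' @param comment second-line comment.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, comment = "cntdna structure") {
  a <- x$atoms
  lines <- c(
    as.character(nrow(a)),
    comment,
    sprintf("%-2s %12.6f %12.6f %12.6f", a$element, a$x * 10, a$y * 10, a$z * 10)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a structure as a PDB file
#'
#' CNT atoms are emitted as chain A, residue `CNT`; DNA nucleotides as chain B
#' with standard residue names `DA`/`DC`/`DG`/`DT` and one residue per
#' nucleotide. Coordinates are converted from nm to Angstrom.
#'
#' @param x a `cnt_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  a <- x$atoms
  res_name <- ifelse(a$role == "CNT", "CNT",
                     paste0("D", ifelse(is.na(a$base), "N", a$base)))
  chain <- ifelse(a$role == "CNT", "A", "B")
  res_seq <- ifelse(a$role == "CNT", 1L, as.integer(a$unit) + 1L)
  # PDB atom names occupy columns 13-16; element right-justified in 77-78
  lines <- sprintf(
    "ATOM  %5d %-4s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000L,
    substr(a$name, 1, 4), substr(res_name, 1, 3), chain, res_seq %% 10000L,
    a$x * 10, a$y * 10, a$z * 10, 1, 0, a$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
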