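#' STM tip model
#'
#' Geometry of the scanning tip used for topography convolution: either a
#' sphere of the apex radius, or a cone with a spherical apex (the default
#' shape of etched STM tips). Apparent widths in constant-current STM images
#' are broadened by morphological dilation with this shape.
#'
#' @param shape `"cone"` (cone with spherical apex) or `"sphere"`.
#' @param apex_radius apex radius of curvature in nm.
#' @param half_angle cone half-angle in degrees (ignored for `"sphere"`).
#' @return list of class `tip_model`.
#' @export
tip_model <- function(shape = c("cone", "sphere"), apex_radius = 2,
                      half_angle = 30) {
  shape <- match.arg(shape)
  if (apex_radius <= 0) stop("apex radius must be positive")
  if (shape == "cone" && !(half_angle > 0 && half_angle < 90)) {
    stop("cone half-angle must lie in (0, 90) degrees")
  }
  structure(list(shape = shape, apex_radius = apex_radius,
                 half_angle = half_angle), class = "tip_model")
}

# depth of the inverted tip surface below the apex at lateral offset s (nm)
tip_depth <- function(tip, s) {
  Rt <- tip$apex_radius
  if (tip$shape == "sphere") {
    d <- ifelse(s <= Rt, Rt - sqrt(pmax(Rt^2 - s^2, 0)), Inf)
  } else {
    th <- tip$half_angle * pi / 180
    s_t <- Rt * cos(th)               # sphere-cone tangency offset
    d_sphere <- Rt - sqrt(pmax(Rt^2 - pmin(s, s_t)^2, 0))
    d <- ifelse(s <= s_t, d_sphere,
                (Rt - Rt * sin(th)) + (s - s_t) / tan(th))
  }
  d
}

#' Topography container
#'
#' @param height numeric matrix of heights in nm (rows = y, columns = x).
#' @param pixel pixel size in nm.
#' @param meta optional list of ground-truth metadata for synthetic renders
#'   (`true_pitch`, `true_angle_from_axis`, `axis_angle`, ...).
#' @return list of class `topography`.
#' @export
topography <- function(height, pixel, meta = list()) {
  if (!is.matrix(height) || any(!is.finite(height))) {
    stop("height must be a finite numeric matrix")
  }
  if (pixel <= 0) stop("pixel size must be positive")
  structure(list(height = height, pixel = pixel, meta = meta),
            class = "topography")
}

#' @export
print.topography <- function(x, ...) {
  cat(sprintf("<topography: %d x %d px at %.3g nm/px (%.1f x %.1f nm), height %.2f-%.2f nm>\n",
              nrow(x$height), ncol(x$height), x$pixel,
              ncol(x$height) * x$pixel, nrow(x$height) * x$pixel,
              min(x$height), max(x$height)))
  invisible(x)
}

#' Parametric helix-on-tube description for rendering
#'
#' @param tube_radius tube radius in nm.
#' @param backbone_radius radial distance of the strand centre line from the
#'   tube axis in nm (default 1.05, the effective value that reconciles a
#'   63.4 degree from-axis wrapping angle with a 3.3 nm coiling period).
#' @param pitch coiling period in nm per turn; alternatively give
#'   `angle_from_axis` and the pitch is `2 pi R tan(90 - angle)`.
#' @param angle_from_axis strand angle from the tube axis in degrees
#'   (used when `pitch` is missing).
#' @param n_coils number of full turns rendered.
#' @param strand_radius radius of the swept strand tube in nm.
#' @param axis_angle orientation of the tube axis in the image plane,
#'   degrees from the image x direction.
#' @param phase start phase of the helix in radians: 0 (default) starts the
#'   strand on the tube crest, so an n-coil render crosses the visible
#'   crest n + 1 times; `pi` starts it on the underside, giving n crest
#'   crossings.
#' @return list of class `helix_param`.
#' @export
helix_param <- function(tube_radius, backbone_radius = 1.05, pitch = NULL,
                        angle_from_axis = NULL, n_coils = 3,
                        strand_radius = 0.30, axis_angle = 0, phase = 0) {
  if (is.null(pitch)) {
    if (is.null(angle_from_axis)) stop("give either pitch or angle_from_axis")
    pitch <- 2 * pi * backbone_radius * tan((90 - angle_from_axis) * pi / 180)
  }
  if (pitch <= 0) stop("pitch must be positive")
  if (tube_radius <= 0 || backbone_radius <= 0 || strand_radius <= 0) {
    stop("radii must be positive")
  }
  angle <- atan2(2 * pi * backbone_radius, pitch) * 180 / pi
  structure(list(tube_radius = tube_radius, backbone_radius = backbone_radius,
                 pitch = pitch, angle_from_axis = angle, n_coils = n_coils,
                 strand_radius = strand_radius, axis_angle = axis_angle,
                 phase = phase),
            class = "helix_param")
}

#' Render a pre-tip topography
#'
#' Computes the height field seen before tip convolution as the upper
#' envelope of the substrate plane, the tube cylinder resting on it, and the
#' DNA strand (a swept tube of `strand_radius` along the parametric helix,
#' or the union of atom spheres for an atomistic hybrid). Parametric renders
#' record their ground truth (pitch, strand angle, axis direction) in the
#' topography metadata.
#'
#' @param x a [helix_param()] or an atomistic hybrid `cnt_structure`.
#' @param size image extent in nm, length-2 `c(x, y)` (default `c(21, 21)`).
#' @param pixel pixel size in nm (default 0.05; a warning is issued above
#'   0.1).
#' @param ... passed between methods.
#' @return a [topography()].
#' @export
render_surface <- function(x, size = c(21, 21), pixel = 0.05, ...) {
  UseMethod("render_surface")
}

render_grid <- function(size, pixel) {
  nx <- round(size[1] / pixel); ny <- round(size[2] / pixel)
  list(nx = nx, ny = ny,
       xs = (seq_len(nx) - 0.5) * pixel, ys = (seq_len(ny) - 0.5) * pixel)
}

# paint spheres (centres cx, cy nm; top height cz + sqrt(r^2 - d^2)) into a
# height matrix
paint_spheres <- function(h, grid, cx, cy, cz, r) {
  px <- grid$xs[2] - grid$xs[1]
  for (k in seq_along(cx)) {
    i0 <- max(1L, floor((cy[k] - r[k]) / px)); i1 <- min(grid$ny, ceiling((cy[k] + r[k]) / px))
    j0 <- max(1L, floor((cx[k] - r[k]) / px)); j1 <- min(grid$nx, ceiling((cx[k] + r[k]) / px))
    if (i0 > i1 || j0 > j1) next
    dy2 <- (grid$ys[i0:i1] - cy[k])^2
    dx2 <- (grid$xs[j0:j1] - cx[k])^2
    d2 <- outer(dy2, dx2, "+")
    cap <- cz[k] + sqrt(pmax(r[k]^2 - d2, 0))
    cap[d2 > r[k]^2] <- -Inf
    blk <- h[i0:i1, j0:j1]
    h[i0:i1, j0:j1] <- pmax(blk, cap)
  }
  h
}

#' @rdname render_surface
#' @export
render_surface.helix_param <- function(x, size = c(21, 21), pixel = 0.05, ...) {
  if (pixel > 0.1) warning("pixel size above 0.1 nm is too coarse for ridge analysis")
  g <- render_grid(size, pixel)
  span <- x$n_coils * x$pitch
  along_max <- sqrt(sum(size^2))  # worst case, checked precisely below
  ax <- x$axis_angle * pi / 180
  u <- c(cos(ax), sin(ax)); v <- c(-sin(ax), cos(ax))
  ext_along <- abs(size[1] * u[1]) + abs(size[2] * u[2])
  if (span > ext_along) {
    stop(sprintf("image extent %.1f nm along the axis cannot hold %g coils of pitch %.2f nm",
                 ext_along, x$n_coils, x$pitch))
  }
  c0 <- size / 2
  # tube cylinder resting on the substrate
  X <- matrix(g$xs, g$ny, g$nx, byrow = TRUE)
  Y <- matrix(g$ys, g$ny, g$nx)
  dperp <- (X - c0[1]) * v[1] + (Y - c0[2]) * v[2]
  r0 <- x$tube_radius
  h <- matrix(0, g$ny, g$nx)
  inside <- abs(dperp) < r0
  h[inside] <- r0 + sqrt(r0^2 - dperp[inside]^2)
  # swept strand
  arc_step <- 0.02
  dt <- arc_step / sqrt((x$pitch / (2 * pi))^2 + x$backbone_radius^2)
  t <- seq(0, 2 * pi * x$n_coils, by = dt)
  a <- (t - max(t) / 2) * x$pitch / (2 * pi)
  ph <- if (is.null(x$phase)) 0 else x$phase
  lat <- x$backbone_radius * sin(t + ph)
  cz <- r0 + x$backbone_radius * cos(t + ph)
  cx <- c0[1] + a * u[1] + lat * v[1]
  cy <- c0[2] + a * u[2] + lat * v[2]
  h <- paint_spheres(h, g, cx, cy, cz, rep(x$strand_radius, length(t)))
  h <- pmax(h, 0)
  topography(h, pixel, meta = list(
    synthetic = TRUE, true_pitch = x$pitch,
    true_angle_from_axis = x$angle_from_axis, axis_angle = x$axis_angle,
    tube_radius = x$tube_radius, backbone_radius = x$backbone_radius,
    n_coils = x$n_coils
  ))
}

# van der Waals radii (nm) for rendering atoms as spheres
vdw_radii <- c(C = 0.170, N = 0.155, O = 0.152, P = 0.180, H = 0.120)

#' @rdname render_surface
#' @param axis_angle orientation of the tube axis in the image plane
#'   (degrees, atomistic method).
#' @export
render_surface.cnt_structure <- function(x, size = c(21, 21), pixel = 0.05,
                                         axis_angle = 0, ...) {
  if (pixel > 0.1) warning("pixel size above 0.1 nm is too coarse for ridge analysis")
  g <- render_grid(size, pixel)
  r0 <- x$meta$tube_radius
  if (is.null(r0)) r0 <- 0
  ax <- axis_angle * pi / 180
  u <- c(cos(ax), sin(ax)); v <- c(-sin(ax), cos(ax))
  xyz <- atom_coords(x)
  # structure frame: tube axis = z; the tube rests on the substrate with a
  # van der Waals contact gap below its lowest atoms
  along <- xyz[, 3] - mean(range(xyz[, 3]))
  latr <- xyz[, 2]
  height <- xyz[, 1] + r0 + vdw_radii[["C"]]
  c0 <- size / 2
  cx <- c0[1] + along * u[1] + latr * v[1]
  cy <- c0[2] + along * u[2] + latr * v[2]
  rv <- unname(vdw_radii[x$atoms$element])
  rv[is.na(rv)] <- 0.15
  h <- matrix(0, g$ny, g$nx)
  h <- paint_spheres(h, g, cx, cy, height, rv)
  h <- pmax(h, 0)
  topography(h, pixel, meta = list(synthetic = TRUE, axis_angle = axis_angle,
                                   tube_radius = r0))
}

#' Tip convolution of a topography
#'
#' Grayscale morphological dilation of the height field by the inverted tip
#' surface, the standard geometric model of constant-current STM imaging of
#' tall objects: the output height at a pixel is the highest position of the
#' tip apex for which no point of the tip touches the sample. Dilation is
#' extensive (output >= input), monotone and translation-equivariant.
#'
#' @param topo a [topography()].
#' @param tip a [tip_model()].
#' @return the dilated [topography()].
#' @export
tip_dilate <- function(topo, tip) {
  stopifnot(inherits(topo, "topography"), inherits(tip, "tip_model"))
  h <- topo$height
  relief <- max(h) - min(h)
  if (relief == 0) return(topo)
  px <- topo$pixel
  # stencil: offsets where the tip depth is within the image relief
  s_max <- if (tip$shape == "sphere") {
    min(tip$apex_radius, sqrt(pmax(2 * tip$apex_radius * relief, 0)))
  } else {
    th <- tip$half_angle * pi / 180
    st <- tip$apex_radius * cos(th)
    d_st <- tip_depth(tip, st)
    if (d_st >= relief) sqrt(pmax(2 * tip$apex_radius * relief, 0))
    else st + (relief - d_st) * tan(th)
  }
  m <- ceiling(s_max / px)
  off <- expand.grid(r = -m:m, c = -m:m)
  s <- px * sqrt(off$r^2 + off$c^2)
  depth <- tip_depth(tip, s)
  keep <- is.finite(depth) & depth <= relief
  out <- .dilate_height(h, as.integer(off$r[keep]), as.integer(off$c[keep]),
                        depth[keep])
  topography(out, topo$pixel, topo$meta)
}

#' Tip-shape deconvolution (surface reconstruction) of a topography
#'
#' Grayscale morphological erosion of the height field by the (inverted) tip
#' surface, the standard first-order reconstruction of a tip-convolved
#' scanning-probe image: it recovers the envelope of the sample surface that
#' is consistent with the measured image and the nominal tip shape.
#' Erosion is the adjoint of [tip_dilate()]; applying it after a dilation
#' restores elongated features (such as DNA coil ridges) that a blunt tip
#' smears into near-circular domes.
#'
#' @param topo a [topography()] (normally a measured / dilated image).
#' @param tip the nominal [tip_model()].
#' @return the reconstructed [topography()].
#' @export
tip_deconvolve <- function(topo, tip) {
  stopifnot(inherits(topo, "topography"), inherits(tip, "tip_model"))
  neg <- topo
  neg$height <- -neg$height
  rec <- tip_dilate(neg, tip)
  rec$height <- -rec$height
  rec
}

#' Add instrument noise to a topography
#'
#' Seeded Gaussian height noise of a given RMS amplitude; `rms = 0` returns
#' the input unchanged.
#'
#' @param topo a [topography()].
#' @param rms noise RMS in nm (default 0.02).
#' @param seed integer seed.
#' @return the noisy [topography()].
#' @export
add_noise <- function(topo, rms = 0.02, seed = 1L) {
  stopifnot(inherits(topo, "topography"))
  if (rms < 0) stop("rms must be >= 0")
  if (rms == 0) return(topo)
  rng <- make_rng(seed)
  h <- topo$height + matrix(rng$rnorm(length(topo$height), sd = rms),
                            nrow(topo$height), ncol(topo$height))
  topography(h, topo$pixel, topo$meta)
}

#' Write / read a topography
#'
#' Text format: comment header lines (`# pixel_nm:`, `# meta:` JSON) followed
#' by the whitespace-separated height matrix. TIFF format: 32-bit float
#' image in nm with a JSON sidecar (`<path>.json`) holding pixel size and
#' metadata.
#'
#' @param topo a [topography()].
#' @param path output path.
#' @param format `"text"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_topography <- function(topo, path, format = c("text", "tiff")) {
  format <- match.arg(format)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# pixel_nm: %.17g", topo$pixel),
                 paste0("# meta: ", jsonlite::toJSON(topo$meta, auto_unbox = TRUE, digits = NA))),
               con)
    utils::write.table(topo$height, con, row.names = FALSE, col.names = FALSE)
  } else {
    # TIFF stores [0,1]; keep the affine map in the sidecar for exact
    # reconstruction in nm
    lo <- min(topo$height); hi <- max(topo$height)
    scale <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((topo$height - lo) / scale, path, bits.per.sample = 32L,
                    reduce = FALSE)
    jsonlite::write_json(list(pixel = topo$pixel, offset = lo, scale = scale,
                              meta = topo$meta),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_topography
#' @export
read_topography <- function(path, format = c("text", "tiff")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    pixel <- as.numeric(sub("# pixel_nm: *", "", hdr[startsWith(hdr, "# pixel_nm:")]))
    meta_line <- hdr[startsWith(hdr, "# meta:")]
    meta <- if (length(meta_line)) jsonlite::fromJSON(sub("# meta: *", "", meta_line)) else list()
    h <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")]))
    dimnames(h) <- NULL
    topography(h, pixel, meta)
  } else {
    h <- tiff::readTIFF(path)
    side <- jsonlite::fromJSON(paste0(path, ".json"))
    topography(h * side$scale + side$offset, side$pixel, as.list(side$meta))
  }
}
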