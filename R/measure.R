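ring_atom_names <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")

base_centroids <- function(structure) {
  a <- structure$atoms
  sel <- a$role == "DNA" & a$name %in% ring_atom_names
  if (!any(sel)) stop("structure contains no DNA base atoms")
  sp <- split(which(sel), a$unit[sel])
  units <- as.integer(names(sp))
  cen <- t(vapply(sp, function(i) c(mean(a$x[i]), mean(a$y[i]), mean(a$z[i])),
                  numeric(3)))
  ord <- order(units)
  list(unit = units[ord], xyz = cen[ord, , drop = FALSE])
}

#' Measure the realized wrapping geometry of a hybrid
#'
#' For each nucleotide the base-ring centroid is expressed in cylindrical
#' coordinates `(r, theta, z)` about the tube axis; the azimuth is unwrapped
#' and the local wrapping angle between consecutive centroids is computed
#' from `tan(angle-from-circumference) = dz / (r_mean * dtheta)`. The
#' coiling period is `2 pi` times the slope of a robust linear fit of `z`
#' against the unwrapped azimuth; it is flagged undefined when the strand
#' sweeps less than a full turn.
#'
#' @param structure a `cnt_structure` with at least 3 nucleotides.
#' @param R0 tube radius in nm used for the surface-clearance column
#'   (default: structure metadata).
#' @param smooth_window odd window (in bases) of the centred moving average
#'   applied to the centroid track before the local-angle differences
#'   (default 3). Optimized bases rock about the strand axis by a few
#'   hundredths of a nm; without smoothing that single-base jitter
#'   dominates the local-angle dispersion and masks the path
#'   inhomogeneity the statistic is meant to capture. Use 1 for the raw
#'   consecutive-centroid estimator.
#' @return list of class `wrap_measurement`: `per_base` (data.frame with the
#'   local angle in both conventions and the centroid clearance),
#'   `mean_angle`, `sd_angle` (from-circumference convention),
#'   `mean_angle_from_axis`, `period` (nm per turn, NA if undefined),
#'   `period_defined`, `sweep` (total unwrapped azimuth, rad), `clearance`
#'   (per-unit base-centroid radius minus `R0`) and `contact_clearance`
#'   (per-unit closest approach of the base ring system to the surface).
#' @export
measure_wrapping <- function(structure, R0 = NULL, smooth_window = 3) {
  bc <- base_centroids(structure)
  n <- nrow(bc$xyz)
  if (n < 3) stop("measure_wrapping requires at least 3 nucleotides")
  if (is.null(R0)) R0 <- structure$meta$tube_radius
  xyz <- bc$xyz
  k <- as.integer(smooth_window)
  if (k > 1 && n > k) {
    sm <- vapply(1:3, function(d) {
      v <- stats::filter(xyz[, d], rep(1 / k, k), sides = 2)
      as.numeric(v)
    }, numeric(n))
    keep <- is.na(sm[, 1])
    sm[keep, ] <- xyz[keep, ]
    xyz <- sm
  }
  # azimuth and height are taken from the smoothed track (symmetric
  # averaging leaves them unbiased on a uniform helix); the radius entering
  # the arc length is taken from the raw centroids, since averaging across
  # a finite azimuth step systematically shrinks it
  r_raw <- sqrt(bc$xyz[, 1]^2 + bc$xyz[, 2]^2)
  r <- r_raw
  theta <- atan2(xyz[, 2], xyz[, 1])
  z <- xyz[, 3]
  dth <- diff(theta)
  dth <- ((dth + pi) %% (2 * pi)) - pi   # wrap increments to (-pi, pi]
  theta_u <- cumsum(c(theta[1], dth))
  dz <- diff(z)
  rbar <- (r[-1] + r[-n]) / 2
  arc <- rbar * diff(theta_u)
  ang <- atan2(abs(dz), abs(arc)) * 180 / pi
  sweep <- abs(theta_u[n] - theta_u[1])
  period <- NA_real_
  period_defined <- FALSE
  if (sweep >= 2 * pi) {
    fit <- tryCatch(MASS::rlm(z ~ theta_u, maxit = 50),
                    error = function(e) stats::lm(z ~ theta_u))
    period <- abs(2 * pi * unname(stats::coef(fit)[2]))
    period_defined <- TRUE
  }
  # stacking contact distance: closest approach of the base ring system to
  # the tube surface (a rolled base keeps pi-contact through its lower edge)
  contact <- rep(NA_real_, n)
  if (!is.null(R0)) {
    a <- structure$atoms
    sel <- a$role == "DNA" & a$name %in% ring_atom_names
    rr <- sqrt(a$x[sel]^2 + a$y[sel]^2)
    contact <- vapply(split(rr, a$unit[sel]), min, numeric(1))[
      as.character(bc$unit)]
  }
  per_base <- data.frame(
    unit = bc$unit[-1],
    angle_from_circumference = ang,
    angle_from_axis = 90 - ang,
    clearance = if (!is.null(R0)) (r_raw[-1] + r_raw[-n]) / 2 - R0 else NA_real_
  )
  structure(list(per_base = per_base,
                 mean_angle = mean(ang), sd_angle = stats::sd(ang),
                 mean_angle_from_axis = 90 - mean(ang),
                 period = period, period_defined = period_defined,
                 sweep = sweep,
                 clearance = if (!is.null(R0)) r_raw - R0 else rep(NA_real_, n),
                 contact_clearance = if (!is.null(R0)) unname(contact) - R0
                                     else rep(NA_real_, n)),
            class = "wrap_measurement")
}

#' @export
print.wrap_measurement <- function(x, ...) {
  cat(sprintf("<wrapping: %.1f +/- %.1f deg from circumference (%.1f deg from axis), period %s>\n",
              x$mean_angle, x$sd_angle, x$mean_angle_from_axis,
              if (x$period_defined) sprintf("%.2f nm", x$period) else "undefined"))
  invisible(x)
}
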