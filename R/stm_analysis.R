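#' Extract a 1-D height profile from a topography
#'
#' Samples the height field by bilinear interpolation along a straight line
#' starting at `anchor` in the direction `orientation`, at a spacing of half
#' the pixel size (or finer). The part of the line outside the image is
#' dropped with a warning.
#'
#' @param topo a [topography()].
#' @param anchor length-2 start point in nm (x, y).
#' @param orientation direction of the section in degrees from the image x
#'   axis.
#' @param length section length in nm.
#' @param spacing sample spacing in nm (default `pixel / 2`).
#' @return list of class `height_profile`: `heights` (nm), `spacing` (nm),
#'   `orientation` (deg), `n`.
#' @export
extract_profile <- function(topo, anchor, orientation, length,
                            spacing = topo$pixel / 2) {
  stopifnot(inherits(topo, "topography"))
  if (spacing > topo$pixel / 2) spacing <- topo$pixel / 2
  th <- orientation * pi / 180
  t <- seq(0, length, by = spacing)
  px <- anchor[1] + t * cos(th)
  py <- anchor[2] + t * sin(th)
  hh <- bilinear_sample(topo, px, py)
  if (anyNA(hh)) {
    warning("section line leaves the image; profile truncated")
    keep <- !is.na(hh)
    # keep the longest contiguous run from the start
    first_bad <- which(!keep)[1]
    hh <- hh[seq_len(first_bad - 1)]
  }
  if (length(hh) < 16) stop("profile has fewer than 16 samples")
  structure(list(heights = hh, spacing = spacing, orientation = orientation,
                 n = length(hh)), class = "height_profile")
}

bilinear_sample <- function(topo, px, py) {
  h <- topo$height; d <- topo$pixel
  nx <- ncol(h); ny <- nrow(h)
  # pixel centres at (j - 0.5) d, (i - 0.5) d
  fx <- px / d + 0.5; fy <- py / d + 0.5
  j0 <- floor(fx); i0 <- floor(fy)
  wx <- fx - j0; wy <- fy - i0
  ok <- j0 >= 1 & j0 + 1 <= nx & i0 >= 1 & i0 + 1 <= ny
  out <- rep(NA_real_, length(px))
  if (any(ok)) {
    i0k <- i0[ok]; j0k <- j0[ok]; wxk <- wx[ok]; wyk <- wy[ok]
    idx <- function(i, j) h[cbind(i, j)]
    out[ok] <- idx(i0k, j0k) * (1 - wxk) * (1 - wyk) +
      idx(i0k, j0k + 1) * wxk * (1 - wyk) +
      idx(i0k + 1, j0k) * (1 - wxk) * wyk +
      idx(i0k + 1, j0k + 1) * wxk * wyk
  }
  out
}

#' Dominant spatial period of a height profile
#'
#' Linear-detrends the profile, computes its discrete Fourier transform with
#' at least 8-fold zero padding, and takes the maximal non-DC spectral
#' magnitude as the modulation peak. The characteristic period is the
#' inverse of the (quadratically interpolated) peak frequency. Uncertainty
#' is reported two ways: the period interval spanned by all frequencies with
#' magnitude at or above 90 percent of the peak, and the zero-level
#' (first-null to first-null) full width of the peak in period units, which
#' for a sine spanning N periods is about `2 lambda / N`.
#'
#' @param profile a [extract_profile()] result (or any list with `heights`
#'   and `spacing`).
#' @param min_cycles smallest number of cycles in the window considered a
#'   real periodicity (default 1.5).
#' @return list of class `period_spectrum`: `freq` (nm^-1), `mag`,
#'   `peak_freq`, `period` (nm), `n_periods`, `band90` (period interval),
#'   `band90_spread`, `zero_width` (nm), `no_periodicity` flag.
#' @export
dominant_period <- function(profile, min_cycles = 1.5) {
  x <- profile$heights
  n0 <- length(x)
  if (n0 < 16) stop("profile too short")
  dx <- profile$spacing
  idx <- seq_len(n0)
  x <- stats::residuals(stats::lm(x ~ idx))
  np <- 2^ceiling(log2(8 * n0))
  sp <- stats::fft(c(x, rep(0, np - n0)))
  k <- seq_len(np %/% 2)          # positive-frequency bins, excluding DC
  freq <- k / (np * dx)
  mag <- Mod(sp[k + 1])
  win_len <- n0 * dx
  search <- which(freq >= min_cycles / win_len)
  if (length(search) == 0) stop("window too short for the requested min_cycles")
  pk <- search[which.max(mag[search])]
  # tie-break identical magnitudes toward the lower frequency
  ties <- search[mag[search] == mag[pk]]
  pk <- min(ties)
  floor_mag <- 1e-9 * (sum(abs(x)) + 1)
  if (mag[pk] <= 3 * stats::median(mag[search]) || mag[pk] <= floor_mag) {
    return(structure(list(freq = freq, mag = mag, peak_freq = NA_real_,
                          period = NA_real_, n_periods = NA_real_,
                          band90 = c(NA_real_, NA_real_),
                          band90_spread = NA_real_, zero_width = NA_real_,
                          no_periodicity = TRUE),
                     class = "period_spectrum"))
  }
  # quadratic interpolation of the peak position
  f_peak <- freq[pk]
  if (pk > 1 && pk < length(mag)) {
    y1 <- mag[pk - 1]; y2 <- mag[pk]; y3 <- mag[pk + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) {
      shift <- 0.5 * (y1 - y3) / den
      f_peak <- freq[pk] + shift * (freq[2] - freq[1])
    }
  }
  period <- 1 / f_peak
  # 90%-of-peak band (contiguous around the peak)
  thr <- 0.9 * mag[pk]
  lo <- pk; while (lo > 1 && mag[lo - 1] >= thr) lo <- lo - 1
  hi <- pk; while (hi < length(mag) && mag[hi + 1] >= thr) hi <- hi + 1
  band90 <- sort(1 / c(freq[hi], freq[lo]))
  # first spectral nulls: walk out of the main lobe until the magnitude
  # stops decreasing (dense zero padding makes the lobe shape smooth)
  null_lo <- pk
  while (null_lo > 1 && mag[null_lo - 1] < mag[null_lo]) null_lo <- null_lo - 1
  null_hi <- pk
  while (null_hi < length(mag) && mag[null_hi + 1] < mag[null_hi]) null_hi <- null_hi + 1
  zero_width <- abs(1 / freq[null_lo] - 1 / freq[null_hi])
  structure(list(freq = freq, mag = mag, peak_freq = f_peak, period = period,
                 n_periods = win_len / period, band90 = band90,
                 band90_spread = diff(band90), zero_width = zero_width,
                 no_periodicity = FALSE),
            class = "period_spectrum")
}

#' @export
print.period_spectrum <- function(x, ...) {
  if (x$no_periodicity) {
    cat("<period spectrum: no periodicity detected>\n")
  } else {
    cat(sprintf("<period %.3f nm over %.1f cycles; 90%%-band [%.3f, %.3f] nm, zero-level width %.3f nm>\n",
                x$period, x$n_periods, x$band90[1], x$band90[2], x$zero_width))
  }
  invisible(x)
}

#' Histogram of characteristic periods across hybrids
#'
#' @param spectra list of [dominant_period()] results.
#' @param bin_width histogram bin width in nm (default 0.3, matching the
#'   measurement spread of a three-coil window).
#' @return list of class `period_histogram`: `breaks`, `counts`,
#'   `modal_period` (bin centre of the maximal count).
#' @export
period_histogram <- function(spectra, bin_width = 0.3) {
  periods <- vapply(spectra, function(s) {
    if (isTRUE(s$no_periodicity)) NA_real_ else s$period
  }, numeric(1))
  periods <- periods[!is.na(periods)]
  if (length(periods) == 0) {
    warning("no spectra with a detected peak; empty histogram")
    return(structure(list(breaks = numeric(0), counts = integer(0),
                          modal_period = NA_real_),
                     class = "period_histogram"))
  }
  lo <- floor(min(periods) / bin_width) * bin_width
  hi <- ceiling(max(periods) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- as.integer(table(cut(periods, breaks, include.lowest = TRUE)))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  structure(list(breaks = breaks, counts = counts,
                 modal_period = mids[which.max(counts)]),
            class = "period_histogram")
}

# principal axis (degrees from image x) of the above-substrate mask
estimate_axis <- function(topo, mask_level = 0.25) {
  h <- topo$height
  thr <- min(h) + mask_level * (max(h) - min(h))
  sel <- which(h > thr, arr.ind = TRUE)
  if (nrow(sel) < 10) stop("no clear above-substrate feature in the image")
  xy <- cbind((sel[, 2] - 0.5) * topo$pixel, (sel[, 1] - 0.5) * topo$pixel)
  cen <- colMeans(xy)
  ev <- eigen(stats::cov(xy))
  u <- ev$vectors[, 1]
  list(angle = atan2(u[2], u[1]) * 180 / pi, center = cen, u = u,
       v = c(-u[2], u[1]))
}

#' Strand orientation relative to the tube axis
#'
#' Estimates the tube-axis direction as the principal axis of the
#' above-substrate mask, resamples a band around the top ridge into
#' axis-aligned coordinates, removes the static cross-tube profile, and
#' locates the dominant wavevector of the remaining coil stripes in the 2-D
#' spectrum. The strand orientation is reported as the stripe direction
#' relative to the tube axis, in degrees.
#'
#' @param topo a [topography()].
#' @param band_halfwidth lateral half-width in nm of the analyzed top-ridge
#'   band (default 0.8).
#' @param tip optional nominal [tip_model()]; when given, the image is first
#'   tip-deconvolved with [tip_deconvolve()], which restores the stripe
#'   slant that a blunt tip smears out near the crest.
#' @return list of class `strand_orientation`: `angle_from_axis` (deg),
#'   `axis_angle` (deg, image frame), `no_periodicity` flag.
#' @export
strand_orientation <- function(topo, band_halfwidth = 0.8, tip = NULL) {
  if (!is.null(tip)) topo <- tip_deconvolve(topo, tip)
  ax <- estimate_axis(topo)
  px <- topo$pixel
  # resample a band around the ridge in axis coordinates
  h <- topo$height
  half_len <- 0.5 * sqrt((ncol(h) * px)^2 + (nrow(h) * px)^2)
  s <- seq(-half_len, half_len, by = px)
  q <- seq(-band_halfwidth, band_halfwidth, by = px)
  S <- outer(s, rep(1, length(q)))
  Q <- outer(rep(1, length(s)), q)
  X <- ax$center[1] + S * ax$u[1] + Q * ax$v[1]
  Y <- ax$center[2] + S * ax$u[2] + Q * ax$v[2]
  patch <- matrix(bilinear_sample(topo, as.numeric(X), as.numeric(Y)),
                  nrow = length(s))
  keep <- rowSums(is.na(patch)) == 0
  patch <- patch[keep, , drop = FALSE]
  if (nrow(patch) < 32) stop("ridge band too short for spectral analysis")
  # remove the static cross-tube profile, then window along the axis
  patch <- sweep(patch, 2, colMeans(patch))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nrow(patch)) - 1) / (nrow(patch) - 1))
  patch <- patch * w
  nps <- 2^ceiling(log2(8 * nrow(patch)))
  pad <- matrix(0, nps, ncol(patch))
  pad[seq_len(nrow(patch)), ] <- patch
  # column-wise axial spectra: F(f_s, q)
  sp <- stats::mvfft(pad)
  ks <- seq_len(nps %/% 2)          # positive axial frequencies, excluding DC
  fs <- ks / (nps * px)
  mag_s <- rowSums(Mod(sp[ks + 1, , drop = FALSE]))
  search <- which(fs >= 1.5 / (nrow(patch) * px))
  pk <- search[which.max(mag_s[search])]
  if (mag_s[pk] <= 3 * stats::median(mag_s[search]) ||
      mag_s[pk] <= 1e-9 * (sum(abs(patch)) + 1)) {
    return(structure(list(angle_from_axis = NA_real_, axis_angle = ax$angle,
                          no_periodicity = TRUE),
                     class = "strand_orientation"))
  }
  f_s <- fs[pk]
  # slanted stripes shift the coil pattern along the axis as the band moves
  # laterally: bumps(s - c q) has column phase -2 pi f_s c q at the spectral
  # ridge, so the phase gradient across the band gives the stripe slope c
  coefs <- sp[pk + 1, ]
  ph <- Arg(coefs)
  ph <- cumsum(c(ph[1], ((diff(ph) + pi) %% (2 * pi)) - pi))  # unwrap
  wgt <- Mod(coefs)
  fit <- stats::lm(ph ~ q, weights = wgt)
  slope <- unname(stats::coef(fit)[2])
  cslope <- -slope / (2 * pi * f_s)   # stripe slope ds/dq
  beta <- atan2(1, abs(cslope)) * 180 / pi
  structure(list(angle_from_axis = beta, axis_angle = ax$angle,
                 peak_freq = f_s, stripe_slope = cslope,
                 no_periodicity = FALSE),
            class = "strand_orientation")
}

#' @export
print.strand_orientation <- function(x, ...) {
  if (isTRUE(x$no_periodicity)) {
    cat("<strand orientation: no ridge periodicity>\n")
  } else {
    cat(sprintf("<strand at %.1f deg from the tube axis (axis at %.1f deg in image)>\n",
                x$angle_from_axis, x$axis_angle))
  }
  invisible(x)
}

#' Longitudinal ridge profile of a tube image
#'
#' Extracts the section along the estimated tube axis through the mask
#' centroid (the analogue of a longitudinal STM section). By default the
#' profile is cropped to the DNA-covered island: the contiguous run of the
#' ridge standing clearly above the bare-tube crest level, which is where
#' the coil modulation lives.
#'
#' @param topo a [topography()].
#' @param length section length in nm (NULL = crop to the modulated island).
#' @param island_frac fraction of the ridge height range above the baseline
#'   used as the island threshold (default 0.25).
#' @return a [extract_profile()] result.
#' @export
ridge_profile <- function(topo, length = NULL, island_frac = 0.25,
                          bridge = 3) {
  ax <- estimate_axis(topo)
  th_deg <- atan2(ax$u[2], ax$u[1]) * 180 / pi
  px <- topo$pixel
  # maximal extent of the axis line inside the image
  lims <- c(ncol(topo$height), nrow(topo$height)) * px
  t_rng <- c(-Inf, Inf)
  for (d in 1:2) {
    if (abs(ax$u[d]) > 1e-12) {
      tt <- sort((c(2 * px, lims[d] - 2 * px) - ax$center[d]) / ax$u[d])
      t_rng <- c(max(t_rng[1], tt[1]), min(t_rng[2], tt[2]))
    }
  }
  ext <- t_rng[2] - t_rng[1]
  if (!is.null(length)) {
    anchor <- ax$center - length / 2 * ax$u
    return(extract_profile(topo, anchor, th_deg, length))
  }
  full <- extract_profile(topo, ax$center + t_rng[1] * ax$u, th_deg, ext)
  h <- full$heights
  # light smoothing so noise does not fragment the island
  ksm <- max(3L, round(0.2 / full$spacing))
  hs <- stats::filter(h, rep(1 / ksm, ksm), sides = 2)
  hs[is.na(hs)] <- h[is.na(hs)]
  thr <- min(hs) + island_frac * (max(hs) - min(hs))
  above <- as.logical(hs > thr)
  # bridge the bare-tube dips between coil crossings (interior gaps shorter
  # than `bridge` nm), so the island spans the whole DNA-covered segment
  r <- rle(above)
  if (length(r$lengths) > 2) {
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    fill <- interior[!r$values[interior] &
                     r$lengths[interior] * full$spacing < bridge]
    r$values[fill] <- TRUE
    above <- inverse.rle(r)
    r <- rle(above)
  }
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (length(runs) == 0) return(full)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  if (i1 - i0 + 1 < 16) return(full)
  structure(list(heights = h[i0:i1], spacing = full$spacing,
                 orientation = full$orientation, n = i1 - i0 + 1),
            class = "height_profile")
}
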