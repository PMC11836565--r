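# Surrogate B0/B1 maps derived from the DMI water signal itself: per-voxel
# water line shift (B0, Hz) and relative water intensity (B1), followed by
# a low-order 2D polynomial fit evaluated at the MRI raster resolution for
# use in the field-augmented encoding.

water_peak <- function(mag, freq, band) {
  in_band <- freq >= band[1] & freq <= band[2]
  if (!any(in_band)) stopf("water band outside the frequency axis")
  ib <- which(in_band)
  p <- ib[which.max(mag[ib])]
  pk <- mag[p]
  # 3-point parabolic interpolation of the peak position
  if (p > 1 && p < length(mag)) {
    a <- mag[p - 1]; b <- mag[p]; c <- mag[p + 1]
    den <- a - 2 * b + c
    delta <- if (abs(den) > 0) 0.5 * (a - c) / den else 0
    delta <- max(min(delta, 0.5), -0.5)
  } else delta <- 0
  list(freq = freq[p] + delta * (freq[2] - freq[1]), height = pk)
}

#' Per-voxel water line-shift map (raw B0 surrogate)
#'
#' Locates the water peak in each voxel's magnitude spectrum within
#' `water_band` by 3-point parabolic interpolation; the offset from the
#' nominal water frequency (0 Hz at carrier) is the voxel's B0 estimate in
#' Hz. Voxels whose water peak is below `snr_floor_frac` times the largest
#' peak are flagged missing (NA).
#'
#' @param spectra a `spatial_spectra` (from [fft_reconstruct()])
#' @param water_band frequency window (Hz) around the nominal water line
#' @param snr_floor_frac relative peak-height floor
#' @return a `field_map` (kind B0) at DMI resolution; missing voxels NA
#' @export
water_shift_map <- function(spectra, water_band = c(-30, 30),
                            snr_floor_frac = 0.05) {
  nd <- spectra$grid_dims
  nv <- prod(nd[1:2])
  sh <- rep(NA_real_, nv)
  ht <- numeric(nv)
  for (v in seq_len(nv)) {
    pk <- water_peak(Mod(voxel_spectrum(spectra, v)), spectra$freq_hz, water_band)
    sh[v] <- pk$freq
    ht[v] <- pk$height
  }
  if (max(ht) <= 0) stopf("no water peak above the floor anywhere")
  sh[ht < snr_floor_frac * max(ht)] <- NA_real_
  field_map(matrix(sh, nd[1], nd[2]), "B0")
}

#' Per-voxel relative water-intensity map (raw B1 surrogate)
#'
#' Integrates the water magnitude over `water_band` per voxel. When an ROI
#' map is supplied, the integral is divided by the voxel's object
#' partial-volume fraction (spatial prior knowledge available to the
#' method) so edge voxels estimate sensitivity per unit object volume;
#' voxels with object fraction below `min_object_frac` are flagged missing.
#' The map is normalized to maximum 1 (relative receive sensitivity).
#'
#' @param spectra a `spatial_spectra`
#' @param water_band frequency window (Hz)
#' @param rois optional `roi_map` for partial-volume correction
#' @param min_object_frac object-fraction floor for valid voxels
#' @return a `field_map` (kind B1), maximum 1, missing voxels NA
#' @export
water_intensity_map <- function(spectra, water_band = c(-30, 30), rois = NULL,
                                min_object_frac = 0.25) {
  nd <- spectra$grid_dims
  nv <- prod(nd[1:2])
  df <- spectra$freq_hz[2] - spectra$freq_hz[1]
  in_band <- spectra$freq_hz >= water_band[1] & spectra$freq_hz <= water_band[2]
  if (!any(in_band)) stopf("water band outside the frequency axis")
  amp <- vapply(seq_len(nv), function(v)
    sum(Mod(voxel_spectrum(spectra, v))[in_band]) * df, 0)
  if (max(amp) <= 0) stopf("no water signal anywhere")
  if (!is.null(rois)) {
    vc <- voxel_classes(rois)
    ok <- vc$frac_object >= min_object_frac
    amp[!ok] <- NA_real_
    amp[ok] <- amp[ok] / vc$frac_object[ok]
  }
  field_map(matrix(amp / max(amp, na.rm = TRUE), nd[1], nd[2]), "B1")
}

#' Fit a low-order polynomial surrogate surface to a raw field map
#'
#' Least-squares 2D polynomial fit to the valid (non-missing) voxels of a
#' DMI-resolution raw map, evaluated at the MRI raster resolution (the
#' parameterization doubles as upsampling for the field-augmented
#' encoding). Rank-deficient designs fall back to a lower order with a
#' warning. Fitted B1 surfaces are floored at a small positive value inside
#' the object so the augmented encoding stays valid where the polynomial
#' undershoots.
#'
#' @param raw a DMI-resolution `field_map` with possible NAs
#' @param order polynomial order (default 3)
#' @param rois `roi_map` defining the target raster and FOV
#' @param b1_floor positive floor applied to fitted B1 values
#' @return a `field_map` on the MRI raster with `coeffs` stored
#' @export
fit_surrogate <- function(raw, order = 3, rois, b1_floor = 0.02) {
  nd <- rois$grid_dims
  if (!all(dim(raw$values) == nd))
    stopf("raw map (%s) is not at the DMI grid resolution (%s)",
          paste(dim(raw$values), collapse = "x"), paste(nd, collapse = "x"))
  vy <- (seq_len(nd[1]) - (nd[1] + 1) / 2) * rois$nominal_voxel_mm[1]
  vx <- (seq_len(nd[2]) - (nd[2] + 1) / 2) * rois$nominal_voxel_mm[2]
  vv <- expand.grid(y = vy, x = vx)
  z <- as.vector(raw$values)
  ok <- is.finite(z)
  for (ord in seq(order, 0)) {
    B <- poly_design(vv$y[ok], vv$x[ok], ord,
                     rois$fov_mm[1] / 2, rois$fov_mm[2] / 2)
    if (sum(ok) < ncol(B)) next
    fit <- stats::lm.fit(B, z[ok])
    if (fit$rank == ncol(B)) {
      if (ord < order)
        warnf("rank-deficient design; polynomial order reduced to %d", ord)
      cf <- fit$coefficients
      co <- pixel_coords(rois)
      d <- dim(rois$labels)
      Bf <- poly_design(rep(co$y, times = d[2]), rep(co$x, each = d[1]), ord,
                        rois$fov_mm[1] / 2, rois$fov_mm[2] / 2)
      vals <- matrix(Bf %*% cf, d[1], d[2])
      if (raw$kind == "B1") vals <- pmax(vals, b1_floor)
      return(field_map(vals, raw$kind, coeffs = cf, order = ord,
                       pixel_mm = rois$pixel_mm))
    }
  }
  stopf("too few valid voxels (%d) for any polynomial fit", sum(ok))
}

#' Estimate surrogate B0 and B1 maps from a DMI dataset
#'
#' Convenience wrapper: FFT reconstruction, water shift and intensity maps,
#' polynomial fits at MRI resolution.
#'
#' @param P a `kspace_data`
#' @param rois the `roi_map` prior
#' @param order polynomial order for both fits
#' @param water_band frequency window (Hz)
#' @return list with `b0`, `b1` (fitted `field_map`s) and the raw maps
#' @export
estimate_surrogate_maps <- function(P, rois, order = 3, water_band = c(-30, 30)) {
  spectra <- fft_reconstruct(P)
  raw_b0 <- water_shift_map(spectra, water_band)
  raw_b1 <- water_intensity_map(spectra, water_band, rois = rois)
  # restrict the B0 fit to voxels with usable object content as well
  raw_b0$values[!is.finite(raw_b1$values)] <- NA_real_
  list(b0 = fit_surrogate(raw_b0, order, rois),
       b1 = fit_surrogate(raw_b1, order, rois),
       raw_b0 = raw_b0, raw_b1 = raw_b1)
}
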