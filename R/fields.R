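# B0 (Hz) and B1 (relative receive sensitivity) field maps: scalar rasters
# parameterized by low-order 2D polynomials.

#' Construct a field map
#'
#' @param values numeric matrix on a raster grid (B0 in Hz, B1 dimensionless)
#' @param kind "B0" or "B1"
#' @param coeffs optional polynomial coefficients (named vector) that
#'   generated/parameterize the surface
#' @param order polynomial order of `coeffs`
#' @param pixel_mm raster pixel size (mm)
#' @return object of class `field_map`
#' @export
field_map <- function(values, kind = c("B0", "B1"), coeffs = NULL,
                      order = NULL, pixel_mm = NULL) {
  kind <- match.arg(kind)
  structure(list(values = as.matrix(values), kind = kind, coeffs = coeffs,
                 order = order, pixel_mm = pixel_mm),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<field_map %s> %dx%d raster, range [%.3g, %.3g]%s\n",
              x$kind, nrow(x$values), ncol(x$values), min(v), max(v),
              if (x$kind == "B0") " Hz" else ""))
  invisible(x)
}

# 2D polynomial design matrix: all monomials x^i * y^j with i + j <= order,
# on coordinates normalized to roughly [-1, 1].
poly_design <- function(y, x, order, scale_y, scale_x) {
  yn <- y / scale_y
  xn <- x / scale_x
  cols <- list()
  nm <- character()
  for (total in 0:order) {
    for (i in 0:total) {       # i = power of x, total - i = power of y
      cols[[length(cols) + 1L]] <- xn^i * yn^(total - i)
      nm <- c(nm, sprintf("x%d_y%d", i, total - i))
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nm
  m
}

#' Draw a random smooth polynomial field over the object
#'
#' Polynomial coefficients are drawn i.i.d. uniform on \[-1, 1\] and the
#' resulting surface is affinely rescaled so that its minimum and maximum
#' over the object mask equal the requested range endpoints — the surface
#' shape is random while the physiological range is guaranteed.
#'
#' For B1, the random surface is blended with a fixed radial (quadratic)
#' profile rising from the object center to the periphery, emulating the
#' receive-sensitivity pattern of a close-fitting surface-coil array (low
#' in the center of the brain, high near the skull); `radial_frac` sets the
#' weight of the structured component and 0 gives a purely random surface.
#' The blend stays within the polynomial family.
#'
#' @param kind "B0" (Hz) or "B1" (relative sensitivity)
#' @param order polynomial order (3 or 4)
#' @param range length-2 numeric: target (min, max) over the mask
#' @param rois `roi_map` providing the raster geometry
#' @param mask logical matrix (default: object pixels)
#' @param seed integer seed
#' @param radial_frac weight of the radial component for B1 (0..1)
#' @return a `field_map` covering the full raster (polynomial evaluated
#'   everywhere; the range guarantee holds over the mask)
#' @export
sample_random_field <- function(kind = c("B0", "B1"), order = 4, range,
                                rois, mask = rois$labels > 0L, seed,
                                radial_frac = 0.75) {
  kind <- match.arg(kind)
  if (!order %in% c(3, 4)) stopf("polynomial order must be 3 or 4")
  if (kind == "B1" && range[1] <= 0) stopf("B1 range must be positive")
  if (range[2] < range[1]) stopf("range must be (min, max)")
  d <- dim(rois$labels)
  co <- pixel_coords(rois)
  Y <- matrix(co$y, d[1], d[2])
  X <- matrix(co$x, d[1], d[2], byrow = TRUE)
  B <- poly_design(as.vector(Y), as.vector(X), order,
                   rois$fov_mm[1] / 2, rois$fov_mm[2] / 2)
  w <- if (kind == "B1") radial_frac else 0
  base <- 0
  base_cf <- numeric(ncol(B))
  if (w > 0) {
    # normalized squared elliptical radius of the object bounding box
    # (a quadratic polynomial, so the blend stays in the design basis)
    ay <- max(abs(Y[mask])) + max(rois$pixel_mm)
    ax <- max(abs(X[mask])) + max(rois$pixel_mm)
    q <- (Y / ay)^2 + (X / ax)^2
    mb <- max(q[mask])
    q <- q / mb
    # rise from the center with a plateau at the periphery, as in
    # voxel-averaged, polynomial-parameterized receive-array profiles
    base <- 2 * q - q^2
    cy <- (rois$fov_mm[1] / 2 / ay)^2 / mb
    cx <- (rois$fov_mm[2] / 2 / ax)^2 / mb
    tm <- c(x0_y2 = 2 * cy, x2_y0 = 2 * cx, x0_y4 = -cy^2, x4_y0 = -cx^2,
            x2_y2 = -2 * cy * cx)
    tm <- tm[names(tm) %in% colnames(B)]   # quartic terms need order >= 4
    base_cf[match(names(tm), colnames(B))] <- tm
  }
  for (attempt in 0:20) {
    set.seed(substream_seed(seed, attempt))
    cf <- stats::runif(ncol(B), -1, 1)
    surf <- matrix(B %*% cf, d[1], d[2])
    lo <- min(surf[mask]); hi <- max(surf[mask])
    if (hi - lo > 1e-9 * max(abs(hi), abs(lo), 1)) {
      if (attempt > 0L) warnf("degenerate field surface; used substream %d", attempt)
      # coefficients of the [0, 1]-normalized random surface
      cr <- cf / (hi - lo)
      cr[1] <- cr[1] - lo / (hi - lo)
      surf <- (surf - lo) / (hi - lo)
      cb <- cr
      if (w > 0) {
        surf <- w * base + (1 - w) * surf
        cb <- w * base_cf + (1 - w) * cr
      }
      lo <- min(surf[mask]); hi <- max(surf[mask])
      a <- (range[2] - range[1]) / (hi - lo)
      b <- range[1] - a * lo
      cf2 <- cb * a
      cf2[1] <- cf2[1] + b
      names(cf2) <- colnames(B)
      return(field_map(a * surf + b, kind, coeffs = cf2, order = order,
                       pixel_mm = rois$pixel_mm))
    }
  }
  stopf("could not draw a non-degenerate polynomial surface")
}
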