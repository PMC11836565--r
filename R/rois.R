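# Compartment label rasters (ROI maps) at anatomical (MRI-like) resolution.
#
# Conventions: rasters are ny x nx integer matrices with 0 = outside the
# object; rows index y, columns x. Physical coordinates are pixel centers in
# mm, with the field of view (FOV) centered at the origin. The FOV is the
# MRSI grid times the nominal voxel size, and the raster is an integer
# upsampling of the MRSI grid so every raster pixel belongs to exactly one
# MRSI voxel.

#' Construct an ROI label map
#'
#' @param labels integer matrix (ny x nx), 0 outside the object; every
#'   nonzero pixel carries exactly one compartment label.
#' @param grid_dims MRSI matrix dimensions c(ny, nx).
#' @param nominal_voxel_mm MRSI voxel size in mm (scalar or c(dy, dx)).
#' @param roles named list mapping role names (brain, GM, WM, CSF,
#'   pathology, skull) to integer label vectors.
#' @return an object of class `roi_map`.
#' @export
roi_map <- function(labels, grid_dims, nominal_voxel_mm, roles) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stopf("labels must be >= 0")
  grid_dims <- as.integer(grid_dims)
  if (length(nominal_voxel_mm) == 1L) nominal_voxel_mm <- rep(nominal_voxel_mm, 2L)
  up <- dim(labels) / grid_dims
  if (any(up != round(up)))
    stopf("raster dims (%s) must be an integer multiple of grid_dims (%s)",
          paste(dim(labels), collapse = "x"), paste(grid_dims, collapse = "x"))
  for (rl in names(roles)) {
    lb <- roles[[rl]]
    if (length(lb) && !any(labels %in% lb))
      stopf("declared role '%s' maps to no pixels", rl)
  }
  structure(list(
    labels = labels,
    grid_dims = grid_dims,
    nominal_voxel_mm = as.numeric(nominal_voxel_mm),
    pixel_mm = as.numeric(nominal_voxel_mm) / as.integer(up),
    fov_mm = grid_dims * as.numeric(nominal_voxel_mm),
    upsample = as.integer(up),
    roles = roles
  ), class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  cat(sprintf("<roi_map> raster %dx%d, MRSI grid %dx%d, voxel %gx%g mm\n",
              nrow(x$labels), ncol(x$labels), x$grid_dims[1], x$grid_dims[2],
              x$nominal_voxel_mm[1], x$nominal_voxel_mm[2]))
  tab <- table(x$labels[x$labels > 0L])
  cat(sprintf("  %d compartments, %d object pixels; roles: %s\n",
              length(tab), sum(tab), paste(names(x$roles), collapse = ", ")))
  invisible(x)
}

#' Physical pixel-center coordinates of a raster
#'
#' @param rois an `roi_map`
#' @return list with vectors `y` (length ny) and `x` (length nx) in mm.
#' @export
pixel_coords <- function(rois) {
  d <- dim(rois$labels)
  list(
    y = (seq_len(d[1]) - (d[1] + 1) / 2) * rois$pixel_mm[1],
    x = (seq_len(d[2]) - (d[2] + 1) / 2) * rois$pixel_mm[2]
  )
}

# Coordinates (mm) of every object pixel plus its label, as a list of
# parallel vectors; used by the encoding and synthesis routines.
object_pixels <- function(rois, mask = rois$labels > 0L) {
  idx <- which(mask)
  d <- dim(rois$labels)
  co <- pixel_coords(rois)
  i <- (idx - 1L) %% d[1] + 1L
  j <- (idx - 1L) %/% d[1] + 1L
  list(idx = idx, y = co$y[i], x = co$x[j], label = rois$labels[idx],
       area = prod(rois$pixel_mm))
}

# MRSI voxel index (row-major over the grid, rows=y) of each raster pixel.
voxel_index_map <- function(rois) {
  d <- dim(rois$labels)
  u <- rois$upsample
  vi <- (seq_len(d[1]) - 1L) %/% u[1] + 1L
  vj <- (seq_len(d[2]) - 1L) %/% u[2] + 1L
  matrix(vi[row(rois$labels)] + (vj[col(rois$labels)] - 1L) * rois$grid_dims[1],
         d[1], d[2])
}

#' Classify MRSI voxels by compartment content
#'
#' Voxels are classified by pixel counting at the MRI raster resolution:
#' a voxel is "pure brain" when every raster pixel in it carries a brain
#' label, and "skull containing" when at least one pixel carries a skull
#' label. Used to select voxels for retention and suppression metrics.
#'
#' @param rois an `roi_map` with roles `brain` and `skull`
#' @return data.frame with one row per MRSI voxel: `voxel` (row-major
#'   index), `frac_brain`, `frac_skull`, `frac_object`, `pure_brain`,
#'   `skull_containing`.
#' @export
voxel_classes <- function(rois) {
  vmap <- voxel_index_map(rois)
  nvox <- prod(rois$grid_dims)
  npix <- prod(rois$upsample)
  lab <- rois$labels
  brain <- rois$roles$brain
  skull <- rois$roles$skull
  cnt <- function(m) tabulate(vmap[m], nbins = nvox)
  n_b <- cnt(matrix(lab %in% brain, nrow(lab)))
  n_s <- cnt(matrix(lab %in% skull, nrow(lab)))
  n_o <- cnt(lab > 0L)
  data.frame(
    voxel = seq_len(nvox),
    frac_brain = n_b / npix,
    frac_skull = n_s / npix,
    frac_object = n_o / npix,
    pure_brain = n_b == npix,
    skull_containing = n_s > 0L
  )
}

ellipse_mask <- function(co, cy, cx, ry, rx) {
  outer(((co$y - cy) / ry)^2, ((co$x - cx) / rx)^2, `+`) <= 1
}

# Superellipse |u/a|^p + |v/b|^p <= 1 with semi-axes chosen so the
# continuous area equals `area`, aspect = a/b, rotated by `theta`.
superellipse_mask <- function(co, cy, cx, area, aspect, p, theta) {
  shape <- 4 * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)  # area = shape * a * b
  b <- sqrt(area / (shape * aspect))
  a <- aspect * b
  Y <- matrix(co$y - cy, length(co$y), length(co$x))
  X <- matrix(co$x - cx, length(co$y), length(co$x), byrow = TRUE)
  U <- cos(theta) * X + sin(theta) * Y
  V <- -sin(theta) * X + cos(theta) * Y
  abs(U / a)^p + abs(V / b)^p <= 1
}

#' Generate a synthetic head phantom
#'
#' Builds a parametric 2D head: an elliptical brain (with CSF rim, central
#' ventricle, GM shell and WM core), a closed extracranial annulus
#' ("skull", comprising skull plus scalp), and one pathology region of
#' random superellipse shape whose area is drawn uniformly in 72%-148% of
#' the nominal MRSI voxel area and which lies fully inside the brain.
#' Geometry (brain semi-axes, annulus thickness) is mildly randomized per
#' seed to emulate between-subject variation.
#'
#' Labels: 1 = GM, 2 = WM, 3 = CSF, 4 = pathology, 5 = skull.
#'
#' @param seed integer seed; fixed seed gives a bit-identical phantom.
#' @param grid_dims MRSI matrix c(ny, nx); default 9 x 13.
#' @param nominal_voxel_mm MRSI voxel size (mm); default 20.
#' @param upsample raster pixels per MRSI voxel per axis; default 6.
#' @param brain_semiaxes_mm nominal brain semi-axes c(y, x) in mm.
#' @param skull_thickness_mm nominal annulus thickness (mm).
#' @param randomize randomize geometry around the nominal values.
#' @param pathology place a pathology region.
#' @param max_tries placement retries before giving up.
#' @return an `roi_map`
#' @export
make_head_phantom <- function(seed, grid_dims = c(9, 13), nominal_voxel_mm = 20,
                              upsample = 6, brain_semiaxes_mm = c(56, 85),
                              skull_thickness_mm = 22, randomize = TRUE,
                              pathology = TRUE, max_tries = 200L) {
  set.seed(as.integer(seed))
  if (length(nominal_voxel_mm) == 1L) nominal_voxel_mm <- rep(nominal_voxel_mm, 2L)
  grid_dims <- as.integer(grid_dims)
  d <- grid_dims * upsample
  pixel_mm <- nominal_voxel_mm / upsample
  co <- list(
    y = (seq_len(d[1]) - (d[1] + 1) / 2) * pixel_mm[1],
    x = (seq_len(d[2]) - (d[2] + 1) / 2) * pixel_mm[2]
  )
  if (randomize) {
    semi <- brain_semiaxes_mm * stats::runif(2, 0.92, 1.03)
    thick <- stats::runif(1, skull_thickness_mm - 2, skull_thickness_mm + 2)
  } else {
    semi <- brain_semiaxes_mm
    thick <- skull_thickness_mm
  }
  fov <- grid_dims * nominal_voxel_mm
  if (any(semi + thick > fov / 2 - 2 * pixel_mm))
    stopf("grid too small: head (semi-axes %s + %g mm) exceeds FOV %s mm",
          paste(round(semi, 1), collapse = "x"), thick,
          paste(fov, collapse = "x"))

  brain <- ellipse_mask(co, 0, 0, semi[1], semi[2])
  head <- ellipse_mask(co, 0, 0, semi[1] + thick, semi[2] + thick)
  if (sum(head & !brain) == 0L) stopf("skull annulus is empty")

  labels <- matrix(0L, d[1], d[2])
  labels[head & !brain] <- 5L
  # Concentric tissue shells by normalized elliptical radius.
  rho <- sqrt(outer((co$y / semi[1])^2, (co$x / semi[2])^2, `+`))
  mean_semi <- mean(semi)
  csf_in <- 1 - 4 / mean_semi
  gm_in <- 1 - 14 / mean_semi
  labels[brain] <- 2L                              # WM core
  labels[brain & rho > gm_in] <- 1L                # GM shell
  labels[brain & rho > csf_in] <- 3L               # CSF rim
  vent <- ellipse_mask(co, 0, 0, 9, 14)            # central ventricle (CSF)
  labels[brain & vent] <- 3L

  if (pathology) {
    vox_area <- prod(nominal_voxel_mm)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      frac <- stats::runif(1, 0.72, 1.48)
      aspect <- stats::runif(1, 0.6, 1.6)
      p <- stats::runif(1, 1.5, 3.5)
      theta <- stats::runif(1, 0, pi)
      cy <- stats::runif(1, -semi[1], semi[1])
      cx <- stats::runif(1, -semi[2], semi[2])
      pm <- superellipse_mask(co, cy, cx, frac * vox_area, aspect, p, theta)
      if (!any(pm)) next
      if (all(brain[pm])) {
        got <- sum(pm) * prod(pixel_mm) / vox_area
        if (got >= 0.72 && got <= 1.48) {  # guard against pixelation drift
          labels[pm] <- 4L
          placed <- TRUE
          break
        }
      }
    }
    if (!placed)
      stopf("could not place pathology ROI inside brain after %d tries", max_tries)
  }

  roles <- list(GM = 1L, WM = 2L, CSF = 3L, brain = c(1L, 2L, 3L), skull = 5L)
  if (pathology) {
    roles$pathology <- 4L
    roles$brain <- c(1L, 2L, 3L, 4L)
  }
  roi_map(labels, grid_dims, nominal_voxel_mm, roles)
}

#' Rigidly shift all compartments relative to the MRSI grid
#'
#' Translates every label by the nearest whole number of raster pixels.
#' Used to vary partial-volume fractions of a tracked MRSI voxel while the
#' k-space grid stays fixed.
#'
#' @param rois an `roi_map`
#' @param offset_mm translation c(dy, dx) in mm
#' @return shifted `roi_map`; errors if any object pixel would leave the raster.
#' @export
shift_rois <- function(rois, offset_mm) {
  sh <- round(offset_mm / rois$pixel_mm)
  d <- dim(rois$labels)
  new <- matrix(0L, d[1], d[2])
  idx <- which(rois$labels > 0L, arr.ind = TRUE)
  i2 <- idx[, 1] + sh[1]
  j2 <- idx[, 2] + sh[2]
  if (any(i2 < 1L | i2 > d[1] | j2 < 1L | j2 > d[2]))
    stopf("shift of (%g, %g) mm moves the object outside the raster",
          offset_mm[1], offset_mm[2])
  new[cbind(i2, j2)] <- rois$labels[idx]
  out <- rois
  out$labels <- new
  out
}
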