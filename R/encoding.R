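# k-space trajectories and compartment encoding matrices.
#
# The phase-encoded MRSI model is P = G C: P the measured N_enc x N_time
# k-space data, C the N_ROI x N_time compartment time signals and G the
# N_enc x N_ROI encoding matrix G[m, k] = integral over ROI_k of
# exp(+i 2 pi k_m . r) dr, discretized as a pixel-center Riemann sum at the
# MRI raster resolution. Field heterogeneity enters as a time-dependent
# generalization G[m, k](t) = sum_r B1(r) exp(i 2 pi B0(r) t)
# exp(i 2 pi k_m . r) dV over ROI_k.

#' Build a phase-encoding trajectory
#'
#' Cartesian k-vectors k = index / FOV on a grid centered at k = 0, ordered
#' by raster scan of the grid (y fastest) for reproducibility. The
#' `spherical` scheme keeps the subset with sum((k_a / k_a,max)^2) <= 1.
#'
#' @param grid_dims MRSI matrix dims c(ny, nx)
#' @param fov_mm field of view per axis (mm)
#' @param scheme "full_cartesian" or "spherical"
#' @return object of class `kspace_trajectory` with `kvec` (N_enc x 2,
#'   cycles/mm, columns ky, kx), `kidx` (integer grid indices), `grid_dims`,
#'   `fov_mm`, `scheme`.
#' @export
build_trajectory <- function(grid_dims, fov_mm, scheme = c("full_cartesian", "spherical")) {
  scheme <- match.arg(scheme)
  grid_dims <- as.integer(grid_dims)
  if (any(grid_dims < 1L)) stopf("grid_dims must be >= 1")
  if (length(fov_mm) == 1L) fov_mm <- rep(fov_mm, length(grid_dims))
  ax <- lapply(grid_dims, function(n) seq.int(-(n %/% 2L), ceiling(n / 2) - 1L))
  names(ax) <- c("ky", "kx", "kz")[seq_along(ax)]
  g <- as.matrix(do.call(expand.grid, ax))
  if (scheme == "spherical") {
    kmax <- pmax(vapply(ax, function(v) max(abs(v)), 0), 1e-12)
    r2 <- rowSums(sweep(g, 2, kmax, `/`)^2)
    g <- g[r2 <= 1 + 1e-12, , drop = FALSE]
  }
  structure(list(
    kvec = sweep(g, 2, fov_mm, `/`),
    kidx = g,
    grid_dims = grid_dims,
    fov_mm = as.numeric(fov_mm),
    scheme = scheme
  ), class = "kspace_trajectory")
}

n_encodings <- function(traj) nrow(traj$kvec)

# Pixel-level encoding matrix E[m, p] = exp(+i 2 pi k_m . r_p) for a set of
# object pixels; the workhorse shared by synthesis, G construction and SRF
# evaluation.
pixel_phase_matrix <- function(traj, px) {
  exp(2i * pi * (outer(traj$kvec[, 1], px$y) + outer(traj$kvec[, 2], px$x)))
}

#' Build the static compartment encoding matrix G
#'
#' G\[m, k\] = sum over pixels r in ROI_k of exp(i 2 pi k_m . r) times the
#' pixel volume.
#'
#' @param traj a `kspace_trajectory`
#' @param rois an `roi_map`
#' @param roi_order optional integer labels fixing column order (default:
#'   sorted nonzero labels)
#' @return complex N_enc x N_ROI matrix of class `encoding_matrix` with
#'   attributes `roi_order` and `traj`
#' @export
build_encoding_matrix <- function(traj, rois, roi_order = NULL) {
  labs <- roi_order %||% sort(unique(rois$labels[rois$labels > 0L]))
  px <- object_pixels(rois)
  E <- pixel_phase_matrix(traj, px)
  G <- matrix(0i, n_encodings(traj), length(labs))
  for (k in seq_along(labs)) {
    sel <- px$label == labs[k]
    if (!any(sel)) stopf("ROI with label %d is empty", labs[k])
    G[, k] <- E[, sel, drop = FALSE] %*% rep(px$area, sum(sel))
  }
  structure(G, roi_order = as.integer(labs), traj = traj,
            class = c("encoding_matrix", "matrix"))
}

#' Build the B0/B1-augmented (time-varying) encoding matrix
#'
#' Generalizes the static G with per-pixel receive sensitivity B1(r) and
#' phase accrual exp(i 2 pi B0(r) t):
#' G\[m, k\](t) = sum_r B1(r) exp(i 2 pi B0(r) t) exp(i 2 pi k_m . r) dV.
#' Reduces exactly to the static matrix for B0 = 0, B1 = 1.
#'
#' @param traj a `kspace_trajectory`
#' @param rois an `roi_map`
#' @param b0,b1 `field_map`s on the ROI raster (NULL = 0 Hz / unity)
#' @param time_s time axis (s), length N_time
#' @param roi_order optional label order
#' @return complex array N_enc x N_ROI x N_time of class `encoding_tv` with
#'   attributes `roi_order`, `traj`, `time_s`
#' @export
build_field_encoding <- function(traj, rois, b0 = NULL, b1 = NULL, time_s,
                                 roi_order = NULL) {
  labs <- roi_order %||% sort(unique(rois$labels[rois$labels > 0L]))
  px <- object_pixels(rois)
  for (fm in list(b0, b1)) {
    if (!is.null(fm) && !all(dim(fm$values) == dim(rois$labels)))
      stopf("field map raster does not match the ROI raster")
  }
  b0v <- if (is.null(b0)) numeric(length(px$idx)) else b0$values[px$idx]
  b1v <- if (is.null(b1)) rep(1, length(px$idx)) else b1$values[px$idx]
  if (any(b1v <= 0)) stopf("B1 must be positive inside the object")
  E <- pixel_phase_matrix(traj, px)
  nt <- length(time_s)
  G <- array(0i, c(n_encodings(traj), length(labs), nt))
  for (k in seq_along(labs)) {
    sel <- px$label == labs[k]
    if (!any(sel)) stopf("ROI with label %d is empty", labs[k])
    # factored form: per-ROI pixel weights x per-pixel phase accrual
    W <- (b1v[sel] * px$area) * exp(2i * pi * outer(b0v[sel], time_s))
    G[, k, ] <- E[, sel, drop = FALSE] %*% W
  }
  structure(G, roi_order = as.integer(labs), traj = traj, time_s = time_s,
            class = "encoding_tv")
}

is_time_varying <- function(G) inherits(G, "encoding_tv")

roi_order_of <- function(G) attr(G, "roi_order")
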