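# SLIM core: SVD pseudoinverse of the encoding matrix, compartment signal
# recovery, skull-only reconstruction, subtraction, and standard FFT
# reconstruction for voxel spectra.

#' Tolerance-truncated SVD pseudoinverse
#'
#' @param G complex matrix (N_enc x N_ROI)
#' @param svd_tol relative truncation threshold: singular values below
#'   `svd_tol * max(singular)` are discarded
#' @return list with `pinv` (N_ROI x N_enc), `cond` (ratio of largest to
#'   smallest retained singular value) and `d` (all singular values)
#' @export
slim_pinv <- function(G, svd_tol = 1e-10) {
  sv <- svd(G)
  keep <- sv$d >= svd_tol * sv$d[1]
  if (sum(keep) < ncol(G))
    stopf("encoding matrix is rank deficient at tolerance %g (singular values: %s)",
          svd_tol, paste(signif(sv$d, 4), collapse = ", "))
  pinv <- sv$v[, keep, drop = FALSE] %*%
    ((1 / sv$d[keep]) * Conj(t(sv$u[, keep, drop = FALSE])))
  list(pinv = pinv, cond = sv$d[1] / min(sv$d[keep]), d = sv$d)
}

#' Solve the SLIM linear model for compartment signals
#'
#' Static G: C = pinv(G) P via the truncated-SVD pseudoinverse. Time-varying
#' (field-augmented) G: C\[, t\] = pinv(G(t)) P\[, t\] per time point.
#'
#' @param G an `encoding_matrix` or `encoding_tv`
#' @param P a `kspace_data` (N_enc must match)
#' @param svd_tol relative SVD truncation tolerance
#' @return object of class `compartment_signals`: list with `values`
#'   (N_ROI x N_time), `roi_order`, `dwell_s`, `cond` (condition number;
#'   max over time points for time-varying G)
#' @export
slim_invert <- function(G, P, svd_tol = 1e-10) {
  labs <- roi_order_of(G)
  vals <- P$values
  if (is_time_varying(G)) {
    if (dim(G)[3] != ncol(vals))
      stopf("time axes disagree: G has %d points, P has %d", dim(G)[3], ncol(vals))
    if (dim(G)[1] != nrow(vals)) stopf("N_enc mismatch between G and P")
    C <- matrix(0i, length(labs), ncol(vals))
    cond <- 0
    for (t in seq_len(ncol(vals))) {
      Gt <- matrix(G[, , t], dim(G)[1], dim(G)[2])
      pv <- slim_pinv(Gt, svd_tol)
      C[, t] <- pv$pinv %*% vals[, t]
      cond <- max(cond, pv$cond)
    }
  } else {
    if (nrow(G) != nrow(vals)) stopf("N_enc mismatch between G and P")
    if (ncol(G) > nrow(G)) stopf("N_ROI (%d) exceeds N_enc (%d)", ncol(G), nrow(G))
    pv <- slim_pinv(unclass(G), svd_tol)
    C <- pv$pinv %*% vals
    cond <- pv$cond
  }
  structure(list(values = C, roi_order = labs, dwell_s = P$dwell_s, cond = cond),
            class = "compartment_signals")
}

#' Reconstruct k-space data from a subset of compartments
#'
#' P_sub\[m, t\] = sum over k in the subset of G\[m, k\](t) C\[k, t\] — the
#' forward model restricted to the chosen ROIs (e.g., all skull sub-ROIs,
#' giving the skull-only dataset to be subtracted).
#'
#' @param G the `encoding_matrix`/`encoding_tv` used for the inversion
#' @param C a `compartment_signals`
#' @param roi_subset labels to include (empty = zero data)
#' @return a `kspace_data`
#' @export
reconstruct_subset <- function(G, C, roi_subset) {
  labs <- roi_order_of(G)
  if (!all(roi_subset %in% labs))
    stopf("unknown ROI label(s): %s",
          paste(setdiff(roi_subset, labs), collapse = ", "))
  idx <- match(roi_subset, labs)
  traj <- attr(G, "traj")
  nt <- ncol(C$values)
  if (is_time_varying(G)) {
    P <- matrix(0i, dim(G)[1], nt)
    if (length(idx)) {
      for (t in seq_len(nt)) {
        Gt <- matrix(G[, , t], dim(G)[1], dim(G)[2])
        P[, t] <- Gt[, idx, drop = FALSE] %*% C$values[idx, t]
      }
    }
  } else {
    P <- if (length(idx))
      unclass(G)[, idx, drop = FALSE] %*% C$values[idx, , drop = FALSE]
    else matrix(0i, nrow(G), nt)
  }
  kspace_data(P, traj, C$dwell_s, meta = list(subset = roi_subset))
}

#' Subtract a skull-only dataset from the measured data
#'
#' @param P measured `kspace_data`
#' @param P_skull reconstructed skull-only `kspace_data` (same shape and
#'   trajectory)
#' @return lipid-free `kspace_data` (elementwise P - P_skull)
#' @export
remove_skull <- function(P, P_skull) {
  if (!all(dim(P$values) == dim(P_skull$values)))
    stopf("shape mismatch: %s vs %s", paste(dim(P$values), collapse = "x"),
          paste(dim(P_skull$values), collapse = "x"))
  if (!isTRUE(all.equal(P$traj$kvec, P_skull$traj$kvec)))
    stopf("trajectory mismatch between datasets")
  kspace_data(P$values - P_skull$values, P$traj, P$dwell_s,
              meta = c(P$meta, list(operation = "remove_skull")))
}

#' Standard FFT reconstruction of voxel spectra
#'
#' Inverse spatial DFT over the phase encodings (conjugate of the encoding
#' phase convention, 1/N_enc normalization so a point source at a voxel
#' center reproduces its time signal scaled by volume) followed by a forward
#' temporal FFT. Spherical-scheme data are treated as Cartesian with
#' unsampled encodings equal to zero.
#'
#' @param P a `kspace_data`
#' @param apodization optional function(t_s) returning a time-domain weight
#' @return object of class `spatial_spectra`: `values` array
#'   (ny x nx x N_freq, frequency ascending), `freq_hz`, `grid_dims`,
#'   `dwell_s`
#' @export
fft_reconstruct <- function(P, apodization = NULL) {
  traj <- P$traj
  nd <- traj$grid_dims
  nt <- ncol(P$values)
  # MRSI voxel centers (mm), object-centered
  vy <- (seq_len(nd[1]) - (nd[1] + 1) / 2) * traj$fov_mm[1] / nd[1]
  vx <- (seq_len(nd[2]) - (nd[2] + 1) / 2) * traj$fov_mm[2] / nd[2]
  vv <- expand.grid(y = vy, x = vx)
  A <- exp(-2i * pi * (outer(vv$y, traj$kvec[, 1]) + outer(vv$x, traj$kvec[, 2])))
  vals <- P$values
  if (!is.null(apodization)) {
    w <- apodization(time_axis(nt, P$dwell_s))
    vals <- sweep(vals, 2, w, `*`)
  }
  img <- (A %*% vals) / prod(nd)           # N_vox x N_time
  spec <- t(stats::mvfft(t(img)))          # forward FFT along time
  # reorder to ascending frequency axis
  ord <- c((nt %/% 2 + 1):nt, 1:(nt %/% 2))
  freq <- ((seq_len(nt) - 1) - nt %/% 2) / (nt * P$dwell_s)
  spec <- spec[, ord, drop = FALSE]
  structure(list(values = array(spec, c(nd[1], nd[2], nt)),
                 freq_hz = freq, grid_dims = nd, dwell_s = P$dwell_s),
            class = "spatial_spectra")
}

#' Extract one voxel's complex spectrum
#'
#' @param spectra a `spatial_spectra`
#' @param voxel row-major voxel index or c(row, col)
#' @return complex vector over `spectra$freq_hz`
#' @export
voxel_spectrum <- function(spectra, voxel) {
  if (length(voxel) == 2L)
    voxel <- voxel[1] + (voxel[2] - 1L) * spectra$grid_dims[1]
  v <- matrix(spectra$values, prod(spectra$grid_dims[1:2]))[voxel, ]
  as.vector(v)
}
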