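# Small fixtures shared across tests: a reduced head phantom (5 x 7 MRSI
# grid, 4x upsampling) keeps unit tests fast while exercising the same
# geometry code paths as the full 9 x 13 configuration.

small_phantom <- function(seed = 1, pathology = FALSE, randomize = FALSE) {
  make_head_phantom(seed, grid_dims = c(5, 7), nominal_voxel_mm = 20,
                    upsample = 4, brain_semiaxes_mm = c(26, 40),
                    skull_thickness_mm = 10, randomize = randomize,
                    pathology = pathology)
}

small_traj <- function(rois) build_trajectory(rois$grid_dims, rois$fov_mm)

# A single-compartment rectangular object (whole raster = one ROI),
# convenient for spectral checks.
slab_rois <- function(grid_dims = c(1, 1), upsample = 4) {
  labels <- matrix(1L, grid_dims[1] * upsample, grid_dims[2] * upsample)
  roi_map(labels, grid_dims, 20, roles = list(brain = 1L))
}

one_line_model <- function(label = 1, freq_hz = 0, amp = 1, t2_s = 0.03) {
  signal_model(stats::setNames(
    list(data.frame(freq_hz = freq_hz, amp = amp, t2_s = t2_s)),
    as.character(label)))
}

# Brute-force spatial DFT reconstruction (independent of fft_reconstruct):
# image value at voxel centers by direct summation.
brute_dft_image <- function(P) {
  traj <- P$traj
  nd <- traj$grid_dims
  vy <- (seq_len(nd[1]) - (nd[1] + 1) / 2) * traj$fov_mm[1] / nd[1]
  vx <- (seq_len(nd[2]) - (nd[2] + 1) / 2) * traj$fov_mm[2] / nd[2]
  out <- array(0i, c(nd[1], nd[2], ncol(P$values)))
  for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) {
    ph <- exp(-2i * pi * (traj$kvec[, 1] * vy[i] + traj$kvec[, 2] * vx[j]))
    out[i, j, ] <- as.vector(crossprod(ph, P$values)) / nrow(traj$kvec)
  }
  out
}
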