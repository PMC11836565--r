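# SLIM inversion, subset reconstruction, subtraction, FFT reconstruction.

fake_encoding <- function(values, traj, labs = seq_len(ncol(values))) {
  structure(values, roi_order = as.integer(labs), traj = traj,
            class = c("encoding_matrix", "matrix"))
}

test_that("slim_invert solves the linear model", {
  traj <- build_trajectory(c(2, 2), 40)
  # identity encoding: C = P
  G <- fake_encoding(diag(4) + 0i, traj)
  P <- kspace_data(matrix(complex(real = rnorm(4 * 8), imaginary = rnorm(4 * 8)),
                          4, 8), traj, 1e-3)
  C <- slim_invert(G, P)
  expect_lt(dmislim:::rel_err(C$values, P$values), 1e-12)
  # forward-model round trip with a known C0
  set.seed(42)
  traj2 <- build_trajectory(c(4, 5), 100)
  G2 <- fake_encoding(matrix(complex(real = rnorm(20 * 5), imaginary = rnorm(20 * 5)),
                             20, 5), traj2)
  C0 <- matrix(complex(real = rnorm(5 * 16), imaginary = rnorm(5 * 16)), 5, 16)
  P2 <- kspace_data(unclass(G2) %*% C0, traj2, 1e-3)
  expect_lt(dmislim:::rel_err(slim_invert(G2, P2)$values, C0), 1e-10)
  # condition number is recorded
  expect_true(is.finite(slim_invert(G2, P2)$cond))
  # rank-deficient G raises and names the singular values
  G3 <- fake_encoding(cbind(unclass(G2)[, 1:4], unclass(G2)[, 4]), traj2)
  expect_error(slim_invert(G3, P2), "rank deficient")
})

test_that("slim_invert agrees with a brute-force least-squares oracle", {
  set.seed(7)
  for (dims in list(c(6, 8), c(13, 15))) {
    traj <- build_trajectory(dims, dims * 20)
    n_enc <- prod(dims)
    n_roi <- 7
    G <- fake_encoding(matrix(complex(real = rnorm(n_enc * n_roi),
                                      imaginary = rnorm(n_enc * n_roi)),
                              n_enc, n_roi), traj)
    P <- kspace_data(matrix(complex(real = rnorm(n_enc * 10),
                                    imaginary = rnorm(n_enc * 10)),
                            n_enc, 10), traj, 1e-3)
    # normal-equation solve, independent of the SVD path
    Gm <- unclass(G)
    oracle <- solve(Conj(t(Gm)) %*% Gm, Conj(t(Gm)) %*% P$values)
    expect_lt(dmislim:::rel_err(slim_invert(G, P)$values, oracle), 1e-8)
  }
})

test_that("time-varying inversion matches the static path when fields are trivial", {
  rois <- small_phantom()
  traj <- small_traj(rois)
  model <- lipid_phantom_model(rois)
  P <- synthesize_dmi(rois, model, traj, n_time = 32)
  crois <- slim_compartments(rois)
  G <- build_encoding_matrix(traj, crois)
  Gtv <- build_field_encoding(traj, crois,
                              time_s = dmislim:::time_axis(32, P$dwell_s))
  Cs <- slim_invert(G, P)
  Ct <- slim_invert(Gtv, P)
  expect_lt(dmislim:::rel_err(Ct$values, Cs$values), 1e-9)
})

test_that("reconstruct_subset and remove_skull satisfy the forward-model identities", {
  rois <- small_phantom()
  traj <- small_traj(rois)
  model <- lipid_phantom_model(rois)
  P <- synthesize_dmi(rois, model, traj, n_time = 64)
  crois <- slim_compartments(rois)
  G <- build_encoding_matrix(traj, crois)
  C <- slim_invert(G, P)
  labs <- attr(G, "roi_order")
  # completeness: all ROIs reproduce the exact-model data
  P_all <- reconstruct_subset(G, C, labs)
  expect_lt(dmislim:::rel_err(P_all$values, P$values), 1e-9)
  # empty subset gives zero data
  expect_true(all(reconstruct_subset(G, C, integer())$values == 0))
  expect_error(reconstruct_subset(G, C, 77L), "unknown ROI")
  # skull subset equals the forward synthesis of the skull-only model
  P_sk <- reconstruct_subset(G, C, crois$roles$skull)
  sk_truth <- synthesize_dmi(rois, silence_except(model, rois$roles$skull),
                             traj, n_time = 64)
  expect_lt(dmislim:::rel_err(P_sk$values, sk_truth$values), 1e-9)
  # subtraction identities and linearity
  expect_equal(remove_skull(P, kspace_data(0 * P$values, traj, P$dwell_s))$values,
               P$values)
  expect_true(all(remove_skull(P, P)$values == 0))
  br_truth <- synthesize_dmi(rois, silence_except(model, rois$roles$brain),
                             traj, n_time = 64)
  expect_lt(dmislim:::rel_err(remove_skull(P, P_sk)$values, br_truth$values), 1e-9)
  s1 <- remove_skull(P, P_sk)
  s2 <- remove_skull(sk_truth, P_sk)
  both <- remove_skull(kspace_data(P$values + sk_truth$values, traj, P$dwell_s),
                       kspace_data(2 * P_sk$values, traj, P$dwell_s))
  expect_lt(dmislim:::rel_err(both$values, s1$values + s2$values), 1e-12)
  expect_error(remove_skull(P, kspace_data(P$values[, 1:10], traj, P$dwell_s)),
               "shape mismatch")
})

test_that("fft_reconstruct recovers point sources and conserves energy", {
  # single-pixel source at a voxel center
  g <- c(5, 5)
  up <- 3
  labels <- matrix(0L, g[1] * up, g[2] * up)
  labels[8, 8] <- 1L   # center pixel of the central voxel
  rois <- roi_map(labels, g, 21, roles = list(brain = 1L))
  traj <- small_traj(rois)
  model <- one_line_model(1, freq_hz = -100)
  P <- synthesize_dmi(rois, model, traj, n_time = 32)
  sp <- fft_reconstruct(P)
  img <- brute_dft_image(P)
  # brute-force DFT oracle agrees (after the same temporal FFT); errors
  # normalized by the global image scale since off-source voxels are ~0
  scale <- max(Mod(img))
  for (v in c(1, 13, 25)) {
    i <- (v - 1) %% g[1] + 1
    j <- (v - 1) %/% g[1] + 1
    ref <- stats::fft(img[i, j, ])
    ord <- c((32 %/% 2 + 1):32, 1:(32 %/% 2))
    expect_lt(max(Mod(voxel_spectrum(sp, v) - ref[ord])) / scale, 1e-9)
  }
  # the central voxel carries the source's time signal scaled by volume
  fid_c <- img[3, 3, ]
  truth <- dmislim:::compartment_fid(model, 1, dmislim:::time_axis(32, P$dwell_s)) *
    prod(rois$pixel_mm)
  expect_lt(dmislim:::rel_err(fid_c, truth), 1e-9)
  # Parseval: k-space and image energies agree under the 1/N normalization
  expect_equal(sum(Mod(P$values)^2) / nrow(P$values), sum(Mod(img)^2),
               tolerance = 1e-9)
  # zero data reconstruct to zero spectra
  z <- fft_reconstruct(kspace_data(0 * P$values, traj, P$dwell_s))
  expect_true(all(z$values == 0))
})
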