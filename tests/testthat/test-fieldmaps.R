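# Surrogate B0/B1 maps from the DMI water signal.

water_only <- function(rois, amp = 1) {
  labs <- sort(unique(rois$labels[rois$labels > 0L]))
  signal_model(stats::setNames(lapply(labs, function(l)
    data.frame(freq_hz = 0, amp = amp, t2_s = 0.03)), labs))
}

test_that("the water-shift map recovers uniform and polynomial B0 offsets", {
  rois <- small_phantom()
  traj <- small_traj(rois)
  model <- water_only(rois)
  const4 <- field_map(matrix(4, nrow(rois$labels), ncol(rois$labels)), "B0")
  P <- synthesize_dmi(rois, model, traj, b0 = const4)
  sh <- water_shift_map(fft_reconstruct(P))
  vc <- voxel_classes(rois)
  interior <- vc$frac_object > 0.9
  expect_lt(max(abs(sh$values[interior] - 4)), 0.2)
  # zero-field phantom maps to ~0
  P0 <- synthesize_dmi(rois, model, traj)
  sh0 <- water_shift_map(fft_reconstruct(P0))
  expect_lt(max(abs(sh0$values[interior])), 0.1)
  # a -10..+10 Hz polynomial field: per-voxel shifts track the
  # voxel-averaged truth and the fitted surrogate recovers the surface
  head <- make_head_phantom(50, randomize = FALSE, pathology = FALSE)
  traj9 <- build_trajectory(head$grid_dims, head$fov_mm)
  b0 <- sample_random_field("B0", 4, c(-10, 10), head, seed = 21)
  Pb <- synthesize_dmi(head, water_only(head), traj9, b0 = b0)
  raw <- water_shift_map(fft_reconstruct(Pb))
  vc9 <- voxel_classes(head)
  vmap <- dmislim:::voxel_index_map(head)
  ok <- which(vc9$frac_object > 0.99 & is.finite(raw$values))
  truth <- vapply(ok, function(v) mean(b0$values[vmap == v]), 0)
  expect_lt(max(abs(raw$values[ok] - truth)), 0.75)
  sur <- estimate_surrogate_maps(Pb, head, order = 3)
  obj <- head$labels > 0L
  expect_lt(mean(abs(sur$b0$values[obj] - b0$values[obj])), 1)
  # endpoint recovery is limited by voxel averaging and the low fit order
  expect_equal(min(sur$b0$values[obj]), -10, tolerance = 0.3)
  expect_equal(max(sur$b0$values[obj]), 10, tolerance = 0.3)
})

test_that("the water-intensity map recovers relative B1 and is scale invariant", {
  rois <- small_phantom()
  traj <- small_traj(rois)
  model <- water_only(rois)
  d <- dim(rois$labels)
  ramp <- field_map(matrix(seq(0.15, 1, length.out = d[2]), d[1], d[2],
                           byrow = TRUE), "B1")
  P <- synthesize_dmi(rois, model, traj, b1 = ramp)
  raw <- water_intensity_map(fft_reconstruct(P), rois = rois)
  vc <- voxel_classes(rois)
  ok <- which(vc$frac_object > 0.99)
  # per-voxel mean of the true ramp, normalized the same way
  vmap <- dmislim:::voxel_index_map(rois)
  truth <- vapply(ok, function(v) mean(ramp$values[vmap == v]), 0)
  rel <- raw$values[ok] / max(raw$values[ok])
  # per-voxel accuracy is limited by Gibbs ringing of the coarse MRSI grid
  expect_lt(max(abs(rel - truth / max(truth))), 0.15)
  expect_lt(median(abs(rel - truth / max(truth))), 0.05)
  # b1 = 1 everywhere: the fitted surrogate is flat over the object
  P1 <- synthesize_dmi(rois, model, traj)
  flat <- water_intensity_map(fft_reconstruct(P1), rois = rois)
  ffit <- fit_surrogate(flat, 3, rois)
  obj <- rois$labels > 0L
  expect_lt(diff(range(ffit$values[obj])) / max(ffit$values[obj]), 0.2)
  # doubling all amplitudes leaves the normalized map unchanged
  P2 <- synthesize_dmi(rois, water_only(rois, amp = 2), traj, b1 = ramp)
  raw2 <- water_intensity_map(fft_reconstruct(P2), rois = rois)
  expect_equal(raw$values[ok], raw2$values[ok], tolerance = 1e-9)
  expect_true(all(raw$values[is.finite(raw$values)] > 0 &
                    raw$values[is.finite(raw$values)] <= 1))
})

test_that("polynomial surrogate fits round-trip exact surfaces and tolerate noise", {
  rois <- small_phantom()
  g <- rois$grid_dims
  vy <- (seq_len(g[1]) - (g[1] + 1) / 2) * rois$nominal_voxel_mm[1]
  vx <- (seq_len(g[2]) - (g[2] + 1) / 2) * rois$nominal_voxel_mm[2]
  Yn <- matrix(vy / (rois$fov_mm[1] / 2), g[1], g[2])
  Xn <- matrix(vx / (rois$fov_mm[2] / 2), g[1], g[2], byrow = TRUE)
  surf <- 2 - 3 * Xn + 1.5 * Yn * Xn + 0.5 * Xn^3   # exact order-3 polynomial
  raw <- field_map(surf, "B0")
  fit <- fit_surrogate(raw, order = 3, rois)
  # residual at the voxel centers ~ 0; evaluation extends to the MRI raster
  co <- pixel_coords(rois)
  d <- dim(rois$labels)
  truth <- 2 - 3 * outer(rep(1, d[1]), co$x / (rois$fov_mm[2] / 2)) +
    1.5 * outer(co$y / (rois$fov_mm[1] / 2), co$x / (rois$fov_mm[2] / 2)) +
    0.5 * outer(rep(1, d[1]), (co$x / (rois$fov_mm[2] / 2))^3)
  expect_lt(max(abs(fit$values - truth)), 1e-8)
  # constant map stays constant
  cfit <- fit_surrogate(field_map(matrix(7, g[1], g[2]), "B0"), 3, rois)
  expect_lt(max(abs(cfit$values - 7)), 1e-9)
  # missing voxels are excluded from the fit
  raw_na <- raw
  raw_na$values[1, 1] <- NA
  fit_na <- fit_surrogate(raw_na, order = 3, rois)
  expect_lt(max(abs(fit_na$values - truth)), 1e-8)
  # Monte-Carlo: i.i.d. noise perturbs coefficients within the LS envelope
  set.seed(31)
  sigma <- 0.1
  devs <- replicate(20, {
    noisy <- field_map(surf + matrix(rnorm(prod(g), 0, sigma), g[1], g[2]), "B0")
    fit_surrogate(noisy, 3, rois)$coeffs - fit$coeffs
  })
  # coefficient SDs bounded by the design-based envelope (generous factor)
  B <- dmislim:::poly_design(rep(vy, times = g[2]), rep(vx, each = g[1]), 3,
                             rois$fov_mm[1] / 2, rois$fov_mm[2] / 2)
  env <- sigma * sqrt(diag(solve(crossprod(B))))
  expect_true(all(apply(devs, 1, sd) < 3 * env))
  expect_true(all(abs(rowMeans(devs)) < 4 * env / sqrt(20)))
})

test_that("surrogate-map compensation reduces residual lipid on heterogeneous phantoms", {
  rois <- make_head_phantom(3)
  traj <- build_trajectory(rois$grid_dims, rois$fov_mm)
  model <- lipid_phantom_model(rois)
  b0 <- sample_random_field("B0", 4, c(-10, 10), rois, seed = 33)
  b1 <- sample_random_field("B1", 4, c(0.15, 1), rois, seed = 34)
  P <- synthesize_dmi(rois, model, traj, b0 = b0, b1 = b1, n_time = 256)
  ref <- synthesize_dmi(rois, silence_except(model, rois$roles$brain), traj,
                        b0 = b0, b1 = b1, n_time = 256)
  crois <- slim_compartments(rois)
  bands <- fig2_bands()
  plain <- dmislim:::slim_remove_skull(P, crois)
  s_plain <- suppression_percent(P, plain$after, crois, bands, reference = ref)
  sur <- estimate_surrogate_maps(P, rois)
  comp <- dmislim:::slim_remove_skull(P, crois, b0 = sur$b0, b1 = sur$b1)
  s_comp <- suppression_percent(P, comp$after, crois, bands, reference = ref)
  expect_lt(s_comp$residual, s_plain$residual)
})
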