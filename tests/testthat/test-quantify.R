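# Band integration, Lorentzian fitting, suppression/retention metrics.

test_that("band integration matches the closed-form Lorentzian magnitude area", {
  t2 <- 0.03
  nt <- 4096
  dwell <- 1e-3
  fid <- exp(-(0:(nt - 1)) * dwell / t2)
  spec <- stats::fft(fid)
  ord <- c((nt %/% 2 + 1):nt, 1:(nt %/% 2))
  freq <- ((seq_len(nt) - 1) - nt %/% 2) / (nt * dwell)
  spec <- spec[ord]
  # closed form: integral over +-W of |1/(1/T2 + i 2 pi f)| = asinh(2 pi W T2) / pi
  W <- 5 / (pi * t2)   # +-5 FWHM
  got <- integrate_peak(spec * dwell, freq, c(-W, W))
  expect_equal(got, asinh(2 * pi * W * t2) / pi, tolerance = 0.02)
  # converges toward the wider-band closed form as the band widens
  W2 <- 10 / (pi * t2)
  got2 <- integrate_peak(spec * dwell, freq, c(-W2, W2))
  expect_equal(got2, asinh(2 * pi * W2 * t2) / pi, tolerance = 0.02)
  expect_gt(got2, got)
  # zero spectrum integrates to zero; empty band raises
  expect_equal(integrate_peak(numeric(nt), freq, c(-W, W)), 0)
  expect_error(integrate_peak(spec, freq, c(1e5, 2e5)), "empty")
})

test_that("band integrals of well-separated lines are additive", {
  t_s <- (0:2047) * 1e-3
  fid1 <- 2 * exp((2i * pi * -150 - 1 / 0.03) * t_s)
  fid2 <- 0.7 * exp((2i * pi * 200 - 1 / 0.03) * t_s)
  sp <- function(f) {
    s <- stats::fft(f)
    s[c(1025:2048, 1:1024)]
  }
  freq <- ((1:2048) - 1 - 1024) / 2.048
  b1 <- c(-175, -125)
  b2 <- c(175, 225)
  a1 <- integrate_peak(sp(fid1), freq, b1)
  a2 <- integrate_peak(sp(fid2), freq, b2)
  both1 <- integrate_peak(sp(fid1 + fid2), freq, b1)
  both2 <- integrate_peak(sp(fid1 + fid2), freq, b2)
  # additive up to the heavy 1/|f| magnitude tails of the distant line
  expect_equal(both1, a1, tolerance = 0.05)
  expect_equal(both2, a2, tolerance = 0.06)
})

test_that("Lorentzian fitting recovers line parameters", {
  dwell <- 1e-3
  t_s <- (0:511) * dwell
  # single noiseless line: near-exact recovery
  fid <- 2.3 * exp((2i * pi * 37.3 - 1 / 0.025) * t_s)
  fit <- fit_lorentzians(fid, dwell, data.frame(name = "a", freq_hz = 40))
  expect_equal(fit$amplitude, 2.3, tolerance = 1e-4)
  expect_equal(fit$freq_hz, 37.3, tolerance = 1e-3)
  expect_equal(fit$t2_s, 0.025, tolerance = 1e-3)
  # zero signal: zero amplitudes, flagged converged
  z <- fit_lorentzians(complex(real = numeric(512)), dwell,
                       data.frame(name = "a", freq_hz = 0))
  expect_equal(z$amplitude, 0)
  # two overlapping lines at SNR ~ 50: amplitudes within a few percent
  set.seed(11)
  errs <- replicate(6, {
    f <- 1.0 * exp((2i * pi * -20 - 1 / 0.03) * t_s) +
      0.8 * exp((2i * pi * 15 - 1 / 0.03) * t_s)
    f <- f + complex(real = rnorm(512, 0, 1 / 50), imaginary = rnorm(512, 0, 1 / 50))
    ft <- fit_lorentzians(f, dwell, data.frame(name = c("a", "b"),
                                               freq_hz = c(-22, 17)))
    abs(ft$amplitude - c(1.0, 0.8)) / c(1.0, 0.8)
  })
  expect_lt(mean(errs), 0.02)
  expect_lt(max(errs), 0.06)
  # water-linked linewidth constraint bounds the metabolite linewidths
  f <- 3 * exp((2i * pi * 0 - 1 / 0.030) * t_s) +
    0.5 * exp((2i * pi * -91.7 - 1 / 0.020) * t_s)
  ft <- fit_lorentzians(f, dwell,
                        data.frame(name = c("water", "lac"), freq_hz = c(0, -92)),
                        linewidth_link = list(water = "water", window_hz = 3))
  lw_w <- ft$linewidth_hz[ft$name == "water"]
  lw_l <- ft$linewidth_hz[ft$name == "lac"]
  # window anchored on the water-only prefit, which can drift slightly
  # from the joint-fit water linewidth
  expect_lte(lw_l, lw_w + 3 + 0.5)
  expect_gte(lw_l, lw_w - 3 - 0.5)
})

test_that("suppression and retention metrics match manual oracles and stay invariant", {
  rois <- small_phantom()
  traj <- small_traj(rois)
  model <- lipid_phantom_model(rois)
  bands <- fig2_bands()
  P <- synthesize_dmi(rois, model, traj, n_time = 128)
  zero <- kspace_data(0 * P$values, traj, P$dwell_s)
  # after = before: 0% suppression, 100% retention (exactly)
  s0 <- suppression_percent(P, P, rois, bands)
  expect_lt(max(abs(s0$per_voxel$suppression)), 1e-9)
  r0 <- retention_percent(P, P, rois, bands, "metab")
  expect_lt(max(abs(r0$per_voxel$retention - 100)), 1e-9)
  # after = 0: 100% suppression
  s1 <- suppression_percent(P, zero, rois, bands)
  expect_lt(max(abs(s1$per_voxel$suppression - 100)), 1e-9)
  # global complex phase and scale leave the metrics unchanged
  ph <- 0.7 * exp(0.3i)
  run <- dmislim:::slim_remove_skull(P, slim_compartments(rois))
  a <- suppression_percent(P, run$after, rois, bands)
  b <- suppression_percent(kspace_data(ph * P$values, traj, P$dwell_s),
                           kspace_data(ph * run$after$values, traj, P$dwell_s),
                           rois, bands)
  expect_equal(a$mean, b$mean, tolerance = 1e-9)
  # manual oracle on a 2-voxel toy: per-voxel ratios computed by hand
  sp_b <- fft_reconstruct(P)
  sp_a <- fft_reconstruct(run$after)
  vc <- voxel_classes(rois)
  v <- vc$voxel[vc$skull_containing][1]
  w <- dmislim:::band_window(bands, "lipid")
  manual <- 100 * (1 - integrate_peak(voxel_spectrum(sp_a, v), sp_a$freq_hz, w) /
                     integrate_peak(voxel_spectrum(sp_b, v), sp_b$freq_hz, w))
  expect_equal(a$per_voxel$suppression[a$per_voxel$voxel == v], manual,
               tolerance = 1e-9)
  # degenerate: fully silent data leaves no evaluable voxel
  expect_error(retention_percent(zero, zero, rois, bands, "metab"))
})

test_that("the lactate fraction map handles the degenerate cases", {
  lac <- matrix(c(0, 2, 3, 0), 2, 2)
  glx <- matrix(c(0, 6, 3, 5), 2, 2)
  m <- lac_glx_map(lac, glx)
  expect_true(is.na(m[1, 1]))
  expect_equal(m[2, 1], 0.25)
  expect_equal(m[1, 2], 0.5)
  expect_equal(m[2, 2], 0)
  expect_true(all(lac_glx_map(matrix(0, 2, 2), matrix(1, 2, 2)) == 0))
})
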