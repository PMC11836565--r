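# Forward synthesis of phase-encoded DMI k-space data from an ROI map, a
# spectral line model and optional B0/B1 heterogeneity.

#' Construct a k-space data container
#'
#' @param values complex N_enc x N_time matrix
#' @param traj the `kspace_trajectory` (N_enc rows must match)
#' @param dwell_s dwell time (s); 1 / spectral width
#' @param meta provenance list
#' @return object of class `kspace_data`
#' @export
kspace_data <- function(values, traj, dwell_s, meta = list()) {
  values <- as.matrix(values)
  if (nrow(values) != n_encodings(traj))
    stopf("N_enc mismatch: %d rows vs %d k-vectors", nrow(values), n_encodings(traj))
  structure(list(values = values, traj = traj, dwell_s = dwell_s, meta = meta),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<kspace_data> %d encodings x %d points, sw = %g Hz, scheme %s\n",
              nrow(x$values), ncol(x$values), 1 / x$dwell_s, x$traj$scheme))
  invisible(x)
}

time_axis <- function(n_time, dwell_s) (seq_len(n_time) - 1) * dwell_s

#' Synthesize a DMI k-space dataset
#'
#' Computes P\[m, t\] = sum over object pixels r of B1(r) s_label(r)(t)
#' exp(i 2 pi B0(r) t) exp(i 2 pi k_m . r) dV, with s_k(t) a sum of
#' Lorentzian (exponentially damped) lines, and optionally adds complex
#' circular Gaussian noise of standard deviation `noise_sigma` per entry.
#'
#' @param rois an `roi_map`
#' @param model a `signal_model` covering every compartment present
#' @param traj a `kspace_trajectory`
#' @param b0,b1 optional `field_map`s on the ROI raster
#' @param n_time number of complex time points
#' @param spectral_width_hz spectral width (Hz); dwell = 1 / sw
#' @param noise_sigma noise standard deviation (0 = noiseless)
#' @param seed seed for the noise draw
#' @return a `kspace_data`
#' @export
synthesize_dmi <- function(rois, model, traj, b0 = NULL, b1 = NULL,
                           n_time = 512, spectral_width_hz = 1000,
                           noise_sigma = 0, seed = NULL) {
  labs <- sort(unique(rois$labels[rois$labels > 0L]))
  for (lb in labs) {
    df <- model$lines[[as.character(lb)]]
    if (is.null(df)) stopf("signal model does not cover compartment %d", lb)
    if (any(abs(df$freq_hz) > spectral_width_hz / 2))
      stopf("line at %g Hz outside the +/- %g Hz Nyquist band",
            df$freq_hz[which.max(abs(df$freq_hz))], spectral_width_hz / 2)
  }
  for (fm in list(b0, b1)) {
    if (!is.null(fm) && !all(dim(fm$values) == dim(rois$labels)))
      stopf("field map raster does not match the ROI raster")
  }
  dwell <- 1 / spectral_width_hz
  t_s <- time_axis(n_time, dwell)
  px <- object_pixels(rois)
  fids <- lapply(labs, function(lb) compartment_fid(model, lb, t_s))
  S <- do.call(rbind, fids)[match(px$label, labs), , drop = FALSE]
  b1v <- if (is.null(b1)) rep(1, length(px$idx)) else b1$values[px$idx]
  S <- S * b1v
  if (!is.null(b0)) S <- S * exp(2i * pi * outer(b0$values[px$idx], t_s))
  E <- pixel_phase_matrix(traj, px)
  P <- (E %*% S) * px$area
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    P <- P + noise_sigma * matrix(complex(real = stats::rnorm(length(P)),
                                          imaginary = stats::rnorm(length(P))),
                                  nrow(P), ncol(P))
  }
  kspace_data(P, traj, dwell,
              meta = list(noise_sigma = noise_sigma, seed = seed))
}
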