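# Spectral signal models: per-compartment lists of Lorentzian lines
# (frequency offset in Hz, amplitude per unit volume, T2 in s). A water
# line at 0 Hz is present in all compartments; each compartment carries one
# additional well-resolved line.

#' Construct a signal model
#'
#' @param lines named list: one entry per compartment label (names are the
#'   integer labels as strings), each a data.frame with columns `freq_hz`,
#'   `amp`, `t2_s`.
#' @return object of class `signal_model`
#' @export
signal_model <- function(lines) {
  for (nm in names(lines)) {
    df <- lines[[nm]]
    if (!all(c("freq_hz", "amp", "t2_s") %in% names(df)))
      stopf("compartment %s: lines need freq_hz, amp, t2_s", nm)
    if (any(df$t2_s <= 0)) stopf("compartment %s: T2 must be > 0", nm)
  }
  structure(list(lines = lines), class = "signal_model")
}

model_labels <- function(model) as.integer(names(model$lines))

# Complex FID of one compartment on a time axis.
compartment_fid <- function(model, label, t_s) {
  df <- model$lines[[as.character(label)]]
  if (is.null(df)) stopf("signal model does not cover compartment %d", label)
  s <- complex(real = numeric(length(t_s)))
  for (r in seq_len(nrow(df))) {
    s <- s + df$amp[r] * exp((2i * pi * df$freq_hz[r] - 1 / df$t2_s[r]) * t_s)
  }
  s
}

#' Scale or add signal models
#'
#' `scale_model` multiplies all amplitudes; `add_models` concatenates the
#' line lists of two models defined on the same compartments (synthesis is
#' linear in the model).
#' @param model,a,b `signal_model`s
#' @param factor scalar multiplier
#' @return a `signal_model`
#' @export
scale_model <- function(model, factor) {
  model$lines <- lapply(model$lines, function(df) { df$amp <- df$amp * factor; df })
  model
}

#' @rdname scale_model
#' @export
add_models <- function(a, b) {
  labs <- union(names(a$lines), names(b$lines))
  signal_model(stats::setNames(lapply(labs, function(nm) {
    rbind(a$lines[[nm]], b$lines[[nm]])
  }), labs))
}

#' Standard simulation signal models
#'
#' `lipid_phantom_model`: water (0 Hz) in every compartment, one brain
#' metabolite line shared by all intracranial tissue, and one lipid line in
#' the skull — the configuration of the suppression/retention study.
#' `tissue_phantom_model`: distinct resolved lines for GM, WM, CSF and
#' pathology (plus water everywhere and lipid in skull), used for
#' tissue-specific retention. `pv_phantom_model`: the partial-volume study
#' model — water everywhere, a skull-specific reference plus lipid in the
#' skull, and a tumor-specific reference plus lactate (sharing the lipid
#' frequency) in the pathology, so the lactate-to-reference ratio of an
#' ideal lipid-free dataset is exactly 1 at any partial volume. All
#' amplitudes are per unit volume and equal by default.
#'
#' @param rois `roi_map` whose roles determine the compartments
#' @param t2_s line T2 (s); 30 ms default
#' @param amp amplitude per unit volume
#' @param water_hz,metab_hz,lipid_hz line offsets (Hz)
#' @param compartments optional restriction of labels
#' @return a `signal_model`
#' @export
lipid_phantom_model <- function(rois, t2_s = 0.030, amp = 1,
                                water_hz = 0, metab_hz = -180, lipid_hz = -380) {
  ln <- function(f) data.frame(freq_hz = f, amp = amp, t2_s = t2_s)
  lines <- list()
  for (lb in rois$roles$brain)
    lines[[as.character(lb)]] <- rbind(ln(water_hz), ln(metab_hz))
  for (lb in rois$roles$skull)
    lines[[as.character(lb)]] <- rbind(ln(water_hz), ln(lipid_hz))
  signal_model(lines)
}

#' @rdname lipid_phantom_model
#' @export
tissue_phantom_model <- function(rois, t2_s = 0.030, amp = 1, water_hz = 0,
                                 lipid_hz = -420) {
  ln <- function(f) data.frame(freq_hz = f, amp = amp, t2_s = t2_s)
  tissue_hz <- c(GM = -120, WM = -180, CSF = -240, pathology = -300)
  lines <- list()
  for (rl in names(tissue_hz)) {
    for (lb in rois$roles[[rl]])
      lines[[as.character(lb)]] <- rbind(ln(water_hz), ln(tissue_hz[[rl]]))
  }
  for (lb in rois$roles$skull)
    lines[[as.character(lb)]] <- rbind(ln(water_hz), ln(lipid_hz))
  signal_model(lines)
}

#' @rdname lipid_phantom_model
#' @export
pv_phantom_model <- function(rois, t2_s = 0.030, amp = 1, water_hz = 0,
                             metab_hz = -240, lipid_hz = -380,
                             skull_ref_hz = -120) {
  ln <- function(f) data.frame(freq_hz = f, amp = amp, t2_s = t2_s)
  lines <- list()
  for (lb in setdiff(rois$roles$brain, rois$roles$pathology))
    lines[[as.character(lb)]] <- ln(water_hz)
  for (lb in rois$roles$pathology)
    lines[[as.character(lb)]] <- rbind(ln(water_hz), ln(metab_hz), ln(lipid_hz))
  for (lb in rois$roles$skull)
    lines[[as.character(lb)]] <- rbind(ln(water_hz), ln(skull_ref_hz), ln(lipid_hz))
  signal_model(lines)
}

#' Restrict a model to a subset of compartments (others silenced)
#'
#' @param model a `signal_model`
#' @param labels compartment labels to keep
#' @return a `signal_model` with zero amplitude outside `labels`
#' @export
silence_except <- function(model, labels) {
  keep <- as.character(labels)
  model$lines <- stats::setNames(lapply(names(model$lines), function(nm) {
    df <- model$lines[[nm]]
    if (!nm %in% keep) df$amp <- 0
    df
  }), names(model$lines))
  model
}
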