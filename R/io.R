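# Readers/writers: NIfTI (+ JSON sidecar) for rasters, a JSON array
# container with base64-encoded IEEE doubles for complex k-space data
# (bit-exact round trips), CSV for metrics tables.

SIDECAR_VERSION <- "1"
KSPACE_VERSION <- "1"

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

doubles_to_b64 <- function(x) jsonlite::base64_enc(writeBin(as.double(x), raw(),
                                                            size = 8))
b64_to_doubles <- function(s) {
  r <- jsonlite::base64_dec(s)
  readBin(r, "double", n = length(r) %/% 8L, size = 8)
}

check_keys <- function(obj, keys, what) {
  miss <- setdiff(keys, names(obj))
  if (length(miss))
    stopf("%s: missing key(s) %s (found: %s)", what,
          paste(miss, collapse = ", "), paste(names(obj), collapse = ", "))
}

#' Write / read an ROI map as NIfTI with a JSON sidecar
#'
#' Labels are stored as int16 with mm pixel dimensions; the sidecar records
#' the role mapping, MRSI grid and nominal voxel size. Round trips are
#' bit-identical for the label raster.
#'
#' @param rois an `roi_map`
#' @param path output path (`.nii` or `.nii.gz`); the sidecar goes next to
#'   it with extension `.json`
#' @return `write_roi_map`: the path, invisibly; `read_roi_map`: an `roi_map`
#' @export
write_roi_map <- function(rois, path) {
  img <- RNifti::asNifti(rois$labels, datatype = "int16",
                         reference = list(pixdim = c(-1, rois$pixel_mm,
                                                     rep(1, 5))))
  RNifti::writeNifti(img, path)
  side <- list(schema = "dmislim.roi_map", version = SIDECAR_VERSION,
               grid_dims = rois$grid_dims,
               nominal_voxel_mm = rois$nominal_voxel_mm,
               roles = rois$roles)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_map
#' @export
read_roi_map <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  check_keys(side, c("schema", "version", "grid_dims", "nominal_voxel_mm",
                     "roles"), "ROI sidecar")
  if (!identical(side$schema, "dmislim.roi_map") ||
      !identical(as.character(side$version), SIDECAR_VERSION))
    stopf("ROI sidecar: expected schema dmislim.roi_map v%s, found %s v%s",
          SIDECAR_VERSION, side$schema, side$version)
  roi_map(matrix(as.integer(img), dim(img)[1], dim(img)[2]),
          side$grid_dims, side$nominal_voxel_mm,
          lapply(side$roles, as.integer))
}

#' Write / read a field map as NIfTI float32 with a JSON sidecar
#'
#' Values round-trip within float32 quantization; polynomial coefficients
#' (when present) are stored exactly in the sidecar.
#'
#' @param fm a `field_map`
#' @param path output path
#' @return `write_field_map`: the path, invisibly; `read_field_map`: a
#'   `field_map`
#' @export
write_field_map <- function(fm, path) {
  pd <- fm$pixel_mm %||% c(1, 1)
  img <- RNifti::asNifti(fm$values, datatype = "float",
                         reference = list(pixdim = c(-1, pd, rep(1, 5))))
  RNifti::writeNifti(img, path)
  side <- list(schema = "dmislim.field_map", version = SIDECAR_VERSION,
               kind = fm$kind, units = if (fm$kind == "B0") "Hz" else "relative",
               order = fm$order, pixel_mm = fm$pixel_mm)
  if (!is.null(fm$coeffs))
    side$coeffs <- list(names = names(fm$coeffs),
                        b64 = doubles_to_b64(fm$coeffs))
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field_map
#' @export
read_field_map <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  check_keys(side, c("schema", "version", "kind"), "field-map sidecar")
  cf <- NULL
  if (!is.null(side$coeffs)) {
    cf <- b64_to_doubles(side$coeffs$b64)
    names(cf) <- side$coeffs$names
  }
  field_map(matrix(as.numeric(img), dim(img)[1], dim(img)[2]), side$kind,
            coeffs = cf, order = side$order, pixel_mm = side$pixel_mm)
}

#' Write / read complex k-space data
#'
#' Self-describing JSON container: datasets `kspace` (complex, base64 IEEE
#' doubles, real/imaginary interleaved by plane) and `kvectors`, with
#' attributes `dwell_s`, `spectral_width_hz`, `grid_dims`, `fov_mm`,
#' `scheme` and provenance metadata. Round trips are bitwise exact.
#'
#' @param P a `kspace_data`
#' @param path output path (`.json`)
#' @return `write_kspace`: the path, invisibly; `read_kspace`: a `kspace_data`
#' @export
write_kspace <- function(P, path) {
  obj <- list(
    schema = "dmislim.kspace", version = KSPACE_VERSION,
    n_enc = nrow(P$values), n_time = ncol(P$values),
    dwell_s = P$dwell_s, spectral_width_hz = 1 / P$dwell_s,
    grid_dims = P$traj$grid_dims, fov_mm = P$traj$fov_mm,
    scheme = P$traj$scheme,
    kvectors = doubles_to_b64(P$traj$kvec),
    kspace_re = doubles_to_b64(Re(P$values)),
    kspace_im = doubles_to_b64(Im(P$values)),
    meta = P$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(obj, c("schema", "version", "n_enc", "n_time", "dwell_s",
                    "grid_dims", "fov_mm", "scheme", "kvectors",
                    "kspace_re", "kspace_im"), "k-space container")
  if (!identical(obj$schema, "dmislim.kspace") ||
      !identical(as.character(obj$version), KSPACE_VERSION))
    stopf("k-space container: expected schema dmislim.kspace v%s, found %s v%s",
          KSPACE_VERSION, obj$schema, obj$version)
  traj <- build_trajectory(obj$grid_dims, obj$fov_mm, obj$scheme)
  kv <- matrix(b64_to_doubles(obj$kvectors), ncol = 2)
  if (!isTRUE(all.equal(unname(as.matrix(traj$kvec)), kv)))
    traj$kvec <- kv
  vals <- matrix(complex(real = b64_to_doubles(obj$kspace_re),
                         imaginary = b64_to_doubles(obj$kspace_im)),
                 obj$n_enc, obj$n_time)
  kspace_data(vals, traj, obj$dwell_s, meta = as.list(obj$meta))
}

#' Write a metrics table to CSV
#'
#' @param metrics a `metrics_table` (or any data.frame)
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}
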