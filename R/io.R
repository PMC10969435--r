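#' Write a multiparametric volume to NIfTI files with a manifest
#'
#' Each channel (and, for phantoms, the brain mask and ground-truth masks)
#' is written as a compressed NIfTI-1 file, and a YAML manifest mapping
#' channel names to file paths is written alongside — the hand-off format
#' the imaging pipeline consumes. For phantoms the generating spec is
#' embedded in the manifest so the volume is fully reproducible.
#'
#' @param vol an `mpmri_volume` or `mp_phantom`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"volume"`).
#' @return invisibly, the manifest path.
#' @export
write_volume <- function(vol, dir, prefix = "volume") {
  stopifnot(inherits(vol, "mpmri_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_nifti_array <- function(m) {
    if (length(dim(m)) == 2) array(as.numeric(m), c(dim(m), 1)) else m
  }
  rel <- function(name) paste0(prefix, "_", name, ".nii.gz")
  manifest <- list(channels = list(), voxel_size = as.numeric(vol$voxel_size))
  for (nm in names(vol$channels)) {
    RNifti::writeNifti(as_nifti_array(vol$channels[[nm]]),
                       file.path(dir, rel(nm)))
    manifest$channels[[nm]] <- rel(nm)
  }
  if (!is.null(vol$brain_mask)) {
    RNifti::writeNifti(as_nifti_array(vol$brain_mask + 0L),
                       file.path(dir, rel("brainmask")))
    manifest$brain_mask <- rel("brainmask")
  }
  for (nm in c("lesion_mask", "active_mask")) {
    if (!is.null(vol[[nm]])) {
      RNifti::writeNifti(as_nifti_array(vol[[nm]]), file.path(dir, rel(nm)))
      manifest[[nm]] <- rel(nm)
    }
  }
  if (!is.null(vol$spec)) {
    sp <- vol$spec
    sp$contrast <- as.data.frame(sp$contrast)
    manifest$phantom_spec <- unclass(sp)
  }
  path <- file.path(dir, paste0(prefix, "_manifest.yaml"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a multiparametric volume from a channel manifest
#'
#' Reads the YAML manifest written by [write_volume()] (or assembled by
#' hand: a `channels` map of channel name to NIfTI path, optional
#' `brain_mask` path and `voxel_size`) and loads the referenced NIfTI
#' files. Paths are resolved relative to the manifest location.
#'
#' @param manifest_path path to the YAML manifest.
#' @return an `mpmri_volume`.
#' @export
read_volume <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  load_img <- function(p) {
    a <- RNifti::readNifti(file.path(base, p))
    a <- array(as.numeric(a), dim(a))  # strip NIfTI header attributes
    if (length(dim(a)) == 3 && dim(a)[3] == 1) a <- a[, , 1]
    a
  }
  channels <- lapply(man$channels, load_img)
  mask <- if (!is.null(man$brain_mask)) load_img(man$brain_mask) > 0 else NULL
  vs <- if (!is.null(man$voxel_size)) as.numeric(man$voxel_size) else 1
  mpmri_volume(channels, voxel_size = vs, brain_mask = mask)
}

#' Export a scalar image as a grayscale PNG preview
#'
#' Intensities are linearly rescaled to the unit interval (constant images
#' map to 0). The image is transposed so row/column orientation matches
#' the matrix layout.
#'
#' @param img numeric matrix (e.g. an `embedded_image` or mask).
#' @param path output `.png` path.
#' @return invisibly, `path`.
#' @export
write_png_preview <- function(img, path) {
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  rng <- range(m)
  m <- if (rng[1] == rng[2]) m * 0 else (m - rng[1]) / diff(rng)
  png::writePNG(t(m), path)
  invisible(path)
}

#' Write a provenance record as JSON
#'
#' The pipeline logs every data-dependent decision taken at run time
#' (quantization step, geodesic backend, components bridged, polarity
#' flip, threshold values); this serializes that record next to the
#' result files.
#'
#' @param provenance named list (e.g. `attr(img, "provenance")`).
#' @param path output `.json` path.
#' @return invisibly, `path`.
#' @export
write_provenance <- function(provenance, path) {
  jsonlite::write_json(provenance, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
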