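#' Export k-t sampling masks as NIfTI volumes
#'
#' Writes one integer NIfTI volume per flow segment (dimensions ky, kz,
#' frame, values = sample counts), the layout used to inspect binned
#' sampling patterns. Requires the RNifti package.
#'
#' @param mask a [build_kt_mask()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
export_mask_nifti <- function(mask, dir) {
  stopifnot(inherits(mask, "kt_mask"))
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("package 'RNifti' is required for NIfTI export", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_flow <- dim(mask$counts)[4]
  paths <- character(n_flow)
  for (s in seq_len(n_flow)) {
    paths[s] <- file.path(dir, sprintf("mask_segment%d.nii.gz", s - 1L))
    RNifti::writeNifti(mask$counts[, , , s], paths[s])
  }
  invisible(paths)
}

#' Export a velocity series as NIfTI volumes with sidecar metadata
#'
#' Writes the magnitude and the three velocity-component series as 4D
#' NIfTI volumes (x, y, z, frame; velocities in cm/s) plus a JSON sidecar
#' recording VENC, frame duration and the discard flags. Requires the
#' RNifti package (and jsonlite for the sidecar).
#'
#' @param vel a [velocity_decode()] result.
#' @param dir output directory (created if missing).
#' @param voxel_mm isotropic voxel size recorded in the headers.
#' @return invisibly, the written file paths.
#' @export
export_velocity_nifti <- function(vel, dir, voxel_mm = 0.8) {
  stopifnot(inherits(vel, "velocity_series"))
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("package 'RNifti' is required for NIfTI export", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comps <- c(vx = "vx", vy = "vy", vz = "vz", magnitude = "magnitude")
  paths <- character(0)
  for (nm in names(comps)) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- RNifti::asNifti(vel[[nm]], pixdim = c(rep(voxel_mm, 3), 1))
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  meta <- list(venc_cmps = vel$venc,
               frame_duration_ms = vel$frame_duration,
               n_card = vel$n_card, n_discard = vel$n_discard,
               voxel_mm = voxel_mm)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    mp <- file.path(dir, "velocity.json")
    jsonlite::write_json(meta, mp, auto_unbox = TRUE)
    paths <- c(paths, mp)
  }
  invisible(paths)
}
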