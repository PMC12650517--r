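#' Write / read a volume
#'
#' Volumes are stored either as NIfTI (voxel size in the header) or as flat
#' little-endian float64 binary with a JSON sidecar describing dimensions
#' and voxel size.
#'
#' @param volume 3-D numeric array.
#' @param path output path; extension ".nii"/".nii.gz" selects NIfTI,
#'   anything else flat binary + "<path>.json" sidecar.
#' @param voxel_size isotropic voxel size in cm.
#' @return invisibly, \code{path}.
#' @export
writeVolume <- function(volume, path, voxel_size = 0.634) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume, reference = NULL)
    RNifti::pixdim(img) <- rep(voxel_size * 10, 3)  # NIfTI stores mm
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    writeBin(as.numeric(volume), con, size = 8, endian = "little")
    close(con)
    jsonlite::write_json(list(dim = dim(volume), voxel_size_cm = voxel_size,
                              dtype = "float64", endian = "little"),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    return(array(as.numeric(img), dim(img)))
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  v <- readBin(con, "numeric", n = prod(meta$dim), size = 8,
               endian = "little")
  close(con)
  array(v, meta$dim)
}

#' Write / read a dual-gated volume set
#'
#' One file per (respiratory, cardiac) gate plus a JSON manifest; the
#' attenuation maps (one per respiratory gate) are stored alongside.
#'
#' @param phantom a \linkS4class{GatedPhantom}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
writeGatedSet <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(phantom@activity)
  vox <- phantom@config$voxel_size
  for (r in seq_len(d[4])) {
    writeVolume(phantom@attenuation[, , , r],
                file.path(dir, sprintf("att_r%02d.bin", r)), vox)
    for (k in seq_len(d[5]))
      writeVolume(phantom@activity[, , , r, k],
                  file.path(dir, sprintf("act_r%02d_k%02d.bin", r, k)), vox)
  }
  jsonlite::write_json(list(grid = d[1:3], n_resp_gates = d[4],
                            n_card_gates = d[5], voxel_size_cm = vox),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname writeGatedSet
#' @export
readGatedSet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  R <- meta$n_resp_gates; K <- meta$n_card_gates
  act <- array(0, c(meta$grid, R, K))
  att <- array(0, c(meta$grid, R))
  for (r in seq_len(R)) {
    att[, , , r] <- readVolume(file.path(dir, sprintf("att_r%02d.bin", r)))
    for (k in seq_len(K))
      act[, , , r, k] <- readVolume(
        file.path(dir, sprintf("act_r%02d_k%02d.bin", r, k)))
  }
  list(activity = act, attenuation = att, voxel_size = meta$voxel_size_cm)
}
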