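# NIfTI export/import with a JSON sidecar carrying the SUV calibration and
# generation provenance.

#' Write an ActivityVolume as NIfTI plus JSON sidecar
#'
#' Writes a float32 NIfTI with mm spacings in the header and a `.json`
#' sidecar next to it carrying `suvScale` and any provenance passed in
#' `meta` (seed, spec echo, package version).
#'
#' @param volume an [ActivityVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param meta named list of extra provenance for the sidecar.
#' @return `path`, invisibly.
#' @export
writeActivityVolume <- function(volume, path, meta = list()) {
  g <- volume@grid
  img <- RNifti::asNifti(volume@values)
  RNifti::pixdim(img) <- c(g@dx, g@dy, g@dz)
  RNifti::writeNifti(img, path, datatype = "float")
  sidecar <- c(list(suvScale = volume@suvScale,
                    grid = list(nx = g@nx, ny = g@ny, nz = g@nz,
                                dx = g@dx, dy = g@dy, dz = g@dz),
                    package = as.character(utils::packageVersion("PETsimIQ"))),
               meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ActivityVolume written by [writeActivityVolume()]
#'
#' @param path the NIfTI path; the sidecar is looked up at `paste0(path,
#'   ".json")` (a missing sidecar yields `suvScale = 1`).
#' @return an [ActivityVolume-class].
#' @export
readActivityVolume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  vals <- array(as.numeric(img), dim(img))
  if (length(dim(vals)) == 2L) vals <- array(vals, c(dim(vals), 1L))
  grid <- VoxelGrid(dim(vals)[1], dim(vals)[2], dim(vals)[3],
                    pd[1], pd[2], if (length(pd) >= 3) pd[3] else 1)
  sc <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$suvScale)) sc <- as.numeric(meta$suvScale)
  }
  ActivityVolume(pmax(vals, 0), grid, suvScale = sc)
}
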