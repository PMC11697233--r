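# On-disk formats: multi-page TIFF volumes (32-bit samples, z-major page
# order) with a JSON sidecar carrying voxel size and intensity scale.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a 3D volume as a multi-page 32-bit TIFF
#'
#' Pages are z planes (shallow side first), stored as 32-bit samples
#' normalized to the volume maximum (relative quantization error below
#' 2^-32). Voxel size and the intensity scale are recorded in a JSON
#' sidecar next to the file, so reads restore physical units.
#'
#' @param volume a [volume3d()] or 3D array.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  a <- vol_data(volume)
  storage.mode(a) <- "double"
  if (length(dim(a)) != 3) stop("expected 3D stack")
  # TIFF samples are stored on [0, 1]; keep the physical scale in the sidecar
  scale <- max(a)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(a)[1]), function(iz) {
    m <- a[iz, , ] / scale
    dim(m) <- dim(a)[2:3]
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(voxel_um = vol_voxel(volume),
                            dtype = "uint32-normalized",
                            intensity_scale = scale,
                            shape_zyx = dim(a)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 3D volume from a multi-page TIFF
#'
#' Accepts 8/16-bit unsigned or 32-bit float pages; integer data are
#' promoted to double (the tiff reader scales to [0, 1]; the original
#' bit depth is recorded). A single-page file is rejected.
#'
#' @param path TIFF path; a `path.json` sidecar (if present) restores
#'   voxel size.
#' @return a [volume3d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e)
                      stop("cannot read volume: ", path, " (",
                           conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) stop("expected 3D stack, got a single-page TIFF: ",
                              path)
  if (!is.null(dim(pages[[1]])) && length(dim(pages[[1]])) == 3)
    stop("multi-channel TIFF not supported: ", path)
  d <- c(length(pages), dim(pages[[1]]))
  a <- array(0, d)
  for (iz in seq_along(pages)) a[iz, , ] <- pages[[iz]]
  voxel <- c(0.13, 0.13, 0.13)
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    if (!is.null(meta$voxel_um)) voxel <- as.numeric(meta$voxel_um)
    if (!is.null(meta$intensity_scale)) a <- a * meta$intensity_scale
  }
  volume3d(a, voxel_um = voxel)
}
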