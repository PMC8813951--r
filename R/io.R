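## Plain-text / TIFF serialization of the package's data objects.
## Rasters travel as single-page TIFF (+ CSV fallback), OCT volumes as
## multi-page TIFF, transects and tables as CSV, specs as YAML.

#' Read and write elevation / label rasters as TIFF + CSV sidecar
#'
#' `writeDEM()` stores heights (mm) in a 32-bit float single-page TIFF,
#' with the value scale and pixel size in a small CSV sidecar
#' (`<path>.meta.csv`); `readDEM()` restores the [ElevationMap-class].
#' `writeLabelMap()`/`readLabelMap()` do the same for patch labels
#' (8-bit).
#'
#' @param dem an [ElevationMap-class].
#' @param path file path.
#' @return `readDEM()` returns an [ElevationMap-class]; writers return
#'   the path invisibly.
#' @name raster-io
#' @export
writeDEM <- function(dem, path) {
  ## heights normalized to [0,1] float TIFF; scale kept in the sidecar
  mx <- max(dem@heights, 1e-12)
  tiff::writeTIFF(dem@heights / mx, path, bits.per.sample = 32L,
                  compression = "none")
  writeMeta(path, c(kind = "dem", scale = mx,
                    px_x = dem@pixelMM[1], px_y = dem@pixelMM[2]))
  invisible(path)
}

writeMeta <- function(path, values) {
  write.csv(data.frame(key = names(values), value = unname(values)),
            paste0(path, ".meta.csv"), row.names = FALSE)
}

readMeta <- function(path, kind) {
  mp <- paste0(path, ".meta.csv")
  if (!file.exists(mp)) stop("missing sidecar metadata: ", mp)
  df <- read.csv(mp, colClasses = c("character", "character"))
  v <- setNames(df$value, df$key)
  if (!identical(unname(v[["kind"]]), kind))
    stop("not a biofilmO2 ", kind, " TIFF")
  v
}

#' @rdname raster-io
#' @export
readDEM <- function(path) {
  img <- tiff::readTIFF(path)
  v <- readMeta(path, "dem")
  new("ElevationMap", heights = img * as.numeric(v[["scale"]]),
      pixelMM = as.numeric(c(v[["px_x"]], v[["px_y"]])), origin = c(0, 0))
}

#' @rdname raster-io
#' @param labels a [PatchLabelMap-class].
#' @export
writeLabelMap <- function(labels, path) {
  tiff::writeTIFF(labels@labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  writeMeta(path, c(kind = "labels", px_x = labels@pixelMM[1],
                    px_y = labels@pixelMM[2]))
  invisible(path)
}

#' @rdname raster-io
#' @export
readLabelMap <- function(path) {
  img <- tiff::readTIFF(path)
  v <- readMeta(path, "labels")
  new("PatchLabelMap", labels = matrix(as.integer(round(img * 255)),
                                       nrow(img), ncol(img)),
      pixelMM = as.numeric(c(v[["px_x"]], v[["px_y"]])))
}

#' Read and write OCT volumes as multi-page TIFF
#'
#' One 8-bit page per z slice, bottom (substrate) first; voxel size and
#' substrate index stored in a CSV sidecar.
#'
#' @param volume an [OCTVolume-class].
#' @param path file path.
#' @return `readOCTVolume()` returns an [OCTVolume-class].
#' @name oct-io
#' @export
writeOCTVolume <- function(volume, path) {
  a <- volume@intensity
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  writeMeta(path, c(kind = "oct", vox_x = volume@voxelMM[1],
                    vox_y = volume@voxelMM[2], vox_z = volume@voxelMM[3],
                    substrate = volume@substrateIndex))
  invisible(path)
}

#' @rdname oct-io
#' @export
readOCTVolume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- readMeta(path, "oct")
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) a[, , k] <- round(pages[[k]] * 255)
  new("OCTVolume", intensity = a,
      voxelMM = as.numeric(c(v[["vox_x"]], v[["vox_y"]], v[["vox_z"]])),
      substrateIndex = as.integer(v[["substrate"]]))
}

#' Read and write microprofile transects as CSV
#'
#' Long-format CSV with columns `transect_id`, `profile`, `x_mm`,
#' `z_mm`, `conc_mol_m3`, `light`, `flow`, `patch`, `surface_z_mm`.
#'
#' @param transect a [MicroprofileTransect-class].
#' @param path file path.
#' @param transect_id identifier written to the file.
#' @return `readTransectCSV()` returns a [MicroprofileTransect-class].
#' @name transect-io
#' @export
writeTransectCSV <- function(transect, path, transect_id = "T1") {
  s <- samples(transect)
  surf <- transect@surfaceZ[as.character(s$profile)]
  df <- data.frame(transect_id = transect_id, profile = s$profile,
                   x_mm = s$x_mm, z_mm = s$z_mm, conc_mol_m3 = s$conc,
                   light = transect@light, flow = transect@flow,
                   patch = transect@patch,
                   surface_z_mm = ifelse(is.na(surf), NA, surf))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname transect-io
#' @export
readTransectCSV <- function(path) {
  df <- read.csv(path)
  need <- c("profile", "x_mm", "z_mm", "conc_mol_m3", "light", "flow", "patch")
  if (!all(need %in% names(df))) stop("missing transect CSV columns")
  surf <- tapply(df$surface_z_mm, df$profile, function(v) v[1])
  surf <- surf[!is.na(surf)]
  new("MicroprofileTransect",
      samples = data.frame(profile = df$profile, x_mm = df$x_mm,
                           z_mm = df$z_mm, conc = df$conc_mol_m3),
      light = df$light[1], flow = as.character(df$flow[1]),
      patch = as.character(df$patch[1]),
      surfaceZ = if (length(surf)) setNames(as.numeric(surf), names(surf))
                 else numeric(0),
      metadata = list(source = path))
}

#' Write a gradient field as CSV
#'
#' Columns: x_mm, z_mm, conc, grad_mag, grad_angle_deg.
#'
#' @param field data.frame from [triangulateField()].
#' @param path file path.
#' @export
writeGradientCSV <- function(field, path) {
  write.csv(field, path, row.names = FALSE)
  invisible(path)
}
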