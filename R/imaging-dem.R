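#' Extract a digital elevation model from an OCT volume
#'
#' Per A-scan column, the biofilm surface is the highest voxel above the
#' intensity threshold; height is surface minus substrate plane, clipped
#' at zero. The substrate plane is either given or detected as the
#' z slice of maximum mean intensity within the lowest quartile of the
#' volume (the highly reflective substrate). A 2D median filter of size
#' 4 pixels denoises the raw DEM (disable with `median_size = 0`, e.g.
#' for voxel-exact round-trip checks).
#'
#' @param volume an [OCTVolume-class].
#' @param intensity_threshold gray level above which a voxel counts as
#'   biomass surface (default 130, the upper segmentation threshold).
#' @param substrate_plane optional z index of the substrate; `NULL`
#'   autodetects.
#' @param median_size median filter size in pixels (0 disables).
#' @return An [ElevationMap-class]; the number of columns with no voxel
#'   above threshold (height set to 0) is reported via attribute
#'   `"n_empty_columns"`.
#' @export
extractDEM <- function(volume, intensity_threshold = 130,
                       substrate_plane = NULL, median_size = 4L) {
  a <- volume@intensity
  d <- dim(a)
  nz <- d[3]
  if (is.null(substrate_plane)) {
    lower <- 1:max(1L, floor(nz / 4))
    means <- vapply(lower, function(k) mean(a[, , k]), numeric(1))
    substrate_plane <- lower[which.max(means)]
  }
  search <- a[, , (substrate_plane + 1L):nz, drop = FALSE] > intensity_threshold
  ## highest TRUE slice per column
  ns <- dim(search)[3]
  top <- matrix(0L, d[1], d[2])
  for (k in seq_len(ns))
    top[search[, , k]] <- k
  empty <- sum(top == 0L)
  h <- top * volume@voxelMM[3]
  if (median_size >= 2L) h <- medianFilterMM(h, median_size)
  dem <- new("ElevationMap", heights = h, pixelMM = volume@voxelMM[1:2],
             origin = c(0, 0))
  attr(dem, "n_empty_columns") <- empty
  dem
}

## Median filter of a non-negative mm-valued raster using EBImage
## (which operates on [0,1] grayscale); size n means an n x n window
## (EBImage takes the half-size).
medianFilterMM <- function(h, size) {
  mx <- max(h)
  if (mx == 0) return(h)
  hs <- EBImage::medianFilter(h / mx, max(1L, size %/% 2L))
  hs * mx
}

#' Stitch DEM tiles acquired in a mosaic pattern
#'
#' Translation-based mosaic of equally sized tiles on a regular grid
#' with fractional overlap (the study acquired 6 x 6 OCT scans with 30%
#' overlap); overlapping pixels are averaged. Tile t(r, c) is placed at
#' offset ((r-1) step_x, (c-1) step_y) with step = round(size * (1 -
#' overlap)).
#'
#' @param tiles list of [ElevationMap-class] tiles, in row-major order
#'   of `grid_layout`.
#' @param grid_layout integer length-2: tiles per (row, column).
#' @param overlap_fraction fractional overlap between neighbours.
#' @return The stitched [ElevationMap-class].
#' @export
stitchTiles <- function(tiles, grid_layout, overlap_fraction = 0.30) {
  stopifnot(length(tiles) == prod(grid_layout))
  dims <- lapply(tiles, function(t) dim(t@heights))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("tiles must share the same shape")
  px <- tiles[[1]]@pixelMM
  tn <- dims[[1]]
  step <- round(tn * (1 - overlap_fraction))
  nr <- grid_layout[1]; nc <- grid_layout[2]
  out_dim <- c(step[1] * (nr - 1L) + tn[1], step[2] * (nc - 1L) + tn[2])
  acc <- matrix(0, out_dim[1], out_dim[2])
  cnt <- matrix(0, out_dim[1], out_dim[2])
  t_i <- 1L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    ri <- (r - 1L) * step[1] + seq_len(tn[1])
    ci <- (c - 1L) * step[2] + seq_len(tn[2])
    acc[ri, ci] <- acc[ri, ci] + tiles[[t_i]]@heights
    cnt[ri, ci] <- cnt[ri, ci] + 1
    t_i <- t_i + 1L
  }
  new("ElevationMap", heights = acc / cnt, pixelMM = px, origin = c(0, 0))
}

#' Median thickness and inter-quantile range
#'
#' Median and inter-quantile range (q0.8 - q0.2) of DEM heights over a
#' mask.
#'
#' @param dem an [ElevationMap-class].
#' @param mask logical matrix (default: all pixels).
#' @return named numeric: `median_mm`, `iqr_mm`.
#' @export
thicknessStats <- function(dem, mask = NULL) {
  h <- dem@heights
  if (is.null(mask)) mask <- matrix(TRUE, nrow(h), ncol(h))
  v <- h[mask]
  if (!length(v)) stop("empty mask")
  q <- quantile(v, c(0.2, 0.8), names = FALSE, type = 7)
  c(median_mm = median(v), iqr_mm = q[2] - q[1])
}

#' Biovolume beneath the DEM surface
#'
#' Volume beneath the biofilm surface: the sum of DEM heights times the
#' pixel area (no internal voids are subtracted).
#'
#' @param dem an [ElevationMap-class].
#' @param mask logical matrix (default: all pixels).
#' @return volume in mm3.
#' @export
#' @examples
#' dem <- new("ElevationMap", heights = matrix(1, 10, 10),
#'            pixelMM = c(1, 1), origin = c(0, 0))
#' biovolume(dem)  # 100 mm3
biovolume <- function(dem, mask = NULL) {
  h <- dem@heights
  if (is.null(mask)) mask <- matrix(TRUE, nrow(h), ncol(h))
  sum(h[mask]) * prod(dem@pixelMM)
}
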