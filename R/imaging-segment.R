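#' Segment biofilm patch types from a macrophotograph
#'
#' Classifies pixels into the three patch types from coloration: DDP by
#' thresholding the red/green channel ratio, then KDP by thresholding a
#' combination of the green channel and a local mean filter of the same
#' channel; the remainder is CDB. Small objects and holes are removed by
#' connected-component filtering, and the KDP mask is dilated by
#' `dilation_px` to capture the diffuse filament fringe. Masks are
#' disjoint, with KDP taking precedence over DDP.
#'
#' Thresholds default to Otsu's criterion on the respective feature
#' image (a reproducible parameter-free choice); both are overridable.
#'
#' @param rgb numeric array nx x ny x 3 in [0, 1].
#' @param ddp_rg_threshold red/green ratio above which a pixel is DDP;
#'   `NULL` = Otsu on the ratio image.
#' @param kdp_green_threshold green-feature value above which a pixel is
#'   KDP; `NULL` = Otsu on the feature image.
#' @param local_mean_radius radius (px) of the local mean filter on the
#'   green channel.
#' @param min_object_px connected components smaller than this are
#'   discarded (and holes smaller than this are filled).
#' @param dilation_px dilation radius applied to the KDP mask.
#' @param pixel_mm pixel size (mm) recorded in the output.
#' @return A [PatchLabelMap-class]. An image with no DDP/KDP evidence
#'   yields an all-CDB map with a warning.
#' @export
segmentPatches <- function(rgb, ddp_rg_threshold = NULL,
                           kdp_green_threshold = NULL,
                           local_mean_radius = 5L, min_object_px = 25L,
                           dilation_px = 5L, pixel_mm = c(0.1, 0.1)) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] >= 3)
  R <- rgb[, , 1]; G <- rgb[, , 2]
  nx <- nrow(R); ny <- ncol(R)

  ratio <- R / pmax(G, 1e-6)
  ratio01 <- pmin(ratio / 3, 1)          # compress to [0,1] for Otsu
  if (is.null(ddp_rg_threshold)) {
    ddp_rg_threshold <- 3 * EBImage::otsu(ratio01)
  }
  ddp <- ratio > ddp_rg_threshold

  gmean <- EBImage::filter2(G, EBImage::makeBrush(2L * local_mean_radius + 1L,
                                                  "disc") |> normalizeBrush())
  gfeat <- (G + gmean) / 2
  if (is.null(kdp_green_threshold)) {
    kdp_green_threshold <- EBImage::otsu(pmin(pmax(gfeat, 0), 1))
  }
  kdp <- gfeat > kdp_green_threshold

  ddp <- cleanMask(ddp, min_object_px)
  kdp <- cleanMask(kdp, min_object_px)
  if (dilation_px > 0 && any(kdp))
    kdp <- EBImage::dilate(kdp * 1, EBImage::makeBrush(
      2L * dilation_px + 1L, "disc")) > 0

  lab <- matrix(PATCH_LEVELS[["CDB"]], nx, ny)
  lab[ddp] <- PATCH_LEVELS[["DDP"]]
  lab[kdp] <- PATCH_LEVELS[["KDP"]]    # KDP precedence
  if (!any(ddp) && !any(kdp))
    warning("no DDP/KDP evidence; returning all-CDB map")
  new("PatchLabelMap", labels = lab, pixelMM = pixel_mm)
}

normalizeBrush <- function(b) b / sum(b)

## Remove small connected components and fill small holes.
cleanMask <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  cc <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(cc[cc > 0])
  keep <- which(sizes >= min_px)
  m <- matrix(cc %in% keep, nrow(mask), ncol(mask))
  ## fill holes smaller than min_px: label background components
  inv <- EBImage::bwlabel((!m) * 1)
  bsz <- tabulate(inv[inv > 0])
  holes <- which(bsz < min_px)
  m[matrix(inv %in% holes, nrow(mask), ncol(mask))] <- TRUE
  m
}

#' Per-patch geometry statistics
#'
#' Landscape summary per patch type: area (mm2), areal coverage (%),
#' biovolume (mm3), volume share (%), and mean and SD of surface height
#' (mm); percentages are relative to the biofilm totals, so coverages
#' and volume shares each sum to 100.
#'
#' @param dem an [ElevationMap-class].
#' @param labels the paired [PatchLabelMap-class].
#' @return data.frame with one row per patch type plus a `landscape`
#'   total row. Missing classes report zeros.
#' @export
patchGeometry <- function(dem, labels) {
  stopifnot(identical(dim(dem@heights), dim(labels@labels)))
  px_area <- prod(dem@pixelMM)
  lab <- labels@labels
  h <- dem@heights
  rows <- lapply(names(PATCH_LEVELS), function(nm) {
    m <- lab == PATCH_LEVELS[[nm]]
    n <- sum(m)
    data.frame(patch = nm,
               area_mm2 = n * px_area,
               volume_mm3 = sum(h[m]) * px_area,
               height_mean_mm = if (n) mean(h[m]) else 0,
               height_sd_mm = if (n > 1) sd(h[m]) else 0)
  })
  out <- do.call(rbind, rows)
  tot_a <- sum(out$area_mm2); tot_v <- sum(out$volume_mm3)
  out$coverage_pct <- if (tot_a > 0) 100 * out$area_mm2 / tot_a else 0
  out$volume_pct <- if (tot_v > 0) 100 * out$volume_mm3 / tot_v else 0
  land <- data.frame(patch = "landscape", area_mm2 = tot_a,
                     volume_mm3 = tot_v,
                     height_mean_mm = if (tot_a > 0) sum(h[lab > 0]) / (tot_a / px_area) else 0,
                     height_sd_mm = if (tot_a > 0) sd(h[lab > 0]) else 0,
                     coverage_pct = if (tot_a > 0) 100 else 0,
                     volume_pct = if (tot_v > 0) 100 else 0)
  rbind(out[, c("patch", "area_mm2", "coverage_pct", "volume_mm3",
                "volume_pct", "height_mean_mm", "height_sd_mm")],
        land[, c("patch", "area_mm2", "coverage_pct", "volume_mm3",
                 "volume_pct", "height_mean_mm", "height_sd_mm")])
}
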