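#' Apparent porosity per patch type from an OCT volume
#'
#' Estimates internal porosity as the void fraction (void voxels / total
#' voxels) in the sub-surface top layer of each column: gray levels
#' above a threshold are biomass, below it void. Because the threshold
#' choice is somewhat arbitrary and OCT intensity decays with depth, the
#' analysis runs over two gray thresholds (120, 130) and two layer
#' thicknesses (0.1, 0.2 mm); the spread over the four settings
#' quantifies the estimation uncertainty. Columns protruding beyond the
#' instrument's reliable imaging depth (`max_height_mm`) are excluded.
#'
#' Void fraction is the reading consistent with the filamentous,
#' loosely packed patch type (KDP) having the highest porosity.
#'
#' @param volume an [OCTVolume-class].
#' @param dem the aligned [ElevationMap-class] (defines the surface).
#' @param labels the [PatchLabelMap-class].
#' @param gray_thresholds two gray levels separating void from biomass.
#' @param layer_depths_mm top-layer thicknesses analyzed (mm).
#' @param max_height_mm columns taller than this are excluded.
#' @return data.frame: per patch type the median column porosity for
#'   each (threshold, layer) setting, the central estimate (mean of the
#'   four medians), and the min-max band. Patch types with no eligible
#'   columns error.
#' @export
porosity <- function(volume, dem, labels, gray_thresholds = c(120, 130),
                     layer_depths_mm = c(0.1, 0.2), max_height_mm = 1.2) {
  a <- volume@intensity
  h <- dem@heights
  lab <- labels@labels
  stopifnot(identical(dim(h), dim(a)[1:2]), identical(dim(h), dim(lab)))
  axial <- volume@voxelMM[3]
  nz <- dim(a)[3]
  ksub <- volume@substrateIndex
  surf_k <- ksub + round(h / axial)

  present <- names(PATCH_LEVELS)[PATCH_LEVELS %in% lab]
  rows <- list()
  for (nm in present) {
    sel <- lab == PATCH_LEVELS[[nm]] & h <= max_height_mm & h > 0
    if (!any(sel))
      stop(sprintf("no eligible columns for patch type %s", nm))
    idx <- which(sel, arr.ind = TRUE)
    med <- matrix(NA_real_, length(gray_thresholds), length(layer_depths_mm))
    for (ti in seq_along(gray_thresholds)) for (li in seq_along(layer_depths_mm)) {
      nlay <- max(1L, round(layer_depths_mm[li] / axial))
      pcol <- numeric(nrow(idx))
      for (r in seq_len(nrow(idx))) {
        ## sample the interior layer strictly below the surface voxel
        ## (the surface voxel delimits the biofilm, it is not interior)
        ks <- min(surf_k[idx[r, 1], idx[r, 2]], nz) - 1L
        k1 <- max(ksub + 1L, ks - nlay + 1L)
        if (ks < k1) { ks <- k1 }
        v <- a[idx[r, 1], idx[r, 2], k1:ks]
        pcol[r] <- mean(v < gray_thresholds[ti])
      }
      med[ti, li] <- median(pcol)
    }
    settings <- as.data.frame(as.list(as.numeric(med)))
    names(settings) <- as.character(outer(gray_thresholds, layer_depths_mm,
                                          function(t, l)
                                            sprintf("thr%g_lay%g", t, l)))
    rows[[nm]] <- cbind(data.frame(patch = nm, porosity = mean(med),
                                   min = min(med), max = max(med)),
                        settings)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
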