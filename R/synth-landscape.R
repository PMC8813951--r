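#' Landscape generator specification
#'
#' Parameters of the synthetic biofilm landscape generator. Per patch
#' type a target mean/SD of surface height (mm), an areal coverage
#' fraction, and a target internal porosity are given. The CDB base
#' layer fills whatever the discrete patches (DDP, KDP) do not cover.
#' Defaults reproduce the slow-flow landscape statistics of the flume
#' study (heights 0.39/0.58/1.09 mm, coverages 0.70/0.20/0.098,
#' porosities 0.36/0.47/0.58 for CDB/DDP/KDP).
#'
#' @param domain_size_mm numeric length-2, landscape extent (mm).
#' @param pixel_mm raster resolution (mm per pixel).
#' @param patch_params named list (CDB, DDP, KDP) of lists with
#'   `mean_height_mm`, `sd_height_mm`, `coverage`, `porosity`.
#' @param seed integer seed; every generator draw derives from it.
#' @return A validated list of class `LandscapeSpec`.
#' @export
#' @examples
#' sp <- landscapeSpec(domain_size_mm = c(10, 10), seed = 1)
landscapeSpec <- function(domain_size_mm = c(45, 45), pixel_mm = 0.1,
                          patch_params = list(
                            CDB = list(mean_height_mm = 0.39, sd_height_mm = 0.15,
                                       coverage = NA, porosity = 0.36),
                            DDP = list(mean_height_mm = 0.58, sd_height_mm = 0.15,
                                       coverage = 0.20, porosity = 0.47),
                            KDP = list(mean_height_mm = 1.09, sd_height_mm = 0.24,
                                       coverage = 0.098, porosity = 0.58)),
                          seed = 1L) {
  stopifnot(length(domain_size_mm) == 2, all(domain_size_mm > 0),
            pixel_mm > 0)
  if (!all(c("CDB", "DDP", "KDP") %in% names(patch_params)))
    stop("patch_params must contain CDB, DDP and KDP entries")
  cov <- vapply(patch_params[c("DDP", "KDP")],
                function(p) p$coverage, numeric(1))
  if (any(cov < 0 | cov > 1) || sum(cov) > 1)
    stop("DDP/KDP coverage fractions must lie in [0,1] and sum to <= 1")
  for (nm in names(patch_params)) {
    p <- patch_params[[nm]]
    if (p$mean_height_mm < 0 || p$sd_height_mm < 0)
      stop("heights must be non-negative")
    if (!is.na(p$porosity) && (p$porosity < 0 || p$porosity > 1))
      stop("porosity must lie in [0,1]")
  }
  structure(list(domain_size_mm = domain_size_mm, pixel_mm = pixel_mm,
                 patch_params = patch_params, seed = as.integer(seed)),
            class = "LandscapeSpec")
}

## Smoothed standardized Gaussian random field on an nx x ny lattice.
randomField <- function(nx, ny, sigma_px) {
  f <- matrix(rnorm(nx * ny), nx, ny)
  f <- smoothMatrix(f, sigma_px)
  (f - mean(f)) / sd(f)
}

#' Generate a synthetic biofilm landscape
#'
#' Places DDP and KDP patches as Gaussian-smoothed thresholded noise
#' blobs on a CDB base (KDP takes precedence where blobs overlap) and
#' draws per-type surface heights as spatially correlated fields with
#' the requested mean and SD, clipped at a small positive floor.
#' Thresholding at the coverage quantile realizes the target coverages
#' exactly at pixel resolution; realized per-type mean heights track the
#' targets well within 10%.
#'
#' @param spec a [landscapeSpec()] object.
#' @return list with `dem` ([ElevationMap-class]) and `labels`
#'   ([PatchLabelMap-class]); identical output for identical seeds.
#' @export
#' @examples
#' ls <- genLandscape(landscapeSpec(domain_size_mm = c(8, 8), seed = 7))
#' ls$labels
genLandscape <- function(spec) {
  stopifnot(inherits(spec, "LandscapeSpec"))
  nx <- round(spec$domain_size_mm[1] / spec$pixel_mm)
  ny <- round(spec$domain_size_mm[2] / spec$pixel_mm)
  if (nx < 4 || ny < 4)
    stop("coverage infeasible at given resolution: raster smaller than 4 px")
  pp <- spec$patch_params
  for (nm in c("DDP", "KDP")) {
    cv <- pp[[nm]]$coverage
    if (cv > 0 && cv * nx * ny < 1)
      stop(sprintf("coverage infeasible at given resolution: %s target %.3g covers < 1 pixel",
                   nm, cv))
  }
  set.seed(spec$seed)
  blob_sigma <- max(2, 1 / spec$pixel_mm)   # ~1 mm correlation length

  ## KDP first (it takes precedence), then DDP on the remaining pixels
  ## with the threshold quantile taken among those pixels, so realized
  ## coverages match the targets exactly at pixel resolution
  labels <- matrix(PATCH_LEVELS[["CDB"]], nx, ny)
  cv_k <- pp[["KDP"]]$coverage
  if (cv_k > 0) {
    f <- randomField(nx, ny, blob_sigma)
    labels[f > quantile(f, 1 - cv_k, names = FALSE)] <- PATCH_LEVELS[["KDP"]]
  }
  cv_d <- pp[["DDP"]]$coverage
  if (cv_d > 0) {
    f <- randomField(nx, ny, blob_sigma)
    open_px <- labels != PATCH_LEVELS[["KDP"]]
    q <- 1 - cv_d * length(labels) / sum(open_px)
    if (q < 0) stop("coverage infeasible: DDP target exceeds non-KDP area")
    thr <- quantile(f[open_px], q, names = FALSE)
    labels[f > thr & open_px] <- PATCH_LEVELS[["DDP"]]
  }

  h <- matrix(0, nx, ny)
  hfield_sigma <- max(2, 0.5 / spec$pixel_mm)
  for (nm in c("CDB", "DDP", "KDP")) {
    m <- labels == PATCH_LEVELS[[nm]]
    if (!any(m)) next
    f <- randomField(nx, ny, hfield_sigma)
    f[m] <- standardize(f[m])          # per-type mean/SD hit exactly pre-clip
    h[m] <- pp[[nm]]$mean_height_mm + pp[[nm]]$sd_height_mm * f[m]
  }
  h <- pmax(h, 0.01)

  dem <- new("ElevationMap", heights = h,
             pixelMM = rep(spec$pixel_mm, 2), origin = c(0, 0))
  lab <- new("PatchLabelMap", labels = labels,
             pixelMM = rep(spec$pixel_mm, 2))
  list(dem = dem, labels = lab)
}

#' Generate an OCT-like intensity volume from a landscape
#'
#' Builds a gray-level volume consistent with the imaging conventions
#' used downstream: a bright substrate plane at the bottom slice,
#' sub-surface voxels drawn as biomass (gray > 130) or void (gray < 120)
#' with per-type void fraction equal to the target porosity, low
#'-intensity noise above the surface, and the voxel at the surface
#' itself always biomass (the surface is defined by biomass). A mild
#' depth decay of biomass intensity imitates OCT signal attenuation.
#'
#' @param dem an [ElevationMap-class].
#' @param labels the paired [PatchLabelMap-class].
#' @param spec the [landscapeSpec()] carrying per-type target porosities.
#' @param axial_mm axial (z) voxel size in mm; the nominal instrument
#'   resolution is 0.00218 mm, coarser values keep synthetic volumes
#'   small.
#' @param max_height_mm height of the imaged volume above the substrate.
#' @param seed integer; deterministic per seed.
#' @return An [OCTVolume-class].
#' @export
genOCTVolume <- function(dem, labels, spec, axial_mm = 0.01,
                         max_height_mm = NULL, seed = spec$seed + 1L) {
  h <- dem@heights
  lab <- labels@labels
  stopifnot(identical(dim(h), dim(lab)))
  if (is.null(max_height_mm)) max_height_mm <- max(h) + 0.1
  nz <- ceiling(max_height_mm / axial_mm) + 1L   # slice 1 = substrate
  nx <- nrow(h); ny <- ncol(h)
  set.seed(seed)

  vol <- array(0, dim = c(nx, ny, nz))
  vol[, , 1] <- 250                               # reflective substrate
  noise <- array(runif(nx * ny * (nz - 1L), 0, 50), c(nx, ny, nz - 1L))
  vol[, , -1] <- noise

  por <- vapply(names(PATCH_LEVELS), function(nm)
    spec$patch_params[[nm]]$porosity, numeric(1))
  surf_k <- 1L + pmax(round(h / axial_mm), 1L)    # surface slice per column
  surf_k <- pmin(surf_k, nz)
  p_void <- matrix(por[pmax(lab, 1L)], nx, ny)
  p_void[lab == 0L] <- 0
  for (k in 2:nz) {
    below <- surf_k >= k
    if (!any(below)) next
    isvoid <- below & (matrix(runif(nx * ny), nx, ny) < p_void)
    isbio <- below & !isvoid
    isbio[surf_k == k] <- below[surf_k == k]      # surface voxel is biomass
    decay <- exp(-0.2 * (k - 2) * axial_mm / 0.5) # gentle attenuation
    gb <- 140 + (90 * decay) * runif(sum(isbio))
    vol[, , k][isbio] <- gb
    vol[, , k][isvoid & !isbio] <- runif(sum(isvoid & !isbio), 40, 110)
  }
  new("OCTVolume", intensity = vol,
      voxelMM = c(dem@pixelMM, axial_mm), substrateIndex = 1L)
}

#' Generate a macrophotograph-like RGB image
#'
#' Renders the label map as an RGB raster with the coloration contrasts
#' the segmentation relies on: DDP pixels have an elevated red/green
#' ratio (brownish diatom mats), KDP pixels an elevated green channel
#' (green filamentous algae), CDB a dull dark base; additive Gaussian
#' pixel noise on all channels. Deterministic per seed.
#'
#' @param dem an [ElevationMap-class] (adds mild brightness shading by
#'   height).
#' @param labels a [PatchLabelMap-class].
#' @param seed integer seed.
#' @param noise_sd Gaussian channel noise SD (image in [0,1]).
#' @return numeric array nx x ny x 3 in [0, 1].
#' @export
genMacrophoto <- function(dem, labels, seed = 1L, noise_sd = 0.03) {
  lab <- labels@labels
  nx <- nrow(lab); ny <- ncol(lab)
  set.seed(seed)
  base <- list(
    `0` = c(0.25, 0.28, 0.30),   # background: bare substrate
    `1` = c(0.35, 0.45, 0.30),   # CDB
    `2` = c(0.55, 0.34, 0.22),   # DDP: red/green ratio ~1.6
    `3` = c(0.30, 0.65, 0.28))   # KDP: bright green
  img <- array(0, c(nx, ny, 3))
  for (ch in 1:3) {
    chan <- matrix(0, nx, ny)
    for (code in names(base)) chan[lab == as.integer(code)] <- base[[code]][ch]
    img[, , ch] <- chan
  }
  shade <- 1 + 0.05 * standardize(as.numeric(dem@heights))
  for (ch in 1:3)
    img[, , ch] <- img[, , ch] * matrix(shade, nx, ny) +
      rnorm(nx * ny, 0, noise_sd)
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}
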