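test_that("landscape generator hits coverage and height targets and is deterministic", {
  fx <- smallLandscape()
  lab <- labelMatrix(fx$labels)
  h <- heights(fx$dem)
  pp <- fx$spec$patch_params

  ## coverages: thresholding at the coverage quantile is exact for
  ## DDP/KDP; CDB fills the remainder
  expect_equal(mean(lab == patchLevels()[["DDP"]]), pp$DDP$coverage,
               tolerance = 1e-6)
  expect_equal(mean(lab == patchLevels()[["KDP"]]), pp$KDP$coverage,
               tolerance = 1e-6)
  expect_true(all(lab %in% patchLevels()))   # partition, no background

  ## realized per-type mean heights within 10% of the targets
  for (nm in c("CDB", "DDP", "KDP")) {
    m <- lab == patchLevels()[[nm]]
    expect_lt(abs(mean(h[m]) - pp[[nm]]$mean_height_mm) /
                pp[[nm]]$mean_height_mm, 0.10)
    expect_lt(abs(sd(h[m]) - pp[[nm]]$sd_height_mm) /
                pp[[nm]]$sd_height_mm, 0.10)
  }

  ## determinism: same spec + seed -> bit-identical rasters
  again <- genLandscape(fx$spec)
  expect_identical(heights(again$dem), h)
  expect_identical(labelMatrix(again$labels), lab)
})

test_that("zero KDP coverage yields a landscape without KDP pixels", {
  spec <- landscapeSpec(domain_size_mm = c(5, 5), pixel_mm = 0.1, seed = 3L,
    patch_params = list(
      CDB = list(mean_height_mm = 0.39, sd_height_mm = 0.15,
                 coverage = NA, porosity = 0.36),
      DDP = list(mean_height_mm = 0.58, sd_height_mm = 0.15,
                 coverage = 0.2, porosity = 0.47),
      KDP = list(mean_height_mm = 1.09, sd_height_mm = 0.24,
                 coverage = 0, porosity = 0.58)))
  ls <- genLandscape(spec)
  expect_false(any(labelMatrix(ls$labels) == patchLevels()[["KDP"]]))
})

test_that("infeasible coverage at the raster resolution is rejected", {
  spec <- landscapeSpec(domain_size_mm = c(1, 1), pixel_mm = 0.1, seed = 1L,
    patch_params = list(
      CDB = list(mean_height_mm = 0.39, sd_height_mm = 0.15,
                 coverage = NA, porosity = 0.36),
      DDP = list(mean_height_mm = 0.58, sd_height_mm = 0.15,
                 coverage = 0, porosity = 0.47),
      KDP = list(mean_height_mm = 1.09, sd_height_mm = 0.24,
                 coverage = 0.005, porosity = 0.58)))
  expect_error(genLandscape(spec), "infeasible")
})

test_that("OCT volume generator matches the gray-level conventions", {
  fx <- smallVolume()
  a <- fx$vol@intensity
  h <- heights(fx$dem)
  axial <- fx$vol@voxelMM[3]
  expect_true(all(a[, , 1] == 250))             # substrate plane
  ## above-surface voxels are low-intensity noise (below both thresholds)
  surf_k <- 1L + pmax(round(h / axial), 1L)
  for (k in c(dim(a)[3] - 1L, dim(a)[3])) {
    above <- surf_k < k
    expect_true(all(a[, , k][above] < 120))
  }
  ## round trip through the two-threshold porosity estimator:
  ## targets 0.36 / 0.47 / 0.58 recovered within 0.05
  dem_rec <- extractDEM(fx$vol, median_size = 0)
  por <- porosity(fx$vol, dem_rec, fx$labels)
  target <- c(CDB = 0.36, DDP = 0.47, KDP = 0.58)
  for (j in seq_len(nrow(por)))
    expect_lt(abs(por$porosity[j] - target[[por$patch[j]]]), 0.05 + 1e-9)
})

test_that("zero target porosity produces all-biomass interiors", {
  spec <- landscapeSpec(domain_size_mm = c(3, 3), pixel_mm = 0.1, seed = 5L,
    patch_params = list(
      CDB = list(mean_height_mm = 0.5, sd_height_mm = 0.1,
                 coverage = NA, porosity = 0),
      DDP = list(mean_height_mm = 0.58, sd_height_mm = 0.15,
                 coverage = 0, porosity = 0),
      KDP = list(mean_height_mm = 1.09, sd_height_mm = 0.24,
                 coverage = 0, porosity = 0)))
  ls <- genLandscape(spec)
  vol <- genOCTVolume(ls$dem, ls$labels, spec, axial_mm = 0.01)
  a <- vol@intensity
  h <- heights(ls$dem)
  surf_k <- 1L + pmax(round(h / 0.01), 1L)
  for (k in 2:dim(a)[3]) {
    below <- surf_k >= k
    if (any(below)) expect_true(all(a[, , k][below] > 130))
  }
})

test_that("macrophotograph generator is deterministic with class-specific coloration", {
  fx <- smallLandscape()
  img1 <- genMacrophoto(fx$dem, fx$labels, seed = 5L)
  img2 <- genMacrophoto(fx$dem, fx$labels, seed = 5L)
  expect_identical(img1, img2)
  lab <- labelMatrix(fx$labels)
  rg <- img1[, , 1] / pmax(img1[, , 2], 1e-6)
  expect_gt(median(rg[lab == patchLevels()[["DDP"]]]),
            median(rg[lab == patchLevels()[["CDB"]]]))
  expect_gt(median(img1[, , 2][lab == patchLevels()[["KDP"]]]),
            median(img1[, , 2][lab == patchLevels()[["CDB"]]]))

  ## all-CDB landscape: no pixel reaches the DDP red/green criterion
  ## used on images with real DDP contrast
  lab_cdb <- new("PatchLabelMap",
                 labels = matrix(patchLevels()[["CDB"]], 40, 40),
                 pixelMM = c(0.1, 0.1))
  dem_cdb <- new("ElevationMap", heights = matrix(0.4, 40, 40),
                 pixelMM = c(0.1, 0.1), origin = c(0, 0))
  img_cdb <- genMacrophoto(dem_cdb, lab_cdb, seed = 2L)
  rg_cdb <- img_cdb[, , 1] / pmax(img_cdb[, , 2], 1e-6)
  expect_true(all(rg_cdb < 1.4))   # DDP ratio is ~1.6
})

test_that("inlet profile generator round-trips through the quadratic fit", {
  pts <- genInletProfile(0.13, n_points = 10L, seed = 1L, noise_sd = 0)
  f <- fitInletProfile(pts)
  expect_lt(max(abs(f(pts$z) - pts$u)), 1e-10)

  pts14 <- genInletProfile(0.06, n_points = 14L, seed = 2L)
  expect_identical(nrow(pts14), 14L)
  expect_true(all(pts14$z <= 0.005 + 1e-12))

  still <- genInletProfile(0, n_points = 5L, seed = 3L, noise_sd = 0)
  expect_true(all(still$u == 0))
  expect_error(genInletProfile(0.1, n_points = 2L))
})

test_that("noise-free forward transects equal the interpolated field", {
  p <- makeModelParams(rate = -1e-3)
  dom <- buildDomain(rep(0.5, 20), width_m = 0.004, nx = 20, nz = 32)
  fl <- zeroFlow(dom, p)
  tr <- genO2Transect(dom, p, noise = sensorNoiseSpec(sigma_conc = 0),
                      light = FALSE, flow = fl,
                      x_mm = c(1, 2, 3), z_range_mm = c(0.05, 2))
  cf <- solveTransport(dom, fl, p, rate = -1e-3, inlet_conc = 0.3)
  g <- biofilmO2:::domainGeometry(dom)
  s <- samples(tr)
  direct <- biofilmO2:::bilinearInterp(g$xc, g$zc, concMatrix(cf),
                                       s$x_mm / 1000, s$z_mm / 1000)
  expect_lt(max(abs(s$conc - direct)), 1e-12 * max(abs(direct)))

  ## consumption sign: dark minimum inside the biofilm <= bulk
  expect_lte(min(s$conc), 0.3)
  expect_identical(tr@metadata$rate, -1e-3)

  ## z spacing is the sensor step
  expect_equal(unique(round(diff(s$z_mm[s$profile == "P01"]), 10)), 0.05)
})
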