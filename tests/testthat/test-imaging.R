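test_that("DEM extraction: noise-only volumes give zero height, synthetic volumes round-trip", {
  ## pure background noise below threshold -> all-zero DEM
  set.seed(1)
  noise <- array(runif(20 * 20 * 30, 0, 50), c(20, 20, 30))
  noise[, , 1] <- 250
  vol0 <- new("OCTVolume", intensity = noise, voxelMM = c(0.1, 0.1, 0.01),
              substrateIndex = 1L)
  dem0 <- extractDEM(vol0, median_size = 0)
  expect_true(all(heights(dem0) == 0))
  expect_identical(attr(dem0, "n_empty_columns"), 400L)

  ## synthetic volume from a known DEM -> recovered within one axial voxel
  fx <- smallVolume()
  dem_rec <- extractDEM(fx$vol, median_size = 0)
  expect_lt(max(abs(heights(dem_rec) - heights(fx$dem))),
            fx$vol@voxelMM[3] + 1e-12)

  ## substrate autodetection agrees with the stored plane
  expect_identical(extractDEM(fx$vol, substrate_plane = 1L,
                              median_size = 0)@heights, dem_rec@heights)
})

test_that("size-4 median filter removes single-column spikes", {
  h <- matrix(0.4, 20, 20)
  h[10, 10] <- 2.0
  dem <- new("ElevationMap", heights = h, pixelMM = c(0.1, 0.1),
             origin = c(0, 0))
  filtered <- biofilmO2:::medianFilterMM(h, 4L)
  expect_equal(filtered[10, 10], 0.4, tolerance = 1e-6)
  expect_equal(filtered[3, 3], 0.4, tolerance = 1e-6)
})

test_that("stitching: identity for 1x1, exact reconstruction for 2x2 cuts, shape check", {
  fx <- smallLandscape()
  big <- fx$dem
  expect_identical(stitchTiles(list(big), c(1, 1))@heights, big@heights)

  ov <- 0.30; tilesz <- 58L
  step <- round(tilesz * (1 - ov))
  tiles <- list()
  for (r in 1:2) for (cc in 1:2) {
    ri <- (r - 1L) * step + seq_len(tilesz)
    ci <- (cc - 1L) * step + seq_len(tilesz)
    tiles[[length(tiles) + 1L]] <- new("ElevationMap",
      heights = big@heights[ri, ci], pixelMM = big@pixelMM, origin = c(0, 0))
  }
  st <- stitchTiles(tiles, c(2, 2), ov)
  ref <- big@heights[seq_len(nrow(st@heights)), seq_len(ncol(st@heights))]
  expect_equal(st@heights, ref, tolerance = 1e-12)

  tiles[[2]] <- new("ElevationMap", heights = big@heights[1:10, 1:10],
                    pixelMM = big@pixelMM, origin = c(0, 0))
  expect_error(stitchTiles(tiles, c(2, 2), ov), "shape")
})

test_that("thickness statistics follow direct-sorting quantiles and translation equivariance", {
  demc <- new("ElevationMap", heights = matrix(0.7, 5, 5),
              pixelMM = c(1, 1), origin = c(0, 0))
  expect_equal(unname(thicknessStats(demc)), c(0.7, 0))

  h <- matrix(1:10, 2, 5)
  dem <- new("ElevationMap", heights = h * 1.0, pixelMM = c(1, 1),
             origin = c(0, 0))
  v <- sort(as.numeric(h))
  q <- quantile(v, c(0.2, 0.8), names = FALSE)
  ts <- thicknessStats(dem)
  expect_equal(unname(ts[1]), median(v))
  expect_equal(unname(ts[2]), q[2] - q[1])

  dem2 <- new("ElevationMap", heights = h + 3, pixelMM = c(1, 1),
              origin = c(0, 0))
  ts2 <- thicknessStats(dem2)
  expect_equal(unname(ts2[1]), unname(ts[1]) + 3)
  expect_equal(unname(ts2[2]), unname(ts[2]))

  expect_error(thicknessStats(dem, mask = matrix(FALSE, 2, 5)), "empty")
})

test_that("biovolume is sum of heights times pixel area, linear and additive", {
  dem <- new("ElevationMap", heights = matrix(1, 10, 10), pixelMM = c(1, 1),
             origin = c(0, 0))
  expect_equal(biovolume(dem), 100)
  expect_equal(biovolume(dem, matrix(FALSE, 10, 10)), 0)

  fx <- smallLandscape()
  m1 <- labelMatrix(fx$labels) == 1L
  m2 <- !m1
  expect_equal(biovolume(fx$dem, m1) + biovolume(fx$dem, m2),
               biovolume(fx$dem))
  dem2 <- new("ElevationMap", heights = 2 * heights(fx$dem),
              pixelMM = fx$dem@pixelMM, origin = c(0, 0))
  expect_equal(biovolume(dem2), 2 * biovolume(fx$dem))
})

test_that("segmentation recovers generated patch classes (IoU >= 0.8)", {
  fx <- smallLandscape()
  img <- genMacrophoto(fx$dem, fx$labels, seed = 5L)
  ## no dilation against the generating mask: the dilation step exists
  ## to capture the diffuse filament fringe of real photographs, which
  ## synthetic images do not have
  seg <- segmentPatches(img, dilation_px = 0L, pixel_mm = c(0.1, 0.1))
  lab <- labelMatrix(fx$labels)
  for (nm in c("CDB", "DDP", "KDP")) {
    a <- lab == patchLevels()[[nm]]
    b <- labelMatrix(seg) == patchLevels()[[nm]]
    expect_gte(sum(a & b) / sum(a | b), 0.8)
  }
})

test_that("segmentation degenerate and morphology properties", {
  ## uniform image -> single class (all CDB) with warning
  uni <- array(0.4, c(30, 30, 3))
  expect_warning(seg <- segmentPatches(uni, ddp_rg_threshold = 1.4,
                                       kdp_green_threshold = 0.55),
                 "all-CDB")
  expect_true(all(labelMatrix(seg) == patchLevels()[["CDB"]]))

  ## KDP area is non-decreasing under dilation
  fx <- smallLandscape()
  img <- genMacrophoto(fx$dem, fx$labels, seed = 5L)
  k0 <- sum(labelMatrix(segmentPatches(img, dilation_px = 0L)) == 3L)
  k5 <- sum(labelMatrix(segmentPatches(img, dilation_px = 5L)) == 3L)
  expect_gte(k5, k0)
})

test_that("patch geometry percentages normalize and reproduce coverage arithmetic", {
  fx <- smallLandscape()
  geo <- patchGeometry(fx$dem, fx$labels)
  patches <- geo[geo$patch != "landscape", ]
  expect_equal(sum(patches$coverage_pct), 100, tolerance = 1e-9)
  expect_equal(sum(patches$volume_pct), 100, tolerance = 0.1)
  ## area * mean height = volume per class
  expect_equal(patches$volume_mm3,
               patches$area_mm2 * patches$height_mean_mm, tolerance = 0.01)

  ## single class covering everything
  lab1 <- new("PatchLabelMap", labels = matrix(1L, 10, 10),
              pixelMM = c(1, 1))
  dem1 <- new("ElevationMap", heights = matrix(0.5, 10, 10),
              pixelMM = c(1, 1), origin = c(0, 0))
  g1 <- patchGeometry(dem1, lab1)
  expect_equal(g1$coverage_pct[g1$patch == "CDB"], 100)
  expect_equal(g1$volume_pct[g1$patch == "CDB"], 100)
  expect_equal(g1$area_mm2[g1$patch == "DDP"], 0)

  ## KDP coverage arithmetic of the study landscape: 197 / 2016 -> 9.8%
  expect_equal(round(100 * 197 / 2016, 1), 9.8)
})

test_that("porosity estimator is exact on counted constructions", {
  ## construction: 30% of interior voxels below both thresholds
  nx <- 10L; ny <- 10L; nlay <- 20L
  a <- array(200, c(nx, ny, nlay + 2L))
  a[, , 1] <- 250
  set.seed(9)
  for (i in 1:nx) for (j in 1:ny) {
    void <- sample(nlay, 6L)              # exactly 30% of 20 interior slices
    a[i, j, 1L + void] <- 60
  }
  ## surface voxel (top slice) stays biomass
  vol <- new("OCTVolume", intensity = a, voxelMM = c(0.1, 0.1, 0.01),
             substrateIndex = 1L)
  dem <- new("ElevationMap", heights = matrix((nlay + 1L) * 0.01, nx, ny),
             pixelMM = c(0.1, 0.1), origin = c(0, 0))
  lab <- new("PatchLabelMap", labels = matrix(1L, nx, ny),
             pixelMM = c(0.1, 0.1))
  p <- porosity(vol, dem, lab,
                gray_thresholds = c(120, 130), layer_depths_mm = c(0.2, 0.2),
                max_height_mm = 1.2)
  expect_equal(p$porosity[p$patch == "CDB"], 0.30, tolerance = 1e-12)

  ## all interior voxels biomass -> porosity 0 for both thresholds
  a0 <- array(200, c(4, 4, 12)); a0[, , 1] <- 250
  vol0 <- new("OCTVolume", intensity = a0, voxelMM = c(0.1, 0.1, 0.01),
              substrateIndex = 1L)
  dem0 <- new("ElevationMap", heights = matrix(0.1, 4, 4),
              pixelMM = c(0.1, 0.1), origin = c(0, 0))
  lab0 <- new("PatchLabelMap", labels = matrix(1L, 4, 4),
              pixelMM = c(0.1, 0.1))
  p0 <- porosity(vol0, dem0, lab0)
  expect_equal(p0$porosity[p0$patch == "CDB"], 0)
  expect_equal(p0$min[1], p0$max[1])

  ## exactly half the layer voxels at gray 0 -> 0.5 for both thresholds
  a5 <- array(200, c(4, 4, 22)); a5[, , 1] <- 250
  a5[, , seq(2, 20, by = 2)] <- 0
  vol5 <- new("OCTVolume", intensity = a5, voxelMM = c(0.1, 0.1, 0.01),
              substrateIndex = 1L)
  dem5 <- new("ElevationMap", heights = matrix(0.21, 4, 4),
              pixelMM = c(0.1, 0.1), origin = c(0, 0))
  p5 <- porosity(vol5, dem5, lab0, layer_depths_mm = c(0.2, 0.2))
  expect_equal(p5$porosity[p5$patch == "CDB"], 0.5, tolerance = 1e-12)
  expect_equal(p5$min[1], p5$max[1])

  ## porosity is monotone non-increasing in the gray threshold applied
  ## to the biomass criterion (void criterion: gray < threshold)
  fx <- smallVolume()
  dem_rec <- extractDEM(fx$vol, median_size = 0)
  pp <- porosity(fx$vol, dem_rec, fx$labels)
  expect_true(all(pp[["thr120_lay0.2"]] <= pp[["thr130_lay0.2"]]))

  ## error when a class has no eligible columns
  lab_mix <- new("PatchLabelMap",
                 labels = matrix(c(1L, 2L), 4, 4), pixelMM = c(0.1, 0.1))
  tall <- new("ElevationMap", heights = matrix(2.0, 4, 4),
              pixelMM = c(0.1, 0.1), origin = c(0, 0))
  expect_error(porosity(vol0, tall, lab_mix), "no eligible columns")
})
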