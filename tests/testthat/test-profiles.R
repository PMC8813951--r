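test_that("linear calibration maps the calibration points and is affine", {
  expect_equal(calibrateLinear(10, 100, 10, 0.3), 0)
  expect_equal(calibrateLinear(100, 100, 10, 0.3), 0.3)
  expect_equal(calibrateLinear(55, 100, 10, 0.3), 0.15)
  ## order preserving
  x <- c(20, 40, 80)
  y <- calibrateLinear(x, 100, 10, 0.3)
  expect_true(all(diff(y) > 0))
  expect_error(calibrateLinear(5, 50, 50, 0.3), "differ")
})

test_that("drift correction rescales by interpolated bulk concentration", {
  ## constant bulk readings -> identity
  v <- c(0.25, 0.28, 0.30)
  expect_equal(driftCorrect(c(1, 2, 3), v, c(0, 4), c(0.3, 0.3)), v)

  ## +10% linear drift over the run: mid-run samples divided by 1.05
  t <- c(0, 5, 10)
  vals <- c(1, 1, 1)
  out <- driftCorrect(t, vals, bulk_times = c(0, 10),
                      bulk_values = c(0.3, 0.33), ref_bulk = 0.3)
  expect_equal(out[2], 1 / 1.05)
  expect_equal(out[1], 1)
  expect_equal(out[3], 1 / 1.1)

  expect_equal(driftCorrect(numeric(0), numeric(0), c(0, 1), c(1, 1)),
               numeric(0))
  expect_error(driftCorrect(c(5), c(1), c(0, 4), c(1, 1)), "bracket")
})

test_that("surface location finds kinks and falls back on flat profiles", {
  z <- seq(0, 2, by = 0.05)
  ## piecewise-linear profile with a single kink at z = 0.8
  kink <- function(z) ifelse(z < 0.8, 0.1 + 0.05 * z, 0.14 + 0.2 * (z - 0.8))
  pl <- data.frame(z_mm = z, conc = kink(z))
  expect_lt(abs(locateSurface(pl, pl, oct_height_mm = 0.85) - 0.8),
            0.05 + 1e-9)   # within one sensor step of the kink

  ## flat profile -> OCT height with warning
  flat <- data.frame(z_mm = z, conc = rep(0.3, length(z)))
  expect_warning(s <- locateSurface(flat, flat, oct_height_mm = 0.7),
                 "OCT height")
  expect_equal(s, 0.7)

  ## window outside the profile -> fallback with warning
  expect_warning(s2 <- locateSurface(pl, pl, oct_height_mm = 5),
                 "OCT height")
  expect_equal(s2, 5)
})

test_that("surface location recovers the generator surface within one sensor step", {
  p <- makeModelParams(rate = -2e-3, diffRatio = 0.6)
  dom <- buildDomain(rep(0.6, 20), width_m = 0.004, nx = 20, nz = 48)
  fl <- solveFlow(dom, p, inlet = quadraticInlet(0.1), advection = FALSE)
  mk <- function(light) genO2Transect(
    dom, p, noise = sensorNoiseSpec(sigma_conc = 0), light = light,
    flow = fl, x_mm = c(2), z_range_mm = c(0.05, 1.5))
  dark <- mk(FALSE); light <- mk(TRUE)
  sd_ <- samples(dark); sl <- samples(light)
  est <- locateSurface(data.frame(z_mm = sl$z_mm, conc = sl$conc),
                       data.frame(z_mm = sd_$z_mm, conc = sd_$conc),
                       oct_height_mm = 0.6)
  expect_lt(abs(est - 0.6), 0.05 + 1e-9)
})

test_that("triangulated gradients are exact for affine fields", {
  zz <- seq(0.05, 0.5, by = 0.05)
  s <- expand.grid(x_mm = c(0, 1, 2), z_mm = zz)
  s$conc <- 2 * s$x_mm + 3 * s$z_mm + 0.1
  s$profile <- sprintf("P%d", match(s$x_mm, c(0, 1, 2)))
  s <- s[order(s$profile, s$z_mm), ]
  tr <- new("MicroprofileTransect", samples = s, light = FALSE,
            flow = "slow", patch = "CDB", surfaceZ = numeric(0),
            metadata = list())
  gf <- triangulateField(tr)
  expect_equal(gf$grad_mag, rep(sqrt(4 + 9), nrow(gf)), tolerance = 1e-10)
  ## -grad c = (-2, -3): upstream and downward -> angle in (90, 180)
  ang <- unique(round(gf$grad_angle_deg, 8))
  expect_length(ang, 1)
  expect_equal(ang, (atan2(3, -2) * 180 / pi) %% 360)

  ## constant field -> zero magnitude everywhere
  s2 <- s; s2$conc <- 0.25
  tr2 <- new("MicroprofileTransect", samples = s2, light = FALSE,
             flow = "slow", patch = "CDB", surfaceZ = numeric(0),
             metadata = list())
  gf2 <- triangulateField(tr2)
  expect_lt(max(gf2$grad_mag), 1e-12)

  ## single profile (collinear points) -> error
  s3 <- s[s$profile == "P1", ]
  tr3 <- new("MicroprofileTransect", samples = s3, light = FALSE,
             flow = "slow", patch = "CDB", surfaceZ = numeric(0),
             metadata = list())
  expect_error(triangulateField(tr3), "collinear|>= 2")
})

test_that("dark gradient angles: ~90 deg when diffusive, > 90 on the depleted rear flank", {
  ## diffusion-dominated dark slab: transport directed at the substrate
  p <- makeModelParams(rate = -1e-3)
  dom <- buildDomain(rep(0.6, 16), width_m = 0.004, nx = 16, nz = 40)
  fl0 <- zeroFlow(dom, p)
  tr0 <- genO2Transect(dom, p, noise = sensorNoiseSpec(sigma_conc = 0),
                       light = FALSE, flow = fl0,
                       x_mm = seq(1, 3, by = 0.5), z_range_mm = c(0.05, 1))
  gf0 <- triangulateField(tr0)
  below0 <- gf0$z_mm < 0.6
  expect_equal(median(gf0$grad_angle_deg[below0]), 90, tolerance = 0.02)

  ## advection-dominated KDP-like patch, dark: downstream O2 depletion
  ## bends gradients against the flow (> 90 deg) on the rear flank
  pk <- makeModelParams(rate = -2e-3, permeability = 2e-10,
                        porosity = 0.86, diffRatio = 0.9)
  elev <- bumpElevation(48)
  domk <- buildDomain(elev, width_m = 0.006, nx = 48, nz = 48)
  trk <- genO2Transect(domk, pk, noise = sensorNoiseSpec(sigma_conc = 0),
                       light = FALSE, inlet = quadraticInlet(0.13),
                       x_mm = seq(3.6, 5.0, by = 0.35),
                       z_range_mm = c(0.05, 1.2))
  gfk <- triangulateField(trk)
  surf <- approx(seq(0, 6, length.out = 48), elev, xout = gfk$x_mm,
                 rule = 2)$y
  belowk <- gfk$z_mm < surf
  expect_gt(median(gfk$grad_angle_deg[belowk]), 90)
})

test_that("pooling keeps only below-surface samples and partitions groups", {
  mk <- function(patch, light, flow, surf, zs, conc) {
    s <- data.frame(profile = "P01", x_mm = 1, z_mm = zs, conc = conc)
    new("MicroprofileTransect", samples = s, light = light, flow = flow,
        patch = patch, surfaceZ = c(P01 = surf), metadata = list())
  }
  z <- seq(0.05, 1, by = 0.05)
  trs <- list(
    mk("CDB", FALSE, "slow", 0.52, z, rep(0.1, length(z))),  # 10 below
    mk("CDB", TRUE, "slow", 0.27, z, rep(0.2, length(z))),   # 5 below
    mk("KDP", FALSE, "slow", 1.02, z, rep(0.3, length(z))),  # 20 below
    mk("DDP", FALSE, "slow", 0.01, z, rep(0.4, length(z))))  # all above
  pooled <- poolDistributions(trs)
  sm <- pooled$summary
  expect_equal(sm$n[sm$patch == "CDB" & !sm$light], 10)
  expect_equal(sm$n[sm$patch == "CDB" & sm$light], 5)
  expect_equal(sm$n[sm$patch == "KDP"], 20)
  expect_false("DDP" %in% sm$patch)             # empty group
  expect_equal(nrow(pooled$samples), 35)        # groups partition samples
  expect_equal(sum(sm$n), nrow(pooled$samples))
})
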