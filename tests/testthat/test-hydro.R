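test_that("domain builder: indicator areas match the elevation profile", {
  ## flat zero -> pure free flow
  d0 <- buildDomain(rep(0, 10), width_m = 0.004, nx = 10, nz = 16)
  expect_false(any(d0@biofilm))

  ## flat slab of 0.4 mm -> area = width x 0.4 mm
  ds <- buildDomain(rep(0.4, 10), width_m = 0.004, nx = 10, nz = 40)
  expect_equal(biofilmArea(ds), 0.004 * 4e-4, tolerance = 0.015)

  ## bump profile: area equals the trapezoid integral within 0.5%
  x <- seq(0, 6, length.out = 120)
  elev <- 0.3 + 1.1 * exp(-((x - 3) / 0.8)^2)
  db <- buildDomain(elev, width_m = 0.006, nx = 120, nz = 120)
  trap <- sum((elev[-1] + elev[-120]) / 2 * diff(x)) / 1e6
  expect_lt(abs(biofilmArea(db) - trap) / trap, 0.005)

  ## clipping warning
  expect_warning(buildDomain(rep(6, 10), width_m = 0.004, nx = 10, nz = 16),
                 "clip")
})

test_that("half-Poiseuille channel oracle matches the closed form to 0.5%", {
  p <- makeModelParams(eddyVisc = 0)
  dom <- buildDomain(rep(0, 8), width_m = 0.002, nx = 8, nz = 64)
  G <- 0.1   # Pa/m pressure gradient, applied as body force
  fl <- solveFlow(dom, p, inlet = list(type = "pressure", p = 0),
                  outlet_pressure = 0, forcing_x = G / p@rho,
                  advection = FALSE)
  g <- biofilmO2:::domainGeometry(dom)
  H <- max(g$zf)
  uex <- (G / (p@rho * p@nu)) * (H * g$zc - g$zc^2 / 2)
  umid <- (velocityU(fl)[4, ] + velocityU(fl)[5, ]) / 2
  expect_lt(max(abs(umid - uex)) / max(uex), 0.005)
  expect_lt(fl@diagnostics$continuity_residual, 1e-6)

  ## wall shear from the same flow equals mu du/dz at the wall = G H
  ws <- wallShearDBL(fl)
  expect_equal(ws$tau, G * H, tolerance = 0.01)
})

test_that("Darcy slab oracle: permeability-controlled seepage to 1%", {
  p <- makeModelParams(eddyVisc = 0, permeability = 1e-10, porosity = 0.5)
  dom <- buildDomain(rep(5, 8), width_m = 0.002, height_m = 0.005,
                     nx = 8, nz = 64)   # fully porous
  dp <- 1.0
  fl <- solveFlow(dom, p, inlet = list(type = "pressure", p = dp),
                  advection = FALSE)
  u_darcy <- p@permeability / (p@rho * p@nu) * dp / 0.002
  umid <- (velocityU(fl)[4, 32] + velocityU(fl)[5, 32]) / 2
  expect_lt(abs(umid - u_darcy) / u_darcy, 0.01)

  ## interior mean speed equals the Darcy velocity
  ivs <- internalVelocityStats(fl)
  expect_equal(ivs$mean_speed, u_darcy, tolerance = 0.02)

  ## insensitivity to the Brinkman effective-viscosity porosity at low K
  p2 <- makeModelParams(eddyVisc = 0, permeability = 1e-10, porosity = 0.9)
  fl2 <- solveFlow(dom, p2, inlet = list(type = "pressure", p = dp),
                   advection = FALSE)
  umid2 <- (velocityU(fl2)[4, 32] + velocityU(fl2)[5, 32]) / 2
  expect_equal(umid2, umid, tolerance = 0.01)
})

test_that("zero inlet velocity with no forcing gives a zero field", {
  p <- makeModelParams(eddyVisc = 0)
  dom <- buildDomain(rep(0.4, 8), width_m = 0.002, nx = 8, nz = 32)
  fl <- solveFlow(dom, p, inlet = list(type = "velocity",
                                       profile = function(z) 0 * z),
                  advection = FALSE)
  expect_equal(max(abs(velocityU(fl)), abs(velocityW(fl))), 0)
})

test_that("1D reaction-diffusion column matches the parabolic closed form to 0.5%", {
  L <- 5e-4; r <- 1e-3; c0 <- 0.3; Deff <- 2e-9
  p <- makeModelParams(diffRatio = 1, Daq = Deff, eddyVisc = 0)
  dom <- buildDomain(rep(L * 1000, 4), width_m = 4e-4, height_m = L,
                     nx = 4, nz = 64)
  fl <- zeroFlow(dom, p)
  bc <- list(inlet = "zeroflux", outlet = "zeroflux",
             top = list(type = "dirichlet", value = c0), bottom = "zeroflux")
  cf <- solveTransport(dom, fl, p, rate = -r, bc = bc)
  g <- biofilmO2:::domainGeometry(dom)
  cex <- c0 - (r / (2 * Deff)) * (L^2 - g$zc^2)
  expect_lt(max(abs(concMatrix(cf)[2, ] - cex)) / c0, 0.005)
  expect_equal(concMatrix(cf)[2, 1], 0.2375, tolerance = 0.002)

  ## steady-state scalar balance: integrated source = boundary flux
  bal <- scalarBalance(cf, fl, bc = bc)
  expect_lt(bal$rel_err, 0.01)

  ## linearity: doubling R doubles the concentration deficit
  cf2 <- solveTransport(dom, fl, p, rate = -2 * r, bc = bc)
  expect_equal(c0 - concMatrix(cf2), 2 * (c0 - concMatrix(cf)),
               tolerance = 1e-8)

  ## R = 0 with uniform boundary concentration -> constant field
  cfc <- solveTransport(dom, fl, p, rate = 0, bc = bc)
  expect_equal(concMatrix(cfc), matrix(c0, 4, 64), tolerance = 1e-10)
})

test_that("advective runs conserve mass and scalar balance on a biofilm patch", {
  p <- makeModelParams(rate = -1e-3, porosity = 0.58, permeability = 1e-10,
                       diffRatio = 0.8)
  dom <- buildDomain(bumpElevation(40), width_m = 0.006, nx = 40, nz = 44)
  fl <- solveFlow(dom, p, inlet = quadraticInlet(0.1), advection = TRUE)
  expect_lt(fl@diagnostics$continuity_residual, 1e-6)
  expect_lt(fl@diagnostics$net_flow_imbalance, 1e-6)
  cf <- solveTransport(dom, fl, p, rate = -1e-3, inlet_conc = 0.3)
  bal <- scalarBalance(cf, fl, inlet_conc = 0.3)
  expect_lt(bal$rel_err, 0.01)
  ## dark consumption: minimum concentration within the bulk value
  expect_lte(min(concMatrix(cf)), 0.3)
  expect_gt(min(concMatrix(cf)), 0)
})

test_that("grid refinement changes the biofilm-mean concentration by < 1%", {
  p <- makeModelParams(rate = -1e-3, porosity = 0.58, permeability = 1e-10,
                       diffRatio = 0.8)
  mean_conc <- function(nx, nz) {
    dom <- buildDomain(bumpElevation(64), width_m = 0.006, nx = nx, nz = nz)
    fl <- solveFlow(dom, p, inlet = quadraticInlet(0.1), advection = FALSE)
    cf <- solveTransport(dom, fl, p, rate = -1e-3, inlet_conc = 0.3)
    mean(concMatrix(cf)[dom@biofilm])
  }
  c1 <- mean_conc(32, 36)
  c2 <- mean_conc(64, 72)
  expect_lt(abs(c2 - c1) / abs(c2), 0.01)
})

test_that("flux decomposition: trivial limits and hand arithmetic", {
  p <- makeModelParams(rate = -1e-3, diffRatio = 0.8)
  dom <- buildDomain(rep(0.5, 10), width_m = 0.004, nx = 10, nz = 24)
  fl0 <- zeroFlow(dom, p)
  cf <- solveTransport(dom, fl0, p, rate = -1e-3,
                       bc = list(inlet = "zeroflux", outlet = "zeroflux",
                                 top = list(type = "dirichlet", value = 0.3),
                                 bottom = "zeroflux"))
  fd0 <- fluxDecomposition(fl0, cf)
  expect_true(all(fd0$ratio[is.finite(fd0$ratio)] == 0))
  expect_equal(fd0$biofilm_mean, 0)

  ## Jc/Jd = |u c| / |D_eff grad c|: 1e-4 * 0.25 / (1.4e-9 * 100) = 1.79e2
  expect_equal((1e-4 * 0.25) / (1.4e-9 * 100), 178.57, tolerance = 1e-3)

  ## homogeneity: scaling c (and hence grad c) leaves ratios unchanged
  cf2 <- new("ConcField", conc = 2 * concMatrix(cf), domain = dom,
             params = p, rate = -2e-3, diagnostics = list())
  ufield <- matrix(1e-4, 11, 24)
  flu <- new("FlowField", u = ufield, w = matrix(0, 10, 25),
             p = matrix(0, 10, 24), domain = dom, params = p,
             diagnostics = list(continuity_residual = 0))
  r1 <- fluxDecomposition(flu, cf)$ratio
  r2 <- fluxDecomposition(flu, cf2)$ratio
  expect_equal(r1[is.finite(r1)], r2[is.finite(r2)], tolerance = 1e-9)
})

test_that("friction-velocity chain follows the stated arithmetic", {
  fs <- frictionScales(1e-2, rho = 1000)
  expect_equal(fs$u_star, 3.1623e-3, tolerance = 1e-4)
  fs2 <- frictionScales(tau = 1000 * (1e-2)^2, rho = 1000, nu = 1e-6,
                        Daq = 1e-6 / 400)   # u* = 1e-2, Sc = 400
  expect_equal(fs2$delta, 1e-4, tolerance = 1e-10)
  expect_equal(fs2$dbl_scale, 5e-6, tolerance = 1e-10)
})

test_that("viscous length scale thins as friction velocity grows (delta = nu/u*)", {
  p <- makeModelParams(eddyVisc = 0)
  dom <- buildDomain(rep(0, 8), width_m = 0.002, nx = 8, nz = 64)
  delta_for <- function(G) {
    fl <- solveFlow(dom, p, inlet = list(type = "pressure", p = 0),
                    forcing_x = G / p@rho, advection = FALSE)
    wallShearDBL(fl)$delta
  }
  expect_gt(delta_for(0.05), delta_for(0.4))

  ## sublayer profile is reported and positive where defined
  fl <- solveFlow(dom, p, inlet = list(type = "pressure", p = 0),
                  forcing_x = 0.1 / p@rho, advection = FALSE)
  sub <- internalVelocityStats(fl)$sublayer_profile
  expect_true(all(sub[!is.na(sub)] > 0))
})
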