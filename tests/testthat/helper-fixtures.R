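## Shared fixtures, built in code at test time.

quadraticInlet <- function(u_bulk, h = 0.005) {
  list(type = "velocity",
       profile = function(z) u_bulk * (2 * z / h - (z / h)^2))
}

## A quiescent flow field on a domain (for pure-diffusion problems).
zeroFlow <- function(domain, params) {
  nx <- length(domain@xf) - 1L; nz <- length(domain@zf) - 1L
  new("FlowField", u = matrix(0, nx + 1L, nz), w = matrix(0, nx, nz + 1L),
      p = matrix(0, nx, nz), domain = domain, params = params,
      diagnostics = list(continuity_residual = 0))
}

## KDP-like protruding patch on a thin base layer.
bumpElevation <- function(n = 48, base = 0.3, height = 1.1, centre = 3,
                          width = 0.9, span = 6) {
  x <- seq(0, span, length.out = n)
  base + height * exp(-((x - centre) / width)^2)
}

## Small landscape shared by imaging tests (cached per session).
.fixture_env <- new.env(parent = emptyenv())
smallLandscape <- function() {
  if (is.null(.fixture_env$ls)) {
    spec <- landscapeSpec(domain_size_mm = c(20, 20), pixel_mm = 0.1,
                          seed = 42L)
    .fixture_env$spec <- spec
    .fixture_env$ls <- genLandscape(spec)
  }
  list(spec = .fixture_env$spec, dem = .fixture_env$ls$dem,
       labels = .fixture_env$ls$labels)
}

smallVolume <- function() {
  if (is.null(.fixture_env$vol)) {
    spec <- landscapeSpec(domain_size_mm = c(6, 6), pixel_mm = 0.1, seed = 7L)
    ls <- genLandscape(spec)
    .fixture_env$vspec <- spec
    .fixture_env$vls <- ls
    .fixture_env$vol <- genOCTVolume(ls$dem, ls$labels, spec, axial_mm = 0.01)
  }
  list(spec = .fixture_env$vspec, dem = .fixture_env$vls$dem,
       labels = .fixture_env$vls$labels, vol = .fixture_env$vol)
}
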