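## Internal numeric helpers shared across modules.

## Bilinear interpolation of a cell-centred field; queries outside the
## centre lattice are clamped to the boundary cell (constant extrapolation
## over the half-cell margin).
bilinearInterp <- function(xc, zc, field, xq, zq) {
  nx <- length(xc); nz <- length(zc)
  ix <- findInterval(xq, xc, all.inside = TRUE)
  iz <- findInterval(zq, zc, all.inside = TRUE)
  tx <- (xq - xc[ix]) / (xc[ix + 1L] - xc[ix])
  tz <- (zq - zc[iz]) / (zc[iz + 1L] - zc[iz])
  tx <- pmin(pmax(tx, 0), 1)
  tz <- pmin(pmax(tz, 0), 1)
  f11 <- field[cbind(ix, iz)]
  f21 <- field[cbind(ix + 1L, iz)]
  f12 <- field[cbind(ix, iz + 1L)]
  f22 <- field[cbind(ix + 1L, iz + 1L)]
  (1 - tx) * (1 - tz) * f11 + tx * (1 - tz) * f21 +
    (1 - tx) * tz * f12 + tx * tz * f22
}

## Standardize a vector to mean 0, sd 1 (guarding constant input).
standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

## Smooth a matrix with an isotropic Gaussian kernel (reflective borders).
smoothMatrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  ## the Gaussian brush (size 2*ceil(3 sigma)+1) must fit inside the image
  sigma_px <- min(sigma_px, (min(dim(m)) - 3) / 6.5)
  if (sigma_px <= 0) return(m)
  rng <- range(m)
  if (diff(rng) == 0) return(m)
  scaled <- (m - rng[1]) / diff(rng)
  sm <- EBImage::gblur(scaled, sigma = sigma_px)
  sm * diff(rng) + rng[1]
}

## Centered moving-average smoothing of a vector (window must be odd).
movingAverage <- function(x, window) {
  if (window <= 1L) return(x)
  k <- rep(1 / window, window)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1L):(half + n)]
}

#' Construct model parameters
#'
#' Convenience constructor for [ModelParams-class] with fluid constants
#' for water at 15 degC (rho = 999.1 kg m-3, nu = 1.139e-6 m2 s-1,
#' D_aq = 1.67e-9 m2 s-1 for O2), all overridable.
#'
#' @param porosity biofilm porosity (void fraction), in (0, 1].
#' @param permeability biofilm permeability K, m2.
#' @param diffRatio effective diffusivity ratio C = D_eff/D_aq, (0, 1].
#' @param prandtlT turbulent Prandtl number P_rt = nu_t / D_t.
#' @param eddyVisc eddy viscosity nu_t, m2 s-1.
#' @param rate volumetric O2 reaction rate R, mol m-3 s-1 (negative for
#'   dark respiration, positive for net photosynthesis).
#' @param Daq,nu,rho fluid constants (see description).
#' @return A [ModelParams-class] object.
#' @export
#' @examples
#' makeModelParams(porosity = 0.58, permeability = 1e-10, diffRatio = 0.8)
makeModelParams <- function(porosity = 0.5, permeability = 1e-10,
                            diffRatio = 0.7, prandtlT = 1, eddyVisc = 1e-5,
                            rate = 0, Daq = 1.67e-9, nu = 1.139e-6,
                            rho = 999.1) {
  new("ModelParams", porosity = porosity, permeability = permeability,
      diffRatio = diffRatio, prandtlT = prandtlT, eddyVisc = eddyVisc,
      rate = rate, Daq = Daq, nu = nu, rho = rho)
}

## Update a ModelParams object from a named list (used by the fitter).
updateParams <- function(params, values) {
  slotmap <- c(R = "rate", K = "permeability", eps = "porosity",
               C = "diffRatio", P_rt = "prandtlT", nu_t = "eddyVisc")
  for (nm in names(values)) {
    sl <- if (nm %in% names(slotmap)) slotmap[[nm]] else nm
    slot(params, sl) <- unname(values[[nm]])
  }
  validObject(params)
  params
}
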