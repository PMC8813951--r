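#' Build a 2D water + biofilm model domain
#'
#' Discretizes a vertical slice of the flume (x along flow, z up from the
#' substrate) into a structured finite-volume grid and marks cells lying
#' below a biofilm elevation profile as porous biofilm. The vertical grid
#' uses a uniformly fine band from the substrate to just above the highest
#' biofilm point (where the fluid-biofilm interface must be resolved) and
#' geometric stretching up to the free surface of the modelled layer.
#'
#' @param elevation_mm numeric vector of biofilm surface heights (mm) along
#'   the slice, or an [ElevationMap-class] together with `row` to take a
#'   cross-section.
#' @param width_m domain length in flow direction (m). Defaults to the
#'   extent of `elevation_mm` at `pixel_mm` spacing when taken from a DEM,
#'   else 0.006 m.
#' @param height_m domain height (m); default 0.005.
#' @param nx,nz number of cells in x and z.
#' @param smooth_window odd integer; moving-average window (in profile
#'   samples) applied to the elevation profile before meshing. 1 = none.
#' @param band_frac fraction of `nz` cells placed in the uniform fine band
#'   covering `[0, max(elevation) + 20\%]`.
#' @param row row of the `ElevationMap` to slice (when a DEM is given).
#' @param pixel_mm spacing of `elevation_mm` samples (mm), used to set the
#'   default width.
#' @return A [ModelDomain-class].
#' @details Elevation values exceeding the domain height are clipped with a
#'   warning. A flat zero profile yields a pure free-flow channel.
#' @export
#' @examples
#' dom <- buildDomain(rep(0.4, 40), width_m = 0.004, nx = 40, nz = 40)
#' dom
buildDomain <- function(elevation_mm, width_m = NULL, height_m = 0.005,
                        nx = 60, nz = 60, smooth_window = 1L,
                        band_frac = 0.55, row = NULL, pixel_mm = 0.1) {
  if (is(elevation_mm, "ElevationMap")) {
    dem <- elevation_mm
    if (is.null(row)) row <- ceiling(ncol(dem@heights) / 2)
    elevation_mm <- dem@heights[, row]
    pixel_mm <- dem@pixelMM[1]
  }
  stopifnot(is.numeric(elevation_mm), all(is.finite(elevation_mm)),
            all(elevation_mm >= 0), nx >= 4, nz >= 8)
  if (is.null(width_m))
    width_m <- max(length(elevation_mm) * pixel_mm / 1000, 0.002)
  elev <- movingAverage(elevation_mm, smooth_window) / 1000  # -> m
  if (any(elev > height_m)) {
    warning("elevation exceeds domain height; clipping")
    elev <- pmin(elev, height_m)
  }
  xf <- seq(0, width_m, length.out = nx + 1L)
  xc <- (xf[-1] + xf[-(nx + 1L)]) / 2
  ## resample elevation onto cell centres
  xs <- seq(0, width_m, length.out = length(elev))
  elev_c <- if (length(elev) > 1) approx(xs, elev, xout = xc, rule = 2)$y
            else rep(elev, nx)

  zmax_b <- max(elev_c)
  if (zmax_b <= 0) {
    zf <- seq(0, height_m, length.out = nz + 1L)
  } else {
    z_band <- min(zmax_b * 1.2 + 0.0002, 0.9 * height_m)
    n_fine <- max(4L, round(band_frac * nz))
    n_coarse <- nz - n_fine
    zf_fine <- seq(0, z_band, length.out = n_fine + 1L)
    ## geometric stretching from the band top to the domain top
    dz0 <- zf_fine[2] - zf_fine[1]
    L <- height_m - z_band
    r <- findGrowthRatio(L, dz0, n_coarse)
    steps <- dz0 * r^seq_len(n_coarse)
    steps <- steps * (L / sum(steps))
    zf <- c(zf_fine, z_band + cumsum(steps))
    zf[length(zf)] <- height_m
  }
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  biofilm <- outer(elev_c, zc, function(e, z) z < e)
  new("ModelDomain", xf = xf, zf = zf, biofilm = biofilm, elevation = elev_c)
}

## Solve for growth ratio r with dz0 * sum_{j=1..n} r^j = L (bisection).
findGrowthRatio <- function(L, dz0, n) {
  if (n <= 0L) return(1)
  f <- function(r) {
    s <- if (abs(r - 1) < 1e-12) n else r * (r^n - 1) / (r - 1)
    dz0 * s - L
  }
  if (f(1) >= 0) return(1)  # uniform already overshoots; rescaled later
  lo <- 1; hi <- 2
  while (f(hi) < 0 && hi < 64) hi <- hi * 2
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## Cell geometry helpers -----------------------------------------------

domainGeometry <- function(domain) {
  xf <- domain@xf; zf <- domain@zf
  nx <- length(xf) - 1L; nz <- length(zf) - 1L
  dx <- diff(xf); dz <- diff(zf)
  xc <- (xf[-1] + xf[-(nx + 1L)]) / 2
  zc <- (zf[-1] + zf[-(nz + 1L)]) / 2
  ## distances between u-face columns / w-face rows (for CV widths)
  dxu <- c(xc[1] - xf[1], diff(xc), xf[nx + 1L] - xc[nx])  # length nx+1
  dzw <- c(zc[1] - zf[1], diff(zc), zf[nz + 1L] - zc[nz])  # length nz+1
  list(nx = nx, nz = nz, dx = dx, dz = dz, xc = xc, zc = zc,
       dxu = dxu, dzw = dzw, xf = xf, zf = zf)
}

#' Biofilm cross-sectional area of a domain
#'
#' Geometric area of the biofilm region (m2 per unit depth). By default
#' partial cell coverage below the elevation profile is accounted for,
#' so the value matches the trapezoid integral of the profile up to
#' resampling error. `partial = FALSE` instead counts whole cells of the
#' binary biofilm indicator -- the region the solver actually applies
#' the reaction in -- which is what conservation checks against solver
#' output must use (a binary indicator carries an O(dz/2) staircase bias
#' on flat profile sections).
#'
#' @param domain a [ModelDomain-class].
#' @param partial logical; account for partial cell coverage.
#' @return numeric scalar, m2.
#' @export
biofilmArea <- function(domain, partial = TRUE) {
  g <- domainGeometry(domain)
  if (!partial) {
    areas <- outer(g$dx, g$dz)
    return(sum(areas[domain@biofilm]))
  }
  frac <- outer(seq_along(g$dx), seq_along(g$dz), function(i, k)
    pmin(pmax((domain@elevation[i] - g$zf[k]) / g$dz[k], 0), 1))
  sum(outer(g$dx, g$dz) * frac)
}
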