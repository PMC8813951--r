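#' Sensor noise specification
#'
#' Noise and sampling settings for forward-modelled O2 transects:
#' additive Gaussian concentration noise and the vertical sensor step
#' (50 um in the flume study).
#'
#' @param sigma_conc noise SD, mol m-3 (>= 0).
#' @param vertical_step_mm sensor step, mm (> 0).
#' @param seed integer seed.
#' @return list of class `SensorNoiseSpec`.
#' @export
sensorNoiseSpec <- function(sigma_conc = 2e-3, vertical_step_mm = 0.05,
                            seed = 1L) {
  stopifnot(sigma_conc >= 0, vertical_step_mm > 0)
  structure(list(sigma_conc = sigma_conc,
                 vertical_step_mm = vertical_step_mm,
                 seed = as.integer(seed)),
            class = "SensorNoiseSpec")
}

#' Generate synthetic inlet velocimetry points
#'
#' Samples (z, u, u_rms) points from a quadratic velocity profile
#' vanishing at the wall, over the lowest 5 mm of the water column --
#' the layer the 2D model resolves (14 points in the study's
#' laser-Doppler data). `u_bulk` sets the apex velocity of the parabola.
#'
#' @param u_bulk bulk velocity (m s-1), apex of the quadratic profile.
#' @param n_points number of points (>= 3).
#' @param seed integer seed.
#' @param noise_sd velocity noise SD (m s-1).
#' @param z_max top of the sampled layer (m).
#' @return data.frame with columns `z` (m), `u` (m s-1), `u_rms`.
#' @export
#' @examples
#' genInletProfile(0.06, n_points = 14, seed = 1)
genInletProfile <- function(u_bulk, n_points = 14L, seed = 1L,
                            noise_sd = 0.002 * abs(u_bulk), z_max = 0.005) {
  stopifnot(n_points >= 3)
  set.seed(seed)
  z <- seq(0, z_max, length.out = n_points)
  ## parabola with apex u_bulk at z_max: u = u_bulk (2 z/zm - (z/zm)^2)
  u <- u_bulk * (2 * z / z_max - (z / z_max)^2)
  u <- u + rnorm(n_points, 0, noise_sd)
  u_rms <- abs(0.1 * u_bulk) + rnorm(n_points, 0, noise_sd / 2)
  data.frame(z = z, u = u, u_rms = pmax(u_rms, 0))
}

#' Quadratic fit of inlet velocimetry points
#'
#' Least-squares quadratic polynomial through measured (z, u) points,
#' returned as a vectorized profile function u(z) for use as the inlet
#' boundary condition of [solveFlow()].
#'
#' @param points data.frame with columns `z` (m) and `u` (m s-1).
#' @return function of z (m) returning velocity (m s-1); its
#'   coefficients (u = a0 + a1 z + a2 z^2) are attached as attribute
#'   `"coefficients"`.
#' @export
fitInletProfile <- function(points) {
  stopifnot(nrow(points) >= 3)
  fit <- lm(u ~ z + I(z^2), data = points)
  cf <- unname(coef(fit))
  f <- function(z) cf[1] + cf[2] * z + cf[3] * z^2
  attr(f, "coefficients") <- cf
  f
}

#' Forward-model a synthetic O2 microsensor transect
#'
#' Solves flow and transport on a model domain at given true parameters,
#' samples the concentration field on vertical profiles at 50 um steps
#' (bilinear interpolation, exactly the interpolation used by the fit
#' objective), and adds Gaussian sensor noise. The true parameters and
#' solver settings are recorded in the transect metadata for recovery
#' experiments.
#'
#' @param domain a [ModelDomain-class].
#' @param true_params a [ModelParams-class]; its `rate` slot provides
#'   |R|, with the sign set by `light`.
#' @param noise a [sensorNoiseSpec()].
#' @param light logical: light (net photosynthesis, R > 0) or dark
#'   (respiration, R < 0).
#' @param x_mm profile stations along the flow (mm); default 5 stations
#'   across the middle of the domain.
#' @param z_range_mm sampled height range (mm above substrate).
#' @param inlet inlet flow boundary condition (see [solveFlow()]).
#' @param inlet_conc inlet/bulk O2 concentration (mol m-3).
#' @param advection retain momentum advection (passed to [solveFlow()]).
#' @param flow optional precomputed [FlowField-class] to reuse.
#' @return A [MicroprofileTransect-class]; solver failures propagate.
#' @export
genO2Transect <- function(domain, true_params, noise = sensorNoiseSpec(),
                          light = FALSE, x_mm = NULL, z_range_mm = NULL,
                          inlet = list(type = "velocity",
                                       profile = function(z)
                                         0.1 * (2 * z / 0.005 - (z / 0.005)^2)),
                          inlet_conc = 0.3, advection = TRUE, flow = NULL) {
  g <- domainGeometry(domain)
  W_mm <- (g$xf[length(g$xf)] - g$xf[1]) * 1000
  if (is.null(x_mm))
    x_mm <- seq(0.25 * W_mm, 0.85 * W_mm, length.out = 5)
  if (is.null(z_range_mm))
    z_range_mm <- c(noise$vertical_step_mm,
                    min(max(domain@elevation) * 1000 + 1.5,
                        g$zf[length(g$zf)] * 1000 * 0.9))
  rate <- if (light) abs(true_params@rate) else -abs(true_params@rate)

  if (is.null(flow))
    flow <- solveFlow(domain, true_params, inlet = inlet,
                      advection = advection)
  conc <- solveTransport(domain, flow, true_params, rate = rate,
                         inlet_conc = inlet_conc)

  z_mm <- seq(z_range_mm[1], z_range_mm[2], by = noise$vertical_step_mm)
  set.seed(noise$seed)
  rows <- do.call(rbind, lapply(seq_along(x_mm), function(j) {
    cq <- bilinearInterp(g$xc, g$zc, conc@conc,
                         rep(x_mm[j] / 1000, length(z_mm)), z_mm / 1000)
    data.frame(profile = sprintf("P%02d", j), x_mm = x_mm[j],
               z_mm = z_mm, conc = cq)
  }))
  if (noise$sigma_conc > 0)
    rows$conc <- rows$conc + rnorm(nrow(rows), 0, noise$sigma_conc)

  surf <- approx(g$xc * 1000, domain@elevation * 1000,
                 xout = x_mm, rule = 2)$y
  names(surf) <- sprintf("P%02d", seq_along(x_mm))
  new("MicroprofileTransect",
      samples = rows, light = light, flow = "synthetic", patch = "synthetic",
      surfaceZ = surf,
      metadata = list(true_params = true_params, rate = rate,
                      noise = unclass(noise), inlet_conc = inlet_conc,
                      advection = advection))
}
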