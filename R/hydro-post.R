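#' Advective/diffusive flux ratio field
#'
#' Per-cell ratio of advective to diffusive O2 flux magnitudes,
#' \eqn{Jc/Jd = |\bar u c| / |D_{eff} \nabla c|}; values above 1 mark
#' advection-dominated transport. Also reports the mean ratio over the
#' biofilm region (excluding infinite-ratio cells where the diffusive
#' flux vanishes) and the advective fraction of the total O2 exchange
#' across the biofilm surface.
#'
#' @param flow a [FlowField-class].
#' @param conc a [ConcField-class] on the same grid.
#' @param exclude_x_m exclude columns with cell centres closer than this
#'   to the inlet from the biofilm mean and surface fraction (the imposed
#'   inlet profile drives an entrance-region artifact inside the porous
#'   matrix; internal flow equilibrates about 1 mm downstream).
#' @return list with `ratio` (nx x nz matrix; `Inf` sentinel where the
#'   diffusive flux is zero), `biofilm_mean`, `surface_advective_fraction`.
#' @export
fluxDecomposition <- function(flow, conc, exclude_x_m = 0) {
  domain <- conc@domain
  g <- domainGeometry(domain)
  nx <- g$nx; nz <- g$nz
  params <- conc@params
  B <- domain@biofilm
  Dt <- eddyDiff(params)
  Dcell <- matrix(params@Daq + Dt, nx, nz)
  Dcell[B] <- params@diffRatio * params@Daq
  C <- conc@conc

  uc <- (flow@u[-1, , drop = FALSE] + flow@u[-(nx + 1L), , drop = FALSE]) / 2
  wc <- (flow@w[, -1, drop = FALSE] + flow@w[, -(nz + 1L), drop = FALSE]) / 2
  speed <- sqrt(uc^2 + wc^2)

  gx <- matrix(0, nx, nz); gz <- matrix(0, nx, nz)
  if (nx > 1) {
    dxc <- diff(g$xc)
    gx[2:(nx - 1), ] <- (C[3:nx, , drop = FALSE] - C[1:(nx - 2), , drop = FALSE]) /
      (g$xc[3:nx] - g$xc[1:(nx - 2)])
    gx[1, ] <- (C[2, ] - C[1, ]) / dxc[1]
    gx[nx, ] <- (C[nx, ] - C[nx - 1, ]) / dxc[nx - 1]
  }
  if (nz > 1) {
    dzc <- diff(g$zc)
    gz[, 2:(nz - 1)] <- sweep(C[, 3:nz, drop = FALSE] - C[, 1:(nz - 2), drop = FALSE],
                              2, g$zc[3:nz] - g$zc[1:(nz - 2)], "/")
    gz[, 1] <- (C[, 2] - C[, 1]) / dzc[1]
    gz[, nz] <- (C[, nz] - C[, nz - 1]) / dzc[nz - 1]
  }
  Jc <- speed * abs(C)
  Jd <- Dcell * sqrt(gx^2 + gz^2)
  ratio <- ifelse(Jd > 0, Jc / Jd, ifelse(Jc > 0, Inf, 0))

  keep <- B & matrix(g$xc >= exclude_x_m, nx, nz)
  bio_vals <- ratio[keep]
  biofilm_mean <- if (any(keep)) mean(bio_vals[is.finite(bio_vals)]) else NA_real_

  ## exchange across the fluid-biofilm interface: advective vs diffusive
  ## magnitudes summed over interface faces (upwind face concentration)
  adv <- 0; dif <- 0
  Fx <- flow@u * matrix(g$dz, nx + 1L, nz, byrow = TRUE)
  Fz <- flow@w * matrix(g$dx, nx, nz + 1L)
  colok <- g$xc >= exclude_x_m
  if (nx > 1) for (j in 2:nx) {
    if (!colok[j]) next
    ik <- which(B[j - 1, ] != B[j, ])
    if (length(ik)) {
      d1 <- g$dx[j - 1] / 2; d2 <- g$dx[j] / 2
      Df <- (d1 + d2) / (d1 / Dcell[j - 1, ik] + d2 / Dcell[j, ik])
      cup <- ifelse(Fx[j, ik] > 0, C[j - 1, ik], C[j, ik])
      adv <- adv + sum(abs(Fx[j, ik] * cup))
      dif <- dif + sum(abs(Df * g$dz[ik] * (C[j, ik] - C[j - 1, ik]) / (d1 + d2)))
    }
  }
  if (nz > 1) for (m in 2:nz) {
    ii <- which(B[, m - 1] != B[, m] & colok)
    if (length(ii)) {
      d1 <- g$dz[m - 1] / 2; d2 <- g$dz[m] / 2
      Df <- (d1 + d2) / (d1 / Dcell[ii, m - 1] + d2 / Dcell[ii, m])
      cup <- ifelse(Fz[ii, m] > 0, C[ii, m - 1], C[ii, m])
      adv <- adv + sum(abs(Fz[ii, m] * cup))
      dif <- dif + sum(abs(Df * g$dx[ii] * (C[ii, m] - C[ii, m - 1]) / (d1 + d2)))
    }
  }
  saf <- if (adv + dif > 0) adv / (adv + dif) else NA_real_
  list(ratio = ratio, biofilm_mean = biofilm_mean,
       surface_advective_fraction = saf)
}

#' Wall shear stress, friction velocity and boundary-layer scales
#'
#' Averages the shear stress over the biofilm surface (or the bottom wall
#' where no biofilm is present) and derives the friction velocity
#' \eqn{u^* = \sqrt{\tau/\rho}}, the viscous length scale
#' \eqn{\delta = \nu/u^*}, and the diffusive-boundary-layer scale
#' \eqn{\delta/\sqrt{Sc}} with Schmidt number \eqn{Sc = \nu/D_{aq}}.
#' Shear is evaluated from the first water cell above the surface using
#' the molecular viscosity: the scales of interest are viscous-sublayer
#' properties, where the constant-eddy-viscosity closure does not apply.
#'
#' @param flow a [FlowField-class].
#' @return list with `tau` (Pa), `u_star` (m s-1), `delta` (m),
#'   `dbl_scale` (m) and the per-column `tau_profile`. Zero average shear
#'   flags `delta` and `dbl_scale` as `Inf`.
#' @export
wallShearDBL <- function(flow) {
  domain <- flow@domain
  params <- flow@params
  g <- domainGeometry(domain)
  nx <- g$nx; nz <- g$nz
  B <- domain@biofilm
  mu <- params@rho * params@nu
  uc <- (flow@u[-1, , drop = FALSE] + flow@u[-(nx + 1L), , drop = FALSE]) / 2

  tau_profile <- numeric(nx)
  for (i in 1:nx) {
    ks <- which(!B[i, ])[1]          # first water cell above the surface
    if (is.na(ks)) { tau_profile[i] <- NA_real_; next }
    z_s <- g$zf[ks]
    tau_profile[i] <- mu * uc[i, ks] / (g$zc[ks] - z_s)
  }
  tau <- if (all(is.na(tau_profile))) NA_real_ else mean(tau_profile, na.rm = TRUE)
  if (!is.finite(tau))
    return(list(tau = NA_real_, u_star = NA_real_, delta = NA_real_,
                dbl_scale = NA_real_, tau_profile = tau_profile))
  u_star <- sqrt(max(tau, 0) / params@rho)
  if (u_star <= 0) {
    delta <- Inf; dbl <- Inf
  } else {
    delta <- params@nu / u_star
    dbl <- delta / sqrt(params@nu / params@Daq)
  }
  list(tau = tau, u_star = u_star, delta = delta, dbl_scale = dbl,
       tau_profile = tau_profile)
}

#' Friction velocity, viscous length and DBL scale from shear stress
#'
#' Arithmetic form of the boundary-layer chain: \eqn{u^* = \sqrt{\tau/\rho}},
#' \eqn{\delta = \nu/u^*}, \eqn{DBL = \delta/\sqrt{Sc}}.
#'
#' @param tau wall shear stress, Pa.
#' @param rho density, kg m-3.
#' @param nu kinematic viscosity, m2 s-1.
#' @param Daq molecular diffusivity, m2 s-1.
#' @return list with `u_star`, `delta`, `dbl_scale`.
#' @export
#' @examples
#' frictionScales(1e-2, 1000, 1e-6, 2.5e-9)
frictionScales <- function(tau, rho = 999.1, nu = 1.139e-6, Daq = 1.67e-9) {
  u_star <- sqrt(tau / rho)
  delta <- if (u_star > 0) nu / u_star else Inf
  list(u_star = u_star, delta = delta,
       dbl_scale = delta / sqrt(nu / Daq))
}

#' Internal velocity statistics and viscous sublayer thickness
#'
#' Volume-weighted mean flow speed inside the biofilm, and the viscous
#' sublayer thickness along the surface, defined per column as the height
#' above the surface where the velocity departs by more than 10% from the
#' linear wall scaling \eqn{u(z) \approx (\tau/\mu)(z - z_s)}.
#'
#' @param flow a [FlowField-class].
#' @param exclude_x_m entrance margin excluded from the biofilm mean (m),
#'   as in [fluxDecomposition()].
#' @return list with `mean_speed` (m s-1, 0 when there is no biofilm),
#'   `sublayer_profile` (per-column thickness, m), `sublayer_mean`.
#' @export
internalVelocityStats <- function(flow, exclude_x_m = 0) {
  domain <- flow@domain
  g <- domainGeometry(domain)
  nx <- g$nx; nz <- g$nz
  B <- domain@biofilm
  uc <- (flow@u[-1, , drop = FALSE] + flow@u[-(nx + 1L), , drop = FALSE]) / 2
  wc <- (flow@w[, -1, drop = FALSE] + flow@w[, -(nz + 1L), drop = FALSE]) / 2
  speed <- sqrt(uc^2 + wc^2)
  areas <- outer(g$dx, g$dz)
  keep <- B & matrix(g$xc >= exclude_x_m, nx, nz)
  mean_speed <- if (any(keep)) sum(speed[keep] * areas[keep]) / sum(areas[keep]) else 0

  sub <- rep(NA_real_, nx)
  for (i in 1:nx) {
    ks <- which(!B[i, ])[1]
    if (is.na(ks)) next
    z_s <- g$zf[ks]
    ## local near-wall slope from the first water cell; the sublayer ends
    ## where the profile departs from this linear scaling by > 10%
    slope <- uc[i, ks] / (g$zc[ks] - z_s)
    if (!is.finite(slope) || slope == 0) next
    dep <- abs(uc[i, ks:nz] - slope * (g$zc[ks:nz] - z_s)) >
      0.1 * abs(slope * (g$zc[ks:nz] - z_s))
    kk <- which(dep)[1]
    sub[i] <- if (is.na(kk)) g$zf[nz + 1L] - z_s else g$zc[ks + kk - 1L] - z_s
  }
  list(mean_speed = mean_speed, sublayer_profile = sub,
       sublayer_mean = mean(sub, na.rm = TRUE))
}
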