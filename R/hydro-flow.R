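#' Solve steady coupled free-flow / porous-biofilm flow
#'
#' Finite-volume solution of the steady incompressible momentum and
#' continuity equations on a staggered (MAC) grid. In the free-flow
#' region the effective kinematic viscosity is \eqn{\nu + \nu_t}
#' (constant-eddy-viscosity Reynolds-averaged closure); inside the
#' biofilm a Brinkman-type balance applies, with Darcy resistance
#' \eqn{(\nu/K)\,\bar u} and the viscous term scaled by \eqn{1/\epsilon}
#' (and no eddy viscosity: turbulence does not penetrate the porous
#' matrix at these scales). Velocity and stress are continuous across the
#' fluid-biofilm interface by construction of the face-viscosity
#' averaging.
#'
#' Boundary conditions: Dirichlet velocity or static pressure at the
#' inlet, zero static pressure at the outlet, no-slip at the bottom, and
#' a slip condition (zero shear, zero normal velocity) at the top.
#' Momentum advection is retained through Picard iteration with
#' under-relaxation and implicit first-order upwinding; a Stokes-Brinkman
#' mode (`advection = FALSE`) solves the linear problem in one step and
#' admits closed-form channel/Darcy oracles.
#'
#' @param domain a [ModelDomain-class].
#' @param params a [ModelParams-class].
#' @param inlet list: `list(type = "velocity", profile = function(z) ...)`
#'   (m s-1 as a function of height in m) or
#'   `list(type = "pressure", p = <Pa>)`.
#' @param outlet_pressure static pressure at the outlet (Pa), default 0.
#' @param forcing_x uniform body force per unit mass (m s-2) along x,
#'   e.g. a kinematic pressure gradient for channel oracles.
#' @param advection logical; retain momentum advection (Picard).
#' @param relax Picard under-relaxation factor.
#' @param maxit maximum Picard iterations.
#' @param tol relative-change convergence tolerance.
#' @param warm_start optional [FlowField-class] used to initialize the
#'   Picard iteration (speeds up repeated solves during fitting).
#' @return A [FlowField-class]; `diagnostics` holds the global continuity
#'   residual (relative to the inflow scale) and the Picard history.
#' @export
#' @examples
#' dom <- buildDomain(rep(0, 20), width_m = 0.004, nx = 20, nz = 32)
#' fl <- solveFlow(dom, makeModelParams(eddyVisc = 0),
#'                 inlet = list(type = "pressure", p = 1e-3),
#'                 advection = FALSE)
#' fl
solveFlow <- function(domain, params,
                      inlet = list(type = "velocity",
                                   profile = function(z) 0.1 + 0 * z),
                      outlet_pressure = 0, forcing_x = 0, advection = TRUE,
                      relax = 0.7, maxit = 40, tol = 1e-6,
                      warm_start = NULL) {
  g <- domainGeometry(domain)
  nx <- g$nx; nz <- g$nz
  B <- domain@biofilm
  nu <- params@nu
  nuC <- matrix(nu + params@eddyVisc, nx, nz)
  nuC[B] <- nu / params@porosity
  darcy <- matrix(0, nx, nz)
  darcy[B] <- nu / params@permeability
  rho <- params@rho
  p_out <- outlet_pressure
  inlet_type <- match.arg(inlet$type, c("velocity", "pressure"))

  Nu <- (nx + 1L) * nz; Nw <- nx * (nz + 1L); Np <- nx * nz
  N <- Nu + Nw + Np
  IU <- function(i, k) (k - 1L) * (nx + 1L) + i
  IW <- function(i, k) Nu + (k - 1L) * nx + i
  IP <- function(i, k) Nu + Nw + (k - 1L) * nx + i
  clampL <- function(i) pmax(i - 1L, 1L)
  clampR <- function(i) pmin(i, nx)

  ## corner viscosity at (xf[i], zf[k]); i in 1..nx+1, k in 2..nz
  nuCorner <- function(i, k) {
    (nuC[cbind(clampL(i), k - 1L)] + nuC[cbind(clampR(i), k - 1L)] +
     nuC[cbind(clampL(i), k)] + nuC[cbind(clampR(i), k)]) / 4
  }

  uin <- NULL
  if (inlet_type == "velocity") uin <- inlet$profile(g$zc)

  u0 <- matrix(0, nx + 1L, nz); w0 <- matrix(0, nx, nz + 1L)
  if (!is.null(warm_start)) { u0 <- warm_start@u; w0 <- warm_start@w }
  else if (inlet_type == "velocity") u0[] <- rep(uin, each = nx + 1L)

  assembleSolve <- function(u0, w0, with_adv) {
    ti <- integer(0); tj <- integer(0); tx <- numeric(0)
    rhs <- numeric(N)
    add <- function(i, j, x) {
      keep <- x != 0
      ti <<- c(ti, i[keep]); tj <<- c(tj, j[keep]); tx <<- c(tx, x[keep])
    }

    ## ---- u-momentum rows -------------------------------------------
    iset <- if (inlet_type == "velocity") 2:(nx + 1L) else 1:(nx + 1L)
    grid <- expand.grid(i = iset, k = 1:nz)
    i <- grid$i; k <- grid$k
    row <- IU(i, k)
    dz_k <- g$dz[k]; dxu_i <- g$dxu[i]; vol <- dxu_i * dz_k

    ## east viscous
    e <- i <= nx
    aE <- ifelse(e, nuC[cbind(clampR(i), k)] * dz_k /
                   ifelse(e, g$dx[pmin(i, nx)], 1), 0)
    add(row[e], IU(i[e] + 1L, k[e]), -aE[e])
    add(row[e], row[e], aE[e])
    ## west viscous
    wv <- i >= 2
    aW <- ifelse(wv, nuC[cbind(clampL(i), k)] * dz_k /
                   ifelse(wv, g$dx[pmax(i - 1L, 1L)], 1), 0)
    add(row[wv], IU(i[wv] - 1L, k[wv]), -aW[wv])
    add(row[wv], row[wv], aW[wv])
    ## north viscous (slip top: zero shear for k = nz)
    nn <- k <= nz - 1L
    if (any(nn)) {
      aN <- nuCorner(i[nn], k[nn] + 1L) * dxu_i[nn] /
        (g$zc[k[nn] + 1L] - g$zc[k[nn]])
      add(row[nn], IU(i[nn], k[nn] + 1L), -aN)
      add(row[nn], row[nn], aN)
    }
    ## south viscous (no-slip wall for k = 1)
    ss <- k >= 2
    if (any(ss)) {
      aS <- nuCorner(i[ss], k[ss]) * dxu_i[ss] / (g$zc[k[ss]] - g$zc[k[ss] - 1L])
      add(row[ss], IU(i[ss], k[ss] - 1L), -aS)
      add(row[ss], row[ss], aS)
    }
    s1 <- k == 1L
    if (any(s1)) {
      nuW <- (nuC[cbind(clampL(i[s1]), rep(1L, sum(s1)))] +
              nuC[cbind(clampR(i[s1]), rep(1L, sum(s1)))]) / 2
      aS1 <- nuW * dxu_i[s1] / (g$zc[1] - g$zf[1])
      add(row[s1], row[s1], aS1)
    }
    ## pressure gradient (kinematic: /rho)
    pe <- i <= nx
    add(row[pe], IP(i[pe], k[pe]), dz_k[pe] / rho)
    rhs[row[!pe]] <- rhs[row[!pe]] - p_out * dz_k[!pe] / rho
    pw <- i >= 2
    add(row[pw], IP(i[pw] - 1L, k[pw]), -dz_k[pw] / rho)
    if (inlet_type == "pressure") {
      p_in <- inlet$p
      rhs[row[!pw]] <- rhs[row[!pw]] + p_in * dz_k[!pw] / rho
    }
    ## Darcy drag
    dcoef <- (darcy[cbind(clampL(i), k)] + darcy[cbind(clampR(i), k)]) / 2 * vol
    add(row, row, dcoef)
    ## body force
    rhs[row] <- rhs[row] + forcing_x * vol

    ## advection (implicit upwind, Picard-frozen mass fluxes)
    if (with_adv) {
      upwindAdd <- function(F, nb, self_rows = row) {
        pos <- F > 0; neg <- F < 0 & !is.na(nb)
        negout <- F < 0 & is.na(nb)   # inflow from outside: zero-gradient
        add(self_rows[pos], self_rows[pos], F[pos])
        add(self_rows[neg], nb[neg], F[neg])
        add(self_rows[negout], self_rows[negout], F[negout])
      }
      Fe <- ifelse(i <= nx, 0.5 * (u0[cbind(i, k)] + u0[cbind(pmin(i + 1L, nx + 1L), k)]),
                   u0[cbind(i, k)]) * dz_k
      nbE <- ifelse(i <= nx, IU(pmin(i + 1L, nx + 1L), k), NA_integer_)
      upwindAdd(Fe, nbE)
      Fw <- -ifelse(i >= 2, 0.5 * (u0[cbind(pmax(i - 1L, 1L), k)] + u0[cbind(i, k)]),
                    u0[cbind(i, k)]) * dz_k
      nbW <- ifelse(i >= 2, IU(pmax(i - 1L, 1L), k), NA_integer_)
      upwindAdd(Fw, nbW)
      Fn <- 0.5 * (w0[cbind(clampL(i), k + 1L)] + w0[cbind(clampR(i), k + 1L)]) * dxu_i
      nbN <- ifelse(k <= nz - 1L, IU(i, pmin(k + 1L, nz)), NA_integer_)
      upwindAdd(Fn, nbN)
      Fs <- -0.5 * (w0[cbind(clampL(i), k)] + w0[cbind(clampR(i), k)]) * dxu_i
      nbS <- ifelse(k >= 2, IU(i, pmax(k - 1L, 1L)), NA_integer_)
      upwindAdd(Fs, nbS)
    }

    ## Dirichlet inlet velocity rows
    if (inlet_type == "velocity") {
      rI <- IU(1L, 1:nz)
      add(rI, rI, rep(1, nz))
      rhs[rI] <- uin
    }

    ## ---- w-momentum rows -------------------------------------------
    gw <- expand.grid(i = 1:nx, k = 2:nz)
    iw <- gw$i; kw <- gw$k
    roww <- IW(iw, kw)
    dzw_k <- g$dzw[kw]; dx_i <- g$dx[iw]; volw <- dx_i * dzw_k

    aN <- nuC[cbind(iw, kw)] * dx_i / g$dz[kw]
    add(roww, IW(iw, kw + 1L), -aN); add(roww, roww, aN)
    aS <- nuC[cbind(iw, kw - 1L)] * dx_i / g$dz[kw - 1L]
    add(roww, IW(iw, kw - 1L), -aS); add(roww, roww, aS)
    ee <- iw <= nx - 1L
    if (any(ee)) {
      aEw <- nuCorner(iw[ee] + 1L, kw[ee]) * dzw_k[ee] /
        (g$xc[iw[ee] + 1L] - g$xc[iw[ee]])
      add(roww[ee], IW(iw[ee] + 1L, kw[ee]), -aEw)
      add(roww[ee], roww[ee], aEw)
    }
    ww <- iw >= 2
    if (any(ww)) {
      aWw <- nuCorner(iw[ww], kw[ww]) * dzw_k[ww] /
        (g$xc[iw[ww]] - g$xc[iw[ww] - 1L])
      add(roww[ww], IW(iw[ww] - 1L, kw[ww]), -aWw)
      add(roww[ww], roww[ww], aWw)
    }
    w1 <- iw == 1L
    if (inlet_type == "velocity" && any(w1)) {
      ## inlet plane carries the prescribed (u, 0): w = 0 wall-like
      aW1 <- nuCorner(rep(1L, sum(w1)), kw[w1]) * dzw_k[w1] /
        (g$xc[1] - g$xf[1])
      add(roww[w1], roww[w1], aW1)
    }
    ## pressure
    add(roww, IP(iw, kw), dx_i / rho)
    add(roww, IP(iw, kw - 1L), -dx_i / rho)
    ## Darcy
    dcw <- (darcy[cbind(iw, kw - 1L)] + darcy[cbind(iw, kw)]) / 2 * volw
    add(roww, roww, dcw)

    if (with_adv) {
      upwindAddW <- function(F, nb) {
        pos <- F > 0; neg <- F < 0 & !is.na(nb)
        negout <- F < 0 & is.na(nb)
        add(roww[pos], roww[pos], F[pos])
        add(roww[neg], nb[neg], F[neg])
        add(roww[negout], roww[negout], F[negout])
      }
      Fn <- 0.5 * (w0[cbind(iw, kw)] + w0[cbind(iw, pmin(kw + 1L, nz + 1L))]) * dx_i
      upwindAddW(Fn, IW(iw, pmin(kw + 1L, nz + 1L)))
      Fs <- -0.5 * (w0[cbind(iw, pmax(kw - 1L, 1L))] + w0[cbind(iw, kw)]) * dx_i
      upwindAddW(Fs, IW(iw, pmax(kw - 1L, 1L)))
      Fe <- 0.5 * (u0[cbind(iw + 1L, kw - 1L)] + u0[cbind(iw + 1L, kw)]) * dzw_k
      nbE <- ifelse(iw <= nx - 1L, IW(pmin(iw + 1L, nx), kw), NA_integer_)
      upwindAddW(Fe, nbE)
      Fw <- -0.5 * (u0[cbind(iw, kw - 1L)] + u0[cbind(iw, kw)]) * dzw_k
      nbW <- ifelse(iw >= 2, IW(pmax(iw - 1L, 1L), kw), NA_integer_)
      ## at the inlet plane the transported w is 0: only self outflow term
      if (inlet_type == "velocity") {
        upwindAddW(ifelse(iw == 1L & Fw < 0, 0, Fw), nbW)
      } else upwindAddW(Fw, nbW)
    }

    ## Dirichlet w rows: bottom and top faces
    rB <- IW(1:nx, 1L); rT <- IW(1:nx, nz + 1L)
    add(c(rB, rT), c(rB, rT), rep(1, 2L * nx))

    ## ---- continuity rows -------------------------------------------
    gc <- expand.grid(i = 1:nx, k = 1:nz)
    ic <- gc$i; kc <- gc$k
    rowc <- IP(ic, kc)
    add(rowc, IU(ic + 1L, kc), g$dz[kc])
    add(rowc, IU(ic, kc), -g$dz[kc])
    add(rowc, IW(ic, kc + 1L), g$dx[ic])
    add(rowc, IW(ic, kc), -g$dx[ic])

    A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(N, N))
    sol <- as.numeric(Matrix::solve(A, rhs))
    list(u = matrix(sol[1:Nu], nx + 1L, nz),
         w = matrix(sol[(Nu + 1L):(Nu + Nw)], nx, nz + 1L),
         p = matrix(sol[(Nu + Nw + 1L):N], nx, nz))
  }

  history <- numeric(0)
  if (!advection) {
    s <- assembleSolve(u0, w0, FALSE)
    u0 <- s$u; w0 <- s$w; p <- s$p
  } else {
    p <- matrix(0, nx, nz)
    for (it in seq_len(maxit)) {
      s <- assembleSolve(u0, w0, TRUE)
      scale <- max(abs(s$u), abs(s$w), 1e-300)
      change <- max(abs(s$u - u0), abs(s$w - w0)) / scale
      history <- c(history, change)
      a <- if (it == 1L) 1 else relax
      u0 <- a * s$u + (1 - a) * u0
      w0 <- a * s$w + (1 - a) * w0
      p <- s$p
      if (change < tol) break
    }
    if (history[length(history)] >= tol && length(history) >= maxit)
      stop(sprintf("flow solver did not converge in %d Picard iterations; residual history: %s",
                   maxit, paste(signif(history, 3), collapse = " ")))
  }

  ## continuity diagnostics
  div <- (u0[-1, , drop = FALSE] - u0[-(nx + 1L), , drop = FALSE]) *
    matrix(g$dz, nx, nz, byrow = TRUE) +
    (w0[, -1, drop = FALSE] - w0[, -(nz + 1L), drop = FALSE]) * g$dx
  inflow <- sum(abs(u0[1, ]) * g$dz)
  if (inflow <= 0) inflow <- max(abs(u0)) * sum(g$dz)
  cres <- if (inflow > 0) max(abs(div)) / inflow else max(abs(div))
  net <- sum(u0[nx + 1L, ] * g$dz) - sum(u0[1, ] * g$dz)
  new("FlowField", u = u0, w = w0, p = p, domain = domain, params = params,
      diagnostics = list(continuity_residual = cres,
                         net_flow_imbalance = if (inflow > 0) abs(net) / inflow else abs(net),
                         picard_history = history))
}
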