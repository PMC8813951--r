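#' Fit specification for transect parameter estimation
#'
#' Declares which model parameters are free, their bounds, and the
#' optimizer settings. Parameters are named `R` (reaction rate), `K`
#' (permeability), `eps` (porosity), `C` (effective diffusivity ratio),
#' `P_rt` (turbulent Prandtl number), `nu_t` (eddy viscosity). Bounds
#' default to ranges bracketing plausible fitted values for these
#' biofilms (porosity 0.2-0.95, C 0.4-1, K 1e-11 to 5e-10 m2,
#' |R| up to 6e-3 mol m-3 s-1).
#'
#' @param free character vector of free parameter names.
#' @param bounds named list of c(lo, hi) per free parameter.
#' @param init named numeric of initial values (defaults to the interval
#'   midpoint on the search scale).
#' @param tol optimality tolerance (relative, on the objective) for the
#'   simplex; default 1e-4.
#' @param maxit maximum objective evaluations per restart.
#' @param restarts number of random restarts (the best objective wins;
#'   mitigates entrapment in local optima).
#' @return list of class `FitSpec`.
#' @export
fitSpec <- function(free = c("R", "K", "eps", "C"),
                    bounds = NULL, init = NULL, tol = 1e-4,
                    maxit = 300L, restarts = 3L) {
  default_bounds <- list(R = c(-6e-3, 6e-3), K = c(1e-11, 5e-10),
                         eps = c(0.2, 0.95), C = c(0.4, 1),
                         P_rt = c(0.3, 3), nu_t = c(1e-6, 1e-4))
  bounds <- modifyList(default_bounds[free], bounds %||% list())
  for (nm in free) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop("bounds must be finite and ordered for ", nm)
  }
  if (!is.null(init))
    for (nm in names(init))
      if (init[[nm]] < bounds[[nm]][1] || init[[nm]] > bounds[[nm]][2])
        stop("initial value outside bounds for ", nm)
  structure(list(free = free, bounds = bounds, init = init, tol = tol,
                 maxit = as.integer(maxit), restarts = as.integer(restarts)),
            class = "FitSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## log10 search scale for scale parameters, linear otherwise; all are
## then mapped through a logit onto their (transformed) bounds so the
## simplex roams an unconstrained space.
LOG_PARAMS <- c("K", "nu_t")

toSearch <- function(x, nm, b) {
  if (nm %in% LOG_PARAMS) { x <- log10(x); b <- log10(b) }
  qlogis(pmin(pmax((x - b[1]) / (b[2] - b[1]), 1e-12), 1 - 1e-12))
}
fromSearch <- function(t, nm, b) {
  bb <- if (nm %in% LOG_PARAMS) log10(b) else b
  x <- bb[1] + plogis(t) * (bb[2] - bb[1])
  if (nm %in% LOG_PARAMS) 10^x else x
}

#' Sum-of-squares objective of a parameter vector
#'
#' Solves flow and transport at the given parameters and returns the sum
#' of squared differences between the measured transect concentrations
#' and the modelled field interpolated (bilinearly) at the measurement
#' locations. Solver failures return a large sentinel so the simplex
#' retreats.
#'
#' @param params a [ModelParams-class] (its `rate` sign decides the
#'   metabolic mode; the transect's light flag is used when generating).
#' @param domain a [ModelDomain-class].
#' @param transect a [MicroprofileTransect-class].
#' @param inlet,inlet_conc,advection forwarded to the solvers.
#' @param flow_cache environment used to warm-start successive flow
#'   solves (internal use by [fitParameters()]).
#' @return scalar objective ((mol m-3)^2); attribute `"per_profile_cor"`
#'   carries Pearson correlations.
#' @export
transectObjective <- function(params, domain, transect,
                              inlet = list(type = "velocity",
                                           profile = function(z)
                                             0.1 * (2 * z / 0.005 - (z / 0.005)^2)),
                              inlet_conc = 0.3, advection = TRUE,
                              flow_cache = NULL) {
  g <- domainGeometry(domain)
  s <- samples(transect)
  res <- tryCatch({
    warm <- if (!is.null(flow_cache)) flow_cache$flow else NULL
    fl <- solveFlow(domain, params, inlet = inlet, advection = advection,
                    warm_start = warm)
    if (!is.null(flow_cache)) flow_cache$flow <- fl
    cf <- solveTransport(domain, fl, params, rate = params@rate,
                         inlet_conc = inlet_conc)
    cm <- bilinearInterp(g$xc, g$zc, cf@conc, s$x_mm / 1000, s$z_mm / 1000)
    obj <- sum((cm - s$conc)^2)
    cors <- vapply(split(seq_len(nrow(s)), s$profile), function(ii) {
      if (sd(s$conc[ii]) == 0 || sd(cm[ii]) == 0) return(NA_real_)
      cor(s$conc[ii], cm[ii])
    }, numeric(1))
    attr(obj, "per_profile_cor") <- cors
    obj
  }, error = function(e) {
    structure(1e30, failed = conditionMessage(e))
  })
  res
}

#' Initial turbulence closure guess
#'
#' Initializes the eddy viscosity from the integral length scale of the
#' turbulence (~7% of the water depth) and turbulent velocity
#' fluctuations of the order of the friction velocity:
#' \eqn{\nu_t \approx 0.07\, h\, u^*}; the turbulent Prandtl number
#' starts at 1.
#'
#' @param water_depth_m water depth h (m).
#' @param u_star friction velocity guess (m s-1).
#' @return list with `nu_t` (m2 s-1) and `P_rt` (= 1).
#' @export
#' @examples
#' initTurbulence(0.022, 6.5e-3)  # nu_t ~ 1e-5 m2/s
initTurbulence <- function(water_depth_m, u_star) {
  list(nu_t = 0.07 * water_depth_m * u_star, P_rt = 1)
}

#' Estimate model parameters from an O2 transect
#'
#' Nelder-Mead least-squares estimation of the free parameters over a
#' smooth bound transform (log scale for K and nu_t, logit onto the
#' bounds for all), with random restarts; the best vertex over all
#' restarts is returned with per-profile Pearson correlations and a
#' restart trace. The simplex stops when the relative objective spread
#' falls below `spec$tol` or after `spec$maxit` evaluations.
#'
#' @param domain a [ModelDomain-class].
#' @param transect a [MicroprofileTransect-class] (>= 1 profile).
#' @param spec a [fitSpec()].
#' @param base_params [ModelParams-class] supplying the fixed
#'   parameters.
#' @param inlet,inlet_conc,advection forwarded to the solvers.
#' @param seed integer seed for restart jitter.
#' @return A [FitResult-class].
#' @export
fitParameters <- function(domain, transect, spec = fitSpec(),
                          base_params = makeModelParams(),
                          inlet = list(type = "velocity",
                                       profile = function(z)
                                         0.1 * (2 * z / 0.005 - (z / 0.005)^2)),
                          inlet_conc = 0.3, advection = TRUE, seed = 1L) {
  stopifnot(inherits(spec, "FitSpec"),
            length(unique(samples(transect)$profile)) >= 1)
  free <- spec$free
  b <- spec$bounds
  mid <- vapply(free, function(nm) fromSearch(0, nm, b[[nm]]), numeric(1))
  start <- mid
  if (!is.null(spec$init))
    start[names(spec$init)] <- unlist(spec$init)

  cache <- new.env(parent = emptyenv())
  evalCount <- 0L
  fn <- function(theta) {
    vals <- setNames(lapply(seq_along(free), function(j)
      fromSearch(theta[j], free[j], b[[free[j]]])), free)
    p <- updateParams(base_params, vals)
    evalCount <<- evalCount + 1L
    as.numeric(transectObjective(p, domain, transect, inlet = inlet,
                                 inlet_conc = inlet_conc,
                                 advection = advection, flow_cache = cache))
  }

  set.seed(seed)
  best <- NULL
  trace <- list()
  for (r in seq_len(max(1L, spec$restarts))) {
    th0 <- vapply(free, function(nm) toSearch(start[[nm]], nm, b[[nm]]),
                  numeric(1))
    ## snap numerically-zero coordinates: optim's Nelder-Mead scales its
    ## initial simplex step by |par|, so a 1e-16 residue from the logit
    ## transform would collapse the simplex at the start point
    th0[abs(th0) < 1e-6] <- 0
    if (r > 1) th0 <- th0 + rnorm(length(th0), 0, 0.8)
    evalCount <- 0L
    opt <- optim(th0, fn, method = "Nelder-Mead",
                 control = list(maxit = spec$maxit, reltol = spec$tol))
    trace[[r]] <- data.frame(restart = r, objective = opt$value,
                             evaluations = evalCount,
                             converged = opt$convergence == 0)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value) || best$value >= 1e30)
    stop("all simplex vertices infeasible (solver failed everywhere)")

  vals <- setNames(lapply(seq_along(free), function(j)
    fromSearch(best$par[j], free[j], b[[free[j]]])), free)
  p_best <- updateParams(base_params, vals)
  obj <- transectObjective(p_best, domain, transect, inlet = inlet,
                           inlet_conc = inlet_conc, advection = advection)
  new("FitResult", params = p_best, objective = as.numeric(obj),
      correlations = attr(obj, "per_profile_cor"),
      trace = do.call(rbind, trace),
      convergence = list(method = "Nelder-Mead", tol = spec$tol,
                         maxit = spec$maxit, restarts = spec$restarts,
                         best_restart = which.min(vapply(trace, function(t)
                           t$objective, numeric(1)))))
}

#' Parameter-recovery simulation study
#'
#' Repeats a forward-generate/fit cycle over independent noise seeds:
#' each replicate forward-models a dark O2 transect at the true
#' parameters on a protruding porous patch, adds sensor noise, and
#' re-estimates (R, K, eps, C) by [fitParameters()]. Used to quantify
#' identifiability: R and C are strongly informed by the profile depth
#' and curvature; K (through internal advection) and eps (momentum
#' only) are weaker.
#'
#' @param n_seeds number of replicates.
#' @param seed master seed (replicate seeds derive from it).
#' @param true_params true [ModelParams-class] (rate interpreted dark).
#' @param sigma sensor noise SD (mol m-3).
#' @param nx,nz fit grid size.
#' @param restarts,maxit optimizer budget per replicate.
#' @param advection physics mode for both generation and fit.
#' @return data.frame per replicate: estimates, true values, relative
#'   errors.
#' @export
recoveryStudy <- function(n_seeds = 10L, seed = 1L,
                          true_params = makeModelParams(
                            rate = -1e-3, permeability = 1e-10,
                            porosity = 0.5, diffRatio = 0.7),
                          sigma = 2e-3, nx = 36L, nz = 40L,
                          restarts = 1L, maxit = 200L, advection = FALSE) {
  xmm <- seq(0, 6, length.out = 48)
  elev <- 0.3 + 0.9 * exp(-((xmm - 3) / 1.1)^2)
  domain <- buildDomain(elev, width_m = 0.006, nx = nx, nz = nz)
  inlet <- list(type = "velocity",
                profile = function(z) 0.1 * (2 * z / 0.005 - (z / 0.005)^2))
  fl_true <- solveFlow(domain, true_params, inlet = inlet,
                       advection = advection)
  out <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    tr <- genO2Transect(domain, true_params,
                        noise = sensorNoiseSpec(sigma_conc = sigma,
                                                seed = seed * 1000L + s),
                        light = FALSE, inlet = inlet, advection = advection,
                        flow = fl_true)
    fit <- fitParameters(domain, tr,
                         spec = fitSpec(free = c("R", "K", "eps", "C"),
                                        restarts = restarts, maxit = maxit),
                         base_params = true_params, inlet = inlet,
                         advection = advection, seed = seed + s)
    p <- fit@params
    out[[s]] <- data.frame(
      seed = s,
      R_est = p@rate, K_est = p@permeability,
      eps_est = p@porosity, C_est = p@diffRatio,
      R_true = -abs(true_params@rate), K_true = true_params@permeability,
      eps_true = true_params@porosity, C_true = true_params@diffRatio,
      objective = fit@objective)
  }
  res <- do.call(rbind, out)
  res$R_relerr <- abs(res$R_est - res$R_true) / abs(res$R_true)
  res$K_relerr <- abs(res$K_est - res$K_true) / res$K_true
  res$eps_relerr <- abs(res$eps_est - res$eps_true) / res$eps_true
  res$C_relerr <- abs(res$C_est - res$C_true) / res$C_true
  res
}
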