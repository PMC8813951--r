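#' @import methods
#' @importFrom stats aggregate approx coef lm median optim plogis qlogis
#'   quantile rnorm runif sd setNames cor
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

## Patch-type label codes used throughout: rasters store integers,
## 0 = background, 1 = CDB (cyanobacteria-dominated base), 2 = DDP
## (diatom-dominated patch), 3 = KDP (Klebsormidiophyceae-dominated patch).
PATCH_LEVELS <- c(CDB = 1L, DDP = 2L, KDP = 3L)

#' Patch-type codes
#'
#' Integer codes used in [PatchLabelMap-class] rasters: `CDB = 1`,
#' `DDP = 2`, `KDP = 3`; `0` marks background (no biofilm).
#'
#' @return Named integer vector of patch codes.
#' @export
#' @examples
#' patchLevels()
patchLevels <- function() PATCH_LEVELS

#' ElevationMap: biofilm surface heights over the substrate
#'
#' A 2D raster of biofilm surface heights (mm above the substrate plane),
#' the geometric backbone of the imaging analysis and of model-domain
#' construction. Row index runs along the flow (x), column index across it
#' (y); the origin sits at the upstream-left corner and pixels are
#' half-open intervals.
#'
#' @slot heights numeric matrix, heights in mm (finite, non-negative).
#' @slot pixelMM numeric length-2, pixel size in mm along (x, y).
#' @slot origin numeric length-2, offset of the raster origin in mm.
#' @exportClass ElevationMap
setClass("ElevationMap",
  representation(heights = "matrix", pixelMM = "numeric", origin = "numeric"),
  prototype(pixelMM = c(0.1, 0.1), origin = c(0, 0)))

setValidity("ElevationMap", function(object) {
  h <- object@heights
  if (!is.numeric(h)) return("heights must be a numeric matrix")
  if (any(!is.finite(h))) return("heights must be finite")
  if (any(h < 0)) return("heights must be non-negative")
  if (length(object@pixelMM) != 2L || any(object@pixelMM <= 0))
    return("pixelMM must be two positive values")
  TRUE
})

#' PatchLabelMap: per-pixel patch-type assignment
#'
#' Integer raster assigning each pixel to a biofilm patch type
#' (see [patchLevels()]); shares geometry with its paired
#' [ElevationMap-class].
#'
#' @slot labels integer matrix with values in \{0, 1, 2, 3\}.
#' @slot pixelMM numeric length-2, pixel size in mm.
#' @exportClass PatchLabelMap
setClass("PatchLabelMap",
  representation(labels = "matrix", pixelMM = "numeric"),
  prototype(pixelMM = c(0.1, 0.1)))

setValidity("PatchLabelMap", function(object) {
  l <- object@labels
  if (!all(l %in% c(0L, PATCH_LEVELS))) return("labels must be in {0,1,2,3}")
  if (length(object@pixelMM) != 2L || any(object@pixelMM <= 0))
    return("pixelMM must be two positive values")
  TRUE
})

#' OCTVolume: gray-level optical coherence tomography stack
#'
#' 3D array of 8-bit gray levels (0-255). The first two indices follow the
#' raster convention of [ElevationMap-class]; the third runs upward from
#' the substrate. `substrateIndex` marks the highly reflective substrate
#' plane (z slice).
#'
#' @slot intensity 3D numeric array of gray levels in [0, 255].
#' @slot voxelMM numeric length-3, voxel size in mm (x, y, z axial).
#' @slot substrateIndex integer z index of the substrate plane.
#' @exportClass OCTVolume
setClass("OCTVolume",
  representation(intensity = "array", voxelMM = "numeric",
                 substrateIndex = "integer"),
  prototype(substrateIndex = 1L))

setValidity("OCTVolume", function(object) {
  a <- object@intensity
  if (length(dim(a)) != 3L) return("intensity must be a 3D array")
  if (min(a) < 0 || max(a) > 255) return("gray levels must lie in [0,255]")
  if (length(object@voxelMM) != 3L || any(object@voxelMM <= 0))
    return("voxelMM must be three positive values")
  if (object@substrateIndex < 1L || object@substrateIndex > dim(a)[3])
    return("substrateIndex outside volume")
  TRUE
})

#' MicroprofileTransect: ordered O2 microsensor depth profiles
#'
#' A set of vertical O2 concentration profiles measured along the flow
#' direction. Samples are stored long-format; `z_mm` is height above the
#' substrate and increases within each profile in fixed sensor steps
#' (50 um by default).
#'
#' @slot samples data.frame with columns `profile` (id), `x_mm`, `z_mm`,
#'   `conc` (mol m-3).
#' @slot light logical, light (TRUE) or dark (FALSE) condition.
#' @slot flow character, flow condition label (e.g. "slow", "fast").
#' @slot patch character, patch-type label.
#' @slot surfaceZ named numeric, per-profile biofilm surface height (mm);
#'   may be empty until aligned.
#' @slot metadata list of free-form provenance (seeds, true parameters of
#'   forward-modelled transects, ...).
#' @exportClass MicroprofileTransect
setClass("MicroprofileTransect",
  representation(samples = "data.frame", light = "logical",
                 flow = "character", patch = "character",
                 surfaceZ = "numeric", metadata = "list"),
  prototype(light = FALSE, flow = "slow", patch = "CDB",
            surfaceZ = numeric(0), metadata = list()))

setValidity("MicroprofileTransect", function(object) {
  s <- object@samples
  need <- c("profile", "x_mm", "z_mm", "conc")
  if (!all(need %in% names(s)))
    return(paste("samples needs columns:", paste(need, collapse = ", ")))
  for (p in unique(s$profile)) {
    z <- s$z_mm[s$profile == p]
    if (any(diff(z) <= 0)) return("z_mm must be strictly increasing per profile")
  }
  TRUE
})

#' ModelParams: physical parameters of the coupled flow/transport model
#'
#' Parameters of the 2D free-flow/porous-biofilm model: biofilm porosity
#' \eqn{\epsilon}, permeability K (m2), effective diffusivity ratio
#' C = D_eff/D_aq, turbulent Prandtl number P_rt, eddy viscosity
#' \eqn{\nu_t} (m2 s-1), volumetric O2 reaction rate R (mol m-3 s-1;
#' negative = dark respiration, positive = net photosynthesis), plus
#' fluid constants. The eddy diffusivity is derived:
#' D_t = \eqn{\nu_t} / P_rt.
#'
#' @slot porosity numeric in (0, 1].
#' @slot permeability numeric > 0, m2.
#' @slot diffRatio numeric in (0, 1], D_eff/D_aq.
#' @slot prandtlT numeric > 0.
#' @slot eddyVisc numeric >= 0, m2 s-1.
#' @slot rate numeric, mol m-3 s-1 (sign encodes light/dark metabolism).
#' @slot Daq numeric > 0, molecular O2 diffusivity in water, m2 s-1.
#' @slot nu numeric > 0, kinematic viscosity, m2 s-1.
#' @slot rho numeric > 0, density, kg m-3.
#' @exportClass ModelParams
setClass("ModelParams",
  representation(porosity = "numeric", permeability = "numeric",
                 diffRatio = "numeric", prandtlT = "numeric",
                 eddyVisc = "numeric", rate = "numeric",
                 Daq = "numeric", nu = "numeric", rho = "numeric"),
  prototype(porosity = 0.5, permeability = 1e-10, diffRatio = 0.7,
            prandtlT = 1, eddyVisc = 1e-5, rate = 0,
            Daq = 1.67e-9, nu = 1.139e-6, rho = 999.1))

setValidity("ModelParams", function(object) {
  if (object@porosity <= 0 || object@porosity > 1)
    return("porosity must be in (0,1]")
  if (object@permeability <= 0) return("permeability must be > 0")
  if (object@diffRatio <= 0 || object@diffRatio > 1)
    return("diffRatio must be in (0,1]")
  if (object@prandtlT <= 0) return("prandtlT must be > 0")
  if (object@eddyVisc < 0) return("eddyVisc must be >= 0")
  if (object@Daq <= 0 || object@nu <= 0 || object@rho <= 0)
    return("fluid constants must be positive")
  TRUE
})

#' ModelDomain: discretized 2D water + biofilm domain
#'
#' Structured finite-volume grid of a vertical slice (x along flow, z up
#' from the substrate), with a biofilm indicator derived from an elevation
#' profile. The z grid is refined in a band covering the fluid-biofilm
#' interface and stretched geometrically above it.
#'
#' @slot xf numeric, x face coordinates (m), length nx + 1.
#' @slot zf numeric, z face coordinates (m), length nz + 1.
#' @slot biofilm logical matrix (nx x nz), TRUE where the cell is biofilm.
#' @slot elevation numeric length nx, biofilm surface height (m) at cell
#'   centres (after optional smoothing/clipping).
#' @exportClass ModelDomain
setClass("ModelDomain",
  representation(xf = "numeric", zf = "numeric", biofilm = "matrix",
                 elevation = "numeric"))

setValidity("ModelDomain", function(object) {
  if (any(diff(object@xf) <= 0) || any(diff(object@zf) <= 0))
    return("face coordinates must be strictly increasing")
  nx <- length(object@xf) - 1L; nz <- length(object@zf) - 1L
  if (!identical(dim(object@biofilm), c(nx, nz)))
    return("biofilm indicator must be nx x nz")
  if (length(object@elevation) != nx)
    return("elevation must have one value per column")
  TRUE
})

#' FlowField: steady velocity and pressure on a ModelDomain
#'
#' Staggered (MAC) fields from [solveFlow()]: `u` on vertical faces
#' ((nx+1) x nz), `w` on horizontal faces (nx x (nz+1)), kinematic
#' pressure `p` (p/rho, m2 s-2) at cell centres.
#'
#' @slot u,w,p numeric matrices (see description).
#' @slot domain the [ModelDomain-class] solved on.
#' @slot params the [ModelParams-class] used.
#' @slot diagnostics list (continuity residual, Picard history, ...).
#' @exportClass FlowField
setClass("FlowField",
  representation(u = "matrix", w = "matrix", p = "matrix",
                 domain = "ModelDomain", params = "ModelParams",
                 diagnostics = "list"))

#' ConcField: steady O2 concentration on a ModelDomain
#'
#' Cell-centred concentration (mol m-3) from [solveTransport()].
#'
#' @slot conc numeric matrix (nx x nz).
#' @slot domain the [ModelDomain-class].
#' @slot params the [ModelParams-class] used.
#' @slot rate numeric, volumetric reaction rate applied (mol m-3 s-1).
#' @slot diagnostics list (negative-concentration diagnostics, ...).
#' @exportClass ConcField
setClass("ConcField",
  representation(conc = "matrix", domain = "ModelDomain",
                 params = "ModelParams", rate = "numeric",
                 diagnostics = "list"))

#' FitResult: outcome of transect parameter estimation
#'
#' @slot params optimised [ModelParams-class].
#' @slot objective numeric, sum of squared residuals ((mol m-3)^2).
#' @slot correlations numeric, per-profile Pearson correlation between
#'   measured and modelled concentrations.
#' @slot trace data.frame, best objective per restart plus counts.
#' @slot convergence list with optim convergence codes and settings.
#' @exportClass FitResult
setClass("FitResult",
  representation(params = "ModelParams", objective = "numeric",
                 correlations = "numeric", trace = "data.frame",
                 convergence = "list"))

setValidity("FitResult", function(object) {
  if (object@objective < 0) return("objective must be non-negative")
  cc <- object@correlations
  if (length(cc) && any(abs(cc[is.finite(cc)]) > 1 + 1e-12))
    return("correlations must lie in [-1,1]")
  TRUE
})
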