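#' Accessors for biofilmO2 classes
#'
#' Small accessor family: `heights()` and `labelMatrix()` return the
#' underlying rasters, `pixelSize()` the pixel size in mm, `samples()`
#' the long-format sample table of a transect, `concMatrix()` /
#' `velocityU()` / `velocityW()` / `pressureField()` the gridded fields,
#' `eddyDiff()` the derived eddy diffusivity D_t = nu_t / P_rt.
#'
#' @param object an object of the documented classes.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("heights", function(object) standardGeneric("heights"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("concMatrix", function(object) standardGeneric("concMatrix"))
#' @rdname accessors
#' @export
setGeneric("velocityU", function(object) standardGeneric("velocityU"))
#' @rdname accessors
#' @export
setGeneric("velocityW", function(object) standardGeneric("velocityW"))
#' @rdname accessors
#' @export
setGeneric("pressureField", function(object) standardGeneric("pressureField"))
#' @rdname accessors
#' @export
setGeneric("eddyDiff", function(object) standardGeneric("eddyDiff"))

#' @rdname accessors
setMethod("heights", "ElevationMap", function(object) object@heights)
#' @rdname accessors
setMethod("labelMatrix", "PatchLabelMap", function(object) object@labels)
#' @rdname accessors
setMethod("pixelSize", "ElevationMap", function(object) object@pixelMM)
#' @rdname accessors
setMethod("pixelSize", "PatchLabelMap", function(object) object@pixelMM)
#' @rdname accessors
setMethod("samples", "MicroprofileTransect", function(object) object@samples)
#' @rdname accessors
setMethod("concMatrix", "ConcField", function(object) object@conc)
#' @rdname accessors
setMethod("velocityU", "FlowField", function(object) object@u)
#' @rdname accessors
setMethod("velocityW", "FlowField", function(object) object@w)
#' @rdname accessors
setMethod("pressureField", "FlowField", function(object) object@p)
#' @rdname accessors
setMethod("eddyDiff", "ModelParams",
          function(object) object@eddyVisc / object@prandtlT)

setMethod("show", "ElevationMap", function(object) {
  d <- dim(object@heights)
  cat(sprintf("ElevationMap: %d x %d px (%.3g x %.3g mm), heights %.3g-%.3g mm\n",
              d[1], d[2], d[1] * object@pixelMM[1], d[2] * object@pixelMM[2],
              min(object@heights), max(object@heights)))
})

setMethod("show", "PatchLabelMap", function(object) {
  tab <- table(factor(object@labels, levels = c(0L, PATCH_LEVELS),
                      labels = c("background", names(PATCH_LEVELS))))
  cat("PatchLabelMap:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "OCTVolume", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("OCTVolume: %d x %d x %d voxels, axial %.4g mm, substrate slice %d\n",
              d[1], d[2], d[3], object@voxelMM[3], object@substrateIndex))
})

setMethod("show", "MicroprofileTransect", function(object) {
  s <- object@samples
  cat(sprintf("MicroprofileTransect: %d profiles, %d samples, %s/%s, patch %s\n",
              length(unique(s$profile)), nrow(s),
              if (object@light) "light" else "dark", object@flow, object@patch))
})

setMethod("show", "ModelParams", function(object) {
  cat(sprintf(paste0("ModelParams: eps=%.3g K=%.3g m2 C=%.3g P_rt=%.3g ",
                     "nu_t=%.3g m2/s R=%.3g mol/m3/s\n"),
              object@porosity, object@permeability, object@diffRatio,
              object@prandtlT, object@eddyVisc, object@rate))
})

setMethod("show", "ModelDomain", function(object) {
  nx <- length(object@xf) - 1L; nz <- length(object@zf) - 1L
  cat(sprintf("ModelDomain: %d x %d cells, %.3g x %.3g m, biofilm fraction %.3f\n",
              nx, nz, diff(range(object@xf)), diff(range(object@zf)),
              mean(object@biofilm)))
})

setMethod("show", "FlowField", function(object) {
  cat(sprintf("FlowField: max |u| = %.4g m/s, continuity residual %.2g\n",
              max(abs(object@u)), object@diagnostics$continuity_residual))
})

setMethod("show", "ConcField", function(object) {
  cat(sprintf("ConcField: conc %.4g-%.4g mol/m3, rate %.3g mol/m3/s\n",
              min(object@conc), max(object@conc), object@rate))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: SSR = %.4g, median profile r = %.3f\n",
              object@objective, median(object@correlations)))
  show(object@params)
})
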