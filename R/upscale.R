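#' Cross-sectional mean flow velocity
#'
#' u = Q / (h w): discharge divided by the flow cross-section.
#'
#' @param Q discharge (m3 s-1).
#' @param h water depth (m).
#' @param w flume width (m).
#' @return mean velocity (m s-1).
#' @export
#' @examples
#' meanVelocity(2.22e-4, 0.022, 0.1)  # ~0.10 m/s
meanVelocity <- function(Q, h, w) {
  if (h <= 0 || w <= 0) stop("depth and width must be positive")
  Q / (h * w)
}

#' Turbulent kinetic energy from RMS velocity fluctuations
#'
#' TKE = (u'^2 + v'^2 + w'^2) / 2.
#'
#' @param u_rms,v_rms,w_rms RMS velocity fluctuations (m s-1).
#' @return TKE (m2 s-2).
#' @export
#' @examples
#' tke(0.01, 0.01, 0.01)  # 1.5e-4
tke <- function(u_rms, v_rms, w_rms) {
  (u_rms^2 + v_rms^2 + w_rms^2) / 2
}

#' Areal O2 flux of a patch from its volumetric rate
#'
#' Converts a volumetric metabolic rate to a flux across the projected
#' planar area by multiplying with the mean biofilm thickness,
#' volume/area expressed in mm (the convention under which the study's
#' printed patch budgets are internally consistent; the resulting
#' numbers are reported in the study's printed unit, mmol m-2 s-1,
#' with this caveat).
#'
#' @param rate_vol volumetric rate (mmol m-3 s-1).
#' @param volume_mm3 patch biovolume (mm3).
#' @param area_mm2 patch projected area (mm2), > 0.
#' @return areal flux in the printed units.
#' @export
#' @examples
#' patchArealFlux(-0.98, 591, 1411)  # -0.41
patchArealFlux <- function(rate_vol, volume_mm3, area_mm2) {
  if (area_mm2 <= 0) stop("area must be positive")
  rate_vol * (volume_mm3 / area_mm2)
}

#' Per-patch O2 budget
#'
#' Assembles volumetric rates and areal fluxes for one patch type. The
#' net ecosystem production is NEP = NP + R with R negative for
#' consumption (i.e. NP - |R|).
#'
#' @param patch patch-type label.
#' @param R_vol dark respiration rate (mmol m-3 s-1, negative).
#' @param NP_vol net photosynthesis rate (mmol m-3 s-1).
#' @param volume_mm3,area_mm2 patch geometry.
#' @return one-row data.frame with volumetric and areal R, NP, NEP.
#' @export
patchBudget <- function(patch, R_vol, NP_vol, volume_mm3, area_mm2) {
  NEP_vol <- NP_vol + R_vol
  data.frame(patch = patch, R_vol = R_vol, NP_vol = NP_vol,
             NEP_vol = NEP_vol,
             R_area = patchArealFlux(R_vol, volume_mm3, area_mm2),
             NP_area = patchArealFlux(NP_vol, volume_mm3, area_mm2),
             NEP_area = patchArealFlux(NEP_vol, volume_mm3, area_mm2),
             volume_mm3 = volume_mm3, area_mm2 = area_mm2)
}

#' Landscape O2 budget from patch budgets
#'
#' Volume-weighted upscaling of patch metabolic rates to the whole
#' biofilm landscape: the landscape volumetric rate is the
#' biovolume-weighted mean of the patch rates, and the landscape areal
#' flux is that rate times total volume / total area (in mm). Spatial
#' arrangement and patch interactions are not considered.
#'
#' @param budgets data.frame of [patchBudget()] rows.
#' @return one-row data.frame with landscape volumetric and areal R,
#'   NP, NEP, plus total area and volume.
#' @export
#' @examples
#' b <- rbind(patchBudget("CDB", -0.98, 5.1, 591, 1411),
#'            patchBudget("DDP", -0.55, 3.0, 253, 408),
#'            patchBudget("KDP", -0.88, 2.5, 189, 197))
#' landscapeBudget(b)  # R_vol -0.86, NP_vol 4.11
landscapeBudget <- function(budgets) {
  V <- sum(budgets$volume_mm3); A <- sum(budgets$area_mm2)
  if (V <= 0) stop("total biofilm volume must be positive")
  wmean <- function(x) sum(x * budgets$volume_mm3) / V
  R_vol <- wmean(budgets$R_vol); NP_vol <- wmean(budgets$NP_vol)
  NEP_vol <- NP_vol + R_vol
  thick <- V / A
  data.frame(patch = "landscape", R_vol = R_vol, NP_vol = NP_vol,
             NEP_vol = NEP_vol, R_area = R_vol * thick,
             NP_area = NP_vol * thick, NEP_area = NEP_vol * thick,
             volume_mm3 = V, area_mm2 = A)
}

#' Flume-study patch geometry (imaging-derived)
#'
#' Published landscape geometry of the three patch types under the two
#' flow conditions (areas and biovolumes from OCT mosaics, heights as
#' mean +- SD), used as worked-example inputs for the upscaling
#' functions and as generator targets for the synthetic landscapes.
#'
#' @return data.frame: flow, patch, height mean/SD (mm), area (mm2),
#'   coverage (%), volume (mm3), volume share (%).
#' @export
studyGeometry <- function() {
  data.frame(
    flow = rep(c("slow", "fast"), each = 3),
    patch = rep(c("CDB", "DDP", "KDP"), 2),
    height_mean_mm = c(0.39, 0.58, 1.09, 0.38, 0.51, 1.27),
    height_sd_mm = c(0.15, 0.15, 0.24, 0.11, 0.13, 0.27),
    area_mm2 = c(1411, 408, 197, 1145, 314, 142),
    coverage_pct = c(70.0, 20.2, 9.8, 71.5, 19.6, 8.9),
    volume_mm3 = c(591, 253, 189, 440, 174, 152),
    volume_pct = c(57, 25, 18, 57, 23, 20))
}

#' Flume-study volumetric metabolic rates (model-derived)
#'
#' Published volumetric rates of dark respiration (R, negative) and net
#' photosynthesis (NP) per patch type and flow condition, in
#' mmol O2 m-3 s-1; inputs for the upscaling worked examples.
#'
#' @return data.frame: flow, patch, R_vol, NP_vol.
#' @export
studyRates <- function() {
  data.frame(
    flow = rep(c("slow", "fast"), each = 3),
    patch = rep(c("CDB", "DDP", "KDP"), 2),
    R_vol = c(-0.98, -0.55, -0.88, -1.61, -1.11, -1.37),
    NP_vol = c(5.1, 3.0, 2.5, 5.38, 2.06, 1.1))
}

#' Rebuild the per-flow landscape budget tables from study inputs
#'
#' Combines [studyGeometry()] and [studyRates()] through
#' [patchBudget()] and [landscapeBudget()] to reproduce the published
#' patch and landscape O2 budget table.
#'
#' @param flow `"slow"` or `"fast"`.
#' @return data.frame of patch rows plus the landscape row.
#' @export
#' @examples
#' round(studyBudget("slow")$R_vol, 2)
studyBudget <- function(flow = c("slow", "fast")) {
  flow <- match.arg(flow)
  geo <- studyGeometry(); rt <- studyRates()
  geo <- geo[geo$flow == flow, ]; rt <- rt[rt$flow == flow, ]
  b <- do.call(rbind, lapply(seq_len(nrow(geo)), function(j)
    patchBudget(geo$patch[j], rt$R_vol[j], rt$NP_vol[j],
                geo$volume_mm3[j], geo$area_mm2[j])))
  rbind(b, landscapeBudget(b))
}
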