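#' Linear two-point microsensor calibration
#'
#' Affine map sending the sensor reading in anoxic solution to 0 and the
#' reading in air-saturated water to the air-saturation concentration.
#'
#' @param raw_signals numeric sensor readings.
#' @param cal_air_signal reading in air-saturated water.
#' @param cal_zero_signal reading in anoxic (ascorbate) solution.
#' @param conc_air_sat air-saturation O2 concentration (mol m-3).
#' @return concentrations (mol m-3).
#' @export
#' @examples
#' calibrateLinear(c(10, 55, 100), 100, 10, 0.3)
calibrateLinear <- function(raw_signals, cal_air_signal, cal_zero_signal,
                            conc_air_sat) {
  if (cal_air_signal == cal_zero_signal)
    stop("calibration signals must differ")
  (raw_signals - cal_zero_signal) / (cal_air_signal - cal_zero_signal) *
    conc_air_sat
}

#' Correct sensor drift against bulk-water readings
#'
#' Compensates slow sensor drift by linear interpolation of repeated
#' bulk-water O2 readings: each sample is rescaled so that the
#' interpolated bulk reading at its time maps to the reference bulk
#' concentration.
#'
#' @param times sample times (any monotone numeric unit).
#' @param values sample concentrations.
#' @param bulk_times,bulk_values times and values of bulk readings; must
#'   bracket the sample times.
#' @param ref_bulk reference bulk concentration (default: first bulk
#'   reading).
#' @return corrected sample values (empty input passes through).
#' @export
driftCorrect <- function(times, values, bulk_times, bulk_values,
                         ref_bulk = bulk_values[1]) {
  if (!length(times)) return(values)
  if (length(bulk_times) < 2)
    stop("need at least two bulk readings")
  if (min(times) < min(bulk_times) || max(times) > max(bulk_times))
    stop("bulk readings must bracket the sample times")
  bulk_at <- approx(bulk_times, bulk_values, xout = times)$y
  values * ref_bulk / bulk_at
}

#' Locate the biofilm surface from paired light/dark profiles
#'
#' Refines an OCT-derived surface height using the inflection point of
#' the O2 profiles: the height of maximum summed absolute second
#' derivative of the light and dark profiles (centred second
#' differences), searched within +-`window_mm` of the OCT height.
#' Summing the per-condition curvature magnitudes uses both conditions
#' without the cancellation that averaging them would suffer when net
#' photosynthesis and respiration are of similar size. Pre-smoothing is
#' off by default -- a running mean displaces the curvature maximum of a
#' sharp interface by about a sensor step -- and can be enabled
#' (`smooth_window = 3`) for noisy sensor data. A profile with no
#' curvature signal in the window falls back to the OCT height with a
#' warning.
#'
#' @param profile_light,profile_dark data.frames with columns `z_mm`,
#'   `conc`, on a common z grid (the dark profile is interpolated onto
#'   the light grid if needed).
#' @param oct_height_mm OCT-derived surface height (mm).
#' @param window_mm half-width of the search window (mm).
#' @param smooth_window odd running-mean window applied to each profile
#'   before differencing (1 = none).
#' @return surface height (mm).
#' @export
locateSurface <- function(profile_light, profile_dark, oct_height_mm,
                          window_mm = 0.3, smooth_window = 1L) {
  z <- profile_light$z_mm
  cl <- profile_light$conc
  cd <- if (isTRUE(all.equal(profile_dark$z_mm, z))) profile_dark$conc
        else approx(profile_dark$z_mm, profile_dark$conc, xout = z, rule = 2)$y
  cl_s <- movingAverage(cl, smooth_window)
  cd_s <- movingAverage(cd, smooth_window)
  n <- length(z)
  if (n < 3) { warning("profile too short; using OCT height"); return(oct_height_mm) }
  curv <- function(v) abs(v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)])
  d2 <- curv(cl_s) + curv(cd_s)
  cm <- (cl_s + cd_s) / 2
  zin <- z[2:(n - 1)]
  inwin <- abs(zin - oct_height_mm) <= window_mm
  if (!any(inwin)) {
    warning("search window outside profile; using OCT height")
    return(oct_height_mm)
  }
  d2w <- d2[inwin]
  if (max(d2w) <= 1e-12 * max(abs(cm), 1e-300)) {
    warning("no curvature signal; using OCT height")
    return(oct_height_mm)
  }
  zin[inwin][which.max(d2w)]
}

#' Triangulate a transect into a 2D concentration gradient field
#'
#' Builds a triangulation of the transect's (x, z) sample points --
#' profiles at x stations with fixed vertical steps form a structured
#' grid; each grid quad is split into two triangles -- and computes the
#' concentration gradient per triangle from the exact plane through its
#' three vertices (hence exact for affine fields). Node gradients are
#' area-weighted averages over incident triangles.
#'
#' Direction convention: the reported angle is the direction of
#' transport down the gradient (\eqn{-\nabla c}), measured with 0
#' degrees pointing downstream (+x) and 90 degrees toward the substrate
#' (-z), in [0, 360). A dark diffusion-dominated profile therefore
#' points at 90 degrees; angles above 90 bend against the flow.
#'
#' @param transect a [MicroprofileTransect-class] with >= 2 profiles.
#' @return data.frame of nodes: `x_mm`, `z_mm`, `conc`, `grad_mag`
#'   (mol m-3 mm-1), `grad_angle_deg`.
#' @export
triangulateField <- function(transect) {
  s <- samples(transect)
  xs <- sort(unique(s$x_mm))
  if (length(xs) < 2) stop("need >= 2 profiles (non-collinear points)")
  ## common z grid across adjacent profiles
  tri <- list(); ti <- 1L
  node_key <- paste(s$x_mm, s$z_mm)
  for (j in seq_len(length(xs) - 1L)) {
    zl <- s$z_mm[s$x_mm == xs[j]]
    zr <- s$z_mm[s$x_mm == xs[j + 1L]]
    zz <- sort(intersect(zl, zr))
    if (length(zz) < 2) next
    for (m in seq_len(length(zz) - 1L)) {
      a <- c(xs[j], zz[m]); b <- c(xs[j + 1L], zz[m])
      cc <- c(xs[j], zz[m + 1L]); d <- c(xs[j + 1L], zz[m + 1L])
      tri[[ti]] <- rbind(a, b, cc); ti <- ti + 1L
      tri[[ti]] <- rbind(b, d, cc); ti <- ti + 1L
    }
  }
  if (!length(tri)) stop("degenerate transect: all points collinear")

  conc_of <- setNames(s$conc, node_key)
  nodes <- unique(s[, c("x_mm", "z_mm", "conc")])
  gsum <- matrix(0, nrow(nodes), 2)
  asum <- numeric(nrow(nodes))
  nkey <- paste(nodes$x_mm, nodes$z_mm)
  for (t in tri) {
    key <- paste(t[, 1], t[, 2])
    cv <- conc_of[key]
    ## plane fit: solve [x z 1] beta = c
    M <- cbind(t[, 1], t[, 2], 1)
    beta <- solve(M, cv)
    area <- abs(det(cbind(t[2, ] - t[1, ], t[3, ] - t[1, ]))) / 2
    rows <- match(key, nkey)
    gsum[rows, 1] <- gsum[rows, 1] + beta[1] * area
    gsum[rows, 2] <- gsum[rows, 2] + beta[2] * area
    asum[rows] <- asum[rows] + area
  }
  ok <- asum > 0
  gx <- ifelse(ok, gsum[, 1] / asum, 0)
  gz <- ifelse(ok, gsum[, 2] / asum, 0)
  ## transport direction: -grad c; 0 deg = +x (downstream), 90 = -z (down)
  fx <- -gx; fz <- -gz
  ang <- (atan2(-fz, fx) * 180 / pi) %% 360
  mag <- sqrt(gx^2 + gz^2)
  ang[mag == 0] <- 0
  data.frame(x_mm = nodes$x_mm, z_mm = nodes$z_mm, conc = nodes$conc,
             grad_mag = mag, grad_angle_deg = ang)
}

#' Pool below-surface concentration samples by group
#'
#' Pools all measurements below the aligned biofilm surface across a set
#' of transects, grouped by patch type, light/dark and flow condition,
#' and reports group sizes and summary quantiles. Feed the returned
#' per-group samples to any standard test (Wilcoxon, Welch t, ...).
#'
#' @param transects list of [MicroprofileTransect-class] objects with
#'   `surfaceZ` set.
#' @return list with `samples` (data.frame: group columns + `conc`) and
#'   `summary` (per-group n, median, q25, q75). Groups with all samples
#'   above the surface are empty (n = 0 rows).
#' @export
poolDistributions <- function(transects) {
  rows <- lapply(transects, function(tr) {
    s <- samples(tr)
    surf <- tr@surfaceZ[as.character(s$profile)]
    keep <- !is.na(surf) & s$z_mm < surf
    if (!any(keep)) return(NULL)
    data.frame(patch = tr@patch, light = tr@light, flow = tr@flow,
               conc = s$conc[keep])
  })
  all <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(all))
    all <- data.frame(patch = character(0), light = logical(0),
                      flow = character(0), conc = numeric(0))
  if (nrow(all)) {
    sm <- aggregate(conc ~ patch + light + flow, data = all, FUN = function(v)
      c(n = length(v), median = median(v),
        q25 = quantile(v, 0.25, names = FALSE),
        q75 = quantile(v, 0.75, names = FALSE)))
    summary <- cbind(sm[, 1:3], as.data.frame(sm$conc))
  } else summary <- data.frame()
  list(samples = all, summary = summary)
}
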