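# Digital phantoms: hot spherical lesions on a cooler background with a
# uniform liver reference sphere, on voxel grids in the clinical PET range
# (3.4x3.4x2.0 to 4.3x4.3x5.0 mm). These provide analytic ground truth for
# validating feature extraction and normalization without any image data.

#' Specification of a synthetic PET phantom
#'
#' @param shape Grid size (nx, ny, nz) in voxels.
#' @param spacing Voxel spacing (mm); default 3.5 x 3.5 x 3.4, the most
#'   common clinical PET grid emulated here.
#' @param backgroundSUV Uniform background uptake.
#' @param lesionCenter,lesionRadius Lesion sphere center (mm, physical
#'   coordinates) and radius (mm).
#' @param lesionSUV Lesion uptake (its meaning depends on `profile`).
#' @param profile "uniform" (hard-edged sphere at `lesionSUV`),
#'   "gaussian" (smooth radial fall-off from `lesionSUV` at the center to
#'   background, emulating scanner blur), or "gradient" (linear radial
#'   ramp from `lesionSUV` at the center to background at the surface).
#' @param liverCenter,liverRadius,liverSUV Uniform liver reference sphere.
#' @param noiseSigma Gaussian noise SD added to every voxel (clamped at 0).
#' @param seed RNG seed used when noise is drawn.
#' @return A `PhantomSpec` list.
#' @export
phantomSpec <- function(shape = c(48, 48, 48), spacing = c(3.5, 3.5, 3.4),
                        backgroundSUV = 1, lesionCenter = NULL,
                        lesionRadius = 15, lesionSUV = 8,
                        profile = c("uniform", "gaussian", "gradient"),
                        liverCenter = NULL, liverRadius = 12, liverSUV = 2,
                        noiseSigma = 0, seed = 1L) {
  profile <- match.arg(profile)
  extent <- shape * spacing
  if (is.null(lesionCenter)) lesionCenter <- extent * c(0.3, 0.3, 0.5)
  if (is.null(liverCenter)) liverCenter <- extent * c(0.72, 0.72, 0.5)
  spec <- list(shape = as.integer(shape), spacing = spacing,
               backgroundSUV = backgroundSUV, lesionCenter = lesionCenter,
               lesionRadius = lesionRadius, lesionSUV = lesionSUV,
               profile = profile, liverCenter = liverCenter,
               liverRadius = liverRadius, liverSUV = liverSUV,
               noiseSigma = noiseSigma, seed = as.integer(seed))
  if (sqrt(sum((lesionCenter - liverCenter)^2)) <=
      lesionRadius + liverRadius)
    stop("lesion and liver spheres must be disjoint")
  if (any(c(backgroundSUV, lesionSUV, liverSUV, noiseSigma) < 0))
    stop("SUV parameters and noise sigma must be >= 0")
  structure(spec, class = "PhantomSpec")
}

.voxelCenterDistances <- function(shape, spacing, center) {
  cx <- ((seq_len(shape[1]) - 0.5) * spacing[1] - center[1])^2
  cy <- ((seq_len(shape[2]) - 0.5) * spacing[2] - center[2])^2
  cz <- ((seq_len(shape[3]) - 0.5) * spacing[3] - center[3])^2
  sqrt(outer(outer(cx, cy, "+"), cz, "+"))
}

#' Generate a synthetic PET phantom with known ground truth
#'
#' Builds the SUV volume, the lesion mask (voxel centers within the lesion
#' sphere), and the liver mask from a [phantomSpec()]. Deterministic for a
#' fixed spec (the spec's seed governs the noise draw). The returned
#' `analyticTruth` holds closed-form feature values that are exact for the
#' noise-free uniform profile: Mean = Max = Min = lesion SUV, MTV = voxel
#' count x voxel volume, RA = background SUV (the rim lies wholly in
#' background when the spheres are separated), TLG = lesion SUV x MTV and
#' SAM = (lesion SUV - background) x MTV.
#'
#' @param spec A [phantomSpec()].
#' @return List with `volume` ([SUVolume-class]), `lesion`, `liver`
#'   ([RegionMask-class]) and `analyticTruth` (named list).
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  shape <- spec$shape; sp <- spec$spacing
  if (any(spec$lesionCenter < 0 | spec$lesionCenter > shape * sp) ||
      any(spec$liverCenter < 0 | spec$liverCenter > shape * sp))
    stop("sphere centers must lie inside the grid")
  dLesion <- .voxelCenterDistances(shape, sp, spec$lesionCenter)
  dLiver <- .voxelCenterDistances(shape, sp, spec$liverCenter)
  lesion <- dLesion <= spec$lesionRadius
  liver <- dLiver <= spec$liverRadius
  vol <- array(spec$backgroundSUV, shape)
  amp <- spec$lesionSUV - spec$backgroundSUV
  if (spec$profile == "uniform") {
    vol[lesion] <- spec$lesionSUV
  } else if (spec$profile == "gaussian") {
    # FWHM equal to the lesion radius: a hot core with blurred edges
    sigma <- spec$lesionRadius / 2.355
    vol <- vol + amp * exp(-dLesion^2 / (2 * sigma^2))
  } else {  # gradient
    ramp <- pmax(0, 1 - dLesion / spec$lesionRadius)
    vol <- vol + amp * ramp
  }
  vol[liver] <- spec$liverSUV
  if (spec$noiseSigma > 0) {
    set.seed(spec$seed)
    vol <- vol + array(rnorm(length(vol), 0, spec$noiseSigma), shape)
    vol[vol < 0] <- 0
  }
  vv <- prod(sp) / 1000
  truth <- list(
    MTV = sum(lesion) * vv,
    liverMean = spec$liverSUV,
    backgroundSUV = spec$backgroundSUV)
  if (spec$profile == "uniform" && spec$noiseSigma == 0) {
    truth$Mean <- truth$Max <- truth$Min <- spec$lesionSUV
    truth$TLG <- spec$lesionSUV * truth$MTV
    truth$RA <- spec$backgroundSUV
    truth$SAM <- (spec$lesionSUV - spec$backgroundSUV) * truth$MTV
  }
  list(volume = SUVolume(vol, spacing = sp),
       lesion = RegionMask(lesion, spacing = sp, label = "lesion"),
       liver = RegionMask(liver, spacing = sp, label = "liver"),
       analyticTruth = truth)
}
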