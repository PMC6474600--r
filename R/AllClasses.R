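#' @import methods
#' @importFrom stats quantile sd coef rexp runif rnorm pnorm qnorm p.adjust
#'   complete.cases cor plogis setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' Names of the 22 quantitative imaging features
#'
#' The feature panel computed by [extractFeatures()]: five standard PET
#' measures (Max, Peak, Mean, MTV, TLG) and seventeen additional descriptors
#' of the lesion uptake distribution, its grayscale quarters, and the lesion
#' rim (SAM, RA).
#'
#' @return Character vector of length 22, in canonical column order.
#' @export
featureNames <- function() {
  c("Max", "Peak", "Mean", "MTV", "TLG",
    "Min", "Std", "RMS",
    "FirstQuartile", "Median", "ThirdQuartile", "UpperAdjacent",
    "Q1Distribution", "Q2Distribution", "Q3Distribution", "Q4Distribution",
    "GlycolysisQ1", "GlycolysisQ2", "GlycolysisQ3", "GlycolysisQ4",
    "SAM", "RA")
}

#' Liver-normalization flags for the feature panel
#'
#' Which features are divided by the mean liver SUV during normalization.
#' Volume (MTV) and the grayscale-quarter percentages are ratios or volumes
#' and are left unchanged; every SUV-carrying feature is normalized.
#'
#' @return Named logical vector over [featureNames()].
#' @export
liverNormalizedFlags <- function() {
  flags <- setNames(rep(TRUE, 22L), featureNames())
  flags[c("MTV", "Q1Distribution", "Q2Distribution",
          "Q3Distribution", "Q4Distribution")] <- FALSE
  flags
}

#' SUVolume: a 3D standardized-uptake-value grid
#'
#' An S4 container for a body-weight-normalized SUV volume on an anisotropic
#' voxel grid. Values are unitless SUV; spacing is in mm.
#'
#' @slot values 3D numeric array of finite, non-negative SUV values.
#' @slot spacing Numeric length-3 voxel spacing (dx, dy, dz) in mm, all > 0.
#' @slot origin Numeric length-3 physical origin in mm.
#'
#' @export
setClass("SUVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("SUVolume", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("'values' must be a 3D array")
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    return("SUV values must be finite numerics")
  if (any(v < 0))
    return("SUV values must be non-negative")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("'spacing' must be three strictly positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("'origin' must be three finite values (mm)")
  TRUE
})

#' RegionMask: a binary region aligned to an SUVolume
#'
#' A lesion, rim, or liver reference region on the same voxel grid as its
#' companion [SUVolume-class].
#'
#' @slot values 3D logical array.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot origin Numeric length-3 physical origin in mm.
#' @slot label One of "lesion", "rim", "liver".
#'
#' @export
setClass("RegionMask",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 label = "character"),
  prototype(values = array(FALSE, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0), label = "lesion"))

setValidity("RegionMask", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("'values' must be a 3D array")
  if (!is.logical(v) || anyNA(v))
    return("mask values must be logical without NA")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("'spacing' must be three strictly positive values (mm)")
  if (length(object@label) != 1L ||
      !object@label %in% c("lesion", "rim", "liver"))
    return("'label' must be one of 'lesion', 'rim', 'liver'")
  TRUE
})

#' FeatureVector: the 22-feature panel for one lesion at one timepoint
#'
#' @slot values Named numeric vector over [featureNames()].
#' @slot liverNormalized Logical; whether SUV-carrying features were divided
#'   by the mean liver SUV.
#' @slot liverMeanSUV The liver mean used for normalization (NA when raw).
#' @slot subjectId Subject identifier.
#' @slot timepoint Scan timepoint label, e.g. "t0" or "t1".
#'
#' @export
setClass("FeatureVector",
  representation(values = "numeric", liverNormalized = "logical",
                 liverMeanSUV = "numeric", subjectId = "character",
                 timepoint = "character"),
  prototype(liverNormalized = FALSE, liverMeanSUV = NA_real_,
            subjectId = NA_character_, timepoint = NA_character_))

setValidity("FeatureVector", function(object) {
  v <- object@values
  if (!identical(names(v), featureNames()))
    return("'values' must be named exactly by featureNames(), in order")
  if (anyNA(v) || any(!is.finite(v)))
    return("feature values must be finite")
  if (length(object@liverNormalized) != 1L)
    return("'liverNormalized' must be a single logical")
  if (object@liverNormalized && !(is.finite(object@liverMeanSUV) &&
                                  object@liverMeanSUV > 0))
    return("normalized vectors must record a positive 'liverMeanSUV'")
  TRUE
})

#' LiverReference: mean hepatic uptake used for normalization
#'
#' @slot meanSUV Positive mean SUV over the liver measurement region.
#' @slot source "mask" when computed from a region, "scalar" when supplied.
#' @slot nVoxels Voxel count of the region (NA for scalar sources).
#'
#' @export
setClass("LiverReference",
  representation(meanSUV = "numeric", source = "character",
                 nVoxels = "integer"),
  prototype(source = "scalar", nVoxels = NA_integer_))

setValidity("LiverReference", function(object) {
  if (length(object@meanSUV) != 1L || !is.finite(object@meanSUV) ||
      object@meanSUV <= 0)
    return("'meanSUV' must be a single positive value")
  if (!object@source %in% c("mask", "scalar"))
    return("'source' must be 'mask' or 'scalar'")
  TRUE
})

#' CohortTable: per-subject features and disease-free survival outcomes
#'
#' Wraps a data.frame with one row per subject: an `id` column, DFS `time`
#' (months) and `event` (1 = recurrence or death, 0 = censored), and feature
#' columns prefixed `t0_` (baseline), `t1_` (post-treatment) and `delta_`
#' (baseline minus post-treatment). Subjects with a complete metabolic
#' response have no post-treatment lesion and carry NA in `t1_`/`delta_`
#' columns.
#'
#' @slot data The underlying data.frame.
#'
#' @export
setClass("CohortTable", representation(data = "data.frame"))

setValidity("CohortTable", function(object) {
  d <- object@data
  need <- c("id", "time", "event")
  if (!all(need %in% names(d)))
    return(paste("missing required column(s):",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyNA(d$time) || any(d$time <= 0))
    return("DFS 'time' must be positive and non-missing")
  if (!all(d$event %in% c(0, 1)))
    return("'event' must be 0 (censored) or 1 (recurrence or death)")
  t0 <- grep("^t0_", names(d), value = TRUE)
  for (col in grep("^delta_", names(d), value = TRUE)) {
    f <- sub("^delta_", "", col)
    c0 <- paste0("t0_", f); c1 <- paste0("t1_", f)
    if (c0 %in% names(d) && c1 %in% names(d)) {
      ok <- is.na(d[[col]]) | is.na(d[[c1]]) |
        abs(d[[col]] - (d[[c0]] - d[[c1]])) <= 1e-8 * pmax(1, abs(d[[col]]))
      if (!all(ok))
        return(paste0("'", col, "' is not t0 - t1 within tolerance"))
    }
  }
  TRUE
})
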