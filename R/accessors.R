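#' @rdname SUVolume-class
#' @param values 3D numeric array of SUV values.
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param origin Physical origin in mm.
#' @export
SUVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("SUVolume", values = array(as.double(values), dim(values)),
      spacing = as.double(spacing), origin = as.double(origin))
}

#' @rdname RegionMask-class
#' @param values 3D array coercible to logical (non-zero = inside).
#' @param spacing Voxel spacing in mm.
#' @param origin Physical origin in mm.
#' @param label Region label: "lesion", "rim" or "liver".
#' @export
RegionMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       label = "lesion") {
  new("RegionMask", values = array(as.logical(values != 0), dim(values)),
      spacing = as.double(spacing), origin = as.double(origin), label = label)
}

#' @rdname CohortTable-class
#' @param data data.frame with id/time/event and prefixed feature columns.
#' @export
CohortTable <- function(data) new("CohortTable", data = as.data.frame(data))

setGeneric("suvValues", function(x) standardGeneric("suvValues"))
setGeneric("spacing", function(x) standardGeneric("spacing"))
setGeneric("origin", function(x) standardGeneric("origin"))
setGeneric("maskLabel", function(x) standardGeneric("maskLabel"))
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))

#' Accessors for volumes and masks
#'
#' `suvValues` returns the raw array, `spacing` the voxel spacing in mm,
#' `origin` the physical origin, `maskLabel` the region label, `nVoxels`
#' the number of set mask voxels, and `voxelVolumeMl` the volume of a
#' single voxel in ml (product of spacings / 1000).
#'
#' @param x An [SUVolume-class] or [RegionMask-class].
#' @name volume-accessors
#' @aliases suvValues spacing origin maskLabel nVoxels voxelVolumeMl
NULL

#' @rdname volume-accessors
#' @export
setMethod("suvValues", "SUVolume", function(x) x@values)
#' @rdname volume-accessors
#' @export
setMethod("suvValues", "RegionMask", function(x) x@values)
#' @rdname volume-accessors
#' @export
setMethod("spacing", "SUVolume", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("spacing", "RegionMask", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("origin", "SUVolume", function(x) x@origin)
#' @rdname volume-accessors
#' @export
setMethod("origin", "RegionMask", function(x) x@origin)
#' @rdname volume-accessors
#' @export
setMethod("maskLabel", "RegionMask", function(x) x@label)
#' @rdname volume-accessors
#' @export
setMethod("nVoxels", "RegionMask", function(x) sum(x@values))
#' @rdname volume-accessors
#' @export
setMethod("voxelVolumeMl", "SUVolume", function(x) prod(x@spacing) / 1000)
#' @rdname volume-accessors
#' @export
setMethod("voxelVolumeMl", "RegionMask", function(x) prod(x@spacing) / 1000)

setGeneric("featureValues", function(x) standardGeneric("featureValues"))
setGeneric("isLiverNormalized", function(x) standardGeneric("isLiverNormalized"))
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' Accessors for feature vectors and cohort tables
#'
#' @param x A [FeatureVector-class] or [CohortTable-class].
#' @name table-accessors
#' @aliases featureValues isLiverNormalized cohortData
NULL

#' @rdname table-accessors
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)
#' @rdname table-accessors
#' @export
setMethod("isLiverNormalized", "FeatureVector", function(x) x@liverNormalized)
#' @rdname table-accessors
#' @export
setMethod("cohortData", "CohortTable", function(x) x@data)

setMethod("show", "SUVolume", function(object) {
  d <- dim(object@values)
  cat("SUVolume:", paste(d, collapse = " x "), "voxels, spacing",
      paste(format(object@spacing, digits = 4), collapse = " x "), "mm\n")
  cat("  SUV range [", format(min(object@values), digits = 4), ", ",
      format(max(object@values), digits = 4), "]\n", sep = "")
})

setMethod("show", "RegionMask", function(object) {
  cat("RegionMask (", object@label, "): ", sum(object@values), " of ",
      length(object@values), " voxels set, ",
      format(sum(object@values) * prod(object@spacing) / 1000, digits = 4),
      " ml\n", sep = "")
})

setMethod("show", "FeatureVector", function(object) {
  cat("FeatureVector [", if (object@liverNormalized) "liver-normalized"
      else "raw", "]",
      if (!is.na(object@subjectId)) paste0(" subject ", object@subjectId),
      if (!is.na(object@timepoint)) paste0(" @", object@timepoint), "\n",
      sep = "")
  print(round(object@values, 4))
})

setMethod("show", "CohortTable", function(object) {
  d <- object@data
  nDelta <- if (any(grepl("^delta_", names(d))))
    sum(stats::complete.cases(d[grep("^delta_", names(d))])) else 0L
  cat("CohortTable:", nrow(d), "subjects,", sum(d$event), "DFS events,",
      nDelta, "with post-treatment change features\n")
})
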