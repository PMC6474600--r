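# Liver-uptake normalization and pre/post-treatment change features.
# Normalization runs as a separate pass after raw extraction so both raw
# and normalized tables can be produced (the un-normalized ranking is a
# useful sensitivity analysis).

#' Mean liver uptake from a reference region
#'
#' Arithmetic mean SUV over the liver measurement region. The region is a
#' user-supplied mask (automatic liver detection is out of scope); a scalar
#' reference can be built directly with [liverReference()].
#'
#' @param volume An [SUVolume-class].
#' @param liver A non-empty liver [RegionMask-class] on the same grid.
#' @return A [LiverReference-class].
#' @export
liverMean <- function(volume, liver) {
  .checkGrid(volume, liver)
  inside <- suvValues(liver)
  if (!any(inside)) stop("empty liver mask")
  new("LiverReference", meanSUV = mean(suvValues(volume)[inside]),
      source = "mask", nVoxels = sum(inside))
}

#' Build a liver reference from a known mean SUV
#'
#' @param meanSUV Positive mean liver SUV.
#' @return A [LiverReference-class] with source "scalar".
#' @export
liverReference <- function(meanSUV) {
  new("LiverReference", meanSUV = as.double(meanSUV), source = "scalar",
      nVoxels = NA_integer_)
}

#' Normalize a feature vector by mean liver uptake
#'
#' Divides every SUV-carrying feature (see [liverNormalizedFlags()]) by the
#' mean liver SUV, to account for inter-scan differences in metabolic
#' baseline activity. MTV and the grayscale-quarter percentages are left
#' unchanged. Normalizing twice is an error.
#'
#' @param features A raw [FeatureVector-class].
#' @param liver A [LiverReference-class] or a positive scalar mean SUV.
#' @return The normalized [FeatureVector-class].
#' @export
normalizeFeatures <- function(features, liver) {
  if (isLiverNormalized(features))
    stop("feature vector is already liver-normalized")
  lm <- if (is(liver, "LiverReference")) liver@meanSUV else as.double(liver)
  if (!is.finite(lm) || lm <= 0) stop("liver mean SUV must be > 0")
  flags <- liverNormalizedFlags()
  vals <- features@values
  vals[flags] <- vals[flags] / lm
  new("FeatureVector", values = vals, liverNormalized = TRUE,
      liverMeanSUV = lm, subjectId = features@subjectId,
      timepoint = features@timepoint)
}

#' Post-treatment change of features (t0 minus t1)
#'
#' Elementwise difference baseline minus post-treatment. Both inputs must
#' share the same normalization state; change is normally computed on
#' liver-normalized features (set `allowRaw = TRUE` to difference raw
#' vectors). Subjects with a complete response have no post-treatment
#' lesion and therefore no change vector.
#'
#' @param t0 Baseline [FeatureVector-class].
#' @param t1 Post-treatment [FeatureVector-class].
#' @param allowRaw Permit differencing un-normalized vectors.
#' @return Named numeric vector of per-feature changes.
#' @export
deltaFeatures <- function(t0, t1, allowRaw = FALSE) {
  if (isLiverNormalized(t0) != isLiverNormalized(t1))
    stop("t0 and t1 have different normalization states")
  if (!isLiverNormalized(t0) && !allowRaw)
    stop("change features are computed on liver-normalized vectors; ",
         "set allowRaw = TRUE to difference raw features")
  if (!is.na(t0@subjectId) && !is.na(t1@subjectId) &&
      t0@subjectId != t1@subjectId)
    stop("t0 and t1 belong to different subjects")
  t0@values - t1@values
}
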