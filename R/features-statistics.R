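# Intensity statistics over the lesion sample: the distributional part of
# the 22-feature panel. Conventions fixed here (and relied on by tests):
#   - quartiles by linear interpolation between order statistics
#     (stats::quantile type 7)
#   - Std is the population (divide-by-n) standard deviation, so
#     RMS^2 = Mean^2 + Std^2 holds exactly
#   - upper adjacent value = largest observation <= Q3 + 1.5 * IQR
#   - grayscale quarters are [Min + k*R/4, Min + (k+1)*R/4) with the last
#     bin closed, R = Max - Min; a degenerate range (R = 0) puts every
#     voxel in Q1

#' LesionSample: the multiset of SUV values inside a region
#'
#' @slot suv Numeric vector of SUV values at the region's voxels.
#' @slot voxelVolumeMl Volume of one voxel in ml.
#'
#' @export
setClass("LesionSample",
  representation(suv = "numeric", voxelVolumeMl = "numeric"))

setValidity("LesionSample", function(object) {
  if (length(object@suv) < 1L) return("sample must contain at least 1 voxel")
  if (anyNA(object@suv) || any(!is.finite(object@suv)))
    return("SUV values must be finite")
  if (object@voxelVolumeMl <= 0) return("voxel volume must be > 0 ml")
  TRUE
})

.checkGrid <- function(volume, mask) {
  if (!identical(dim(suvValues(volume)), dim(suvValues(mask))))
    stop("mask grid shape ", paste(dim(suvValues(mask)), collapse = "x"),
         " does not match volume ",
         paste(dim(suvValues(volume)), collapse = "x"))
  if (any(abs(spacing(volume) - spacing(mask)) > 1e-6))
    stop("mask voxel spacing does not match volume spacing")
  invisible(TRUE)
}

#' Extract the SUV sample inside a region
#'
#' @param volume An [SUVolume-class].
#' @param mask A [RegionMask-class] on the same grid (checked).
#' @return A [LesionSample-class].
#' @export
lesionSample <- function(volume, mask) {
  .checkGrid(volume, mask)
  inside <- suvValues(mask)
  if (!any(inside)) stop("empty region mask (label '", maskLabel(mask), "')")
  new("LesionSample", suv = suvValues(volume)[inside],
      voxelVolumeMl = voxelVolumeMl(volume))
}

.asSample <- function(x, voxelVolumeMl = 1) {
  if (is(x, "LesionSample")) x
  else new("LesionSample", suv = as.numeric(x),
           voxelVolumeMl = voxelVolumeMl)
}

#' Descriptive statistics of the lesion uptake distribution
#'
#' Max, Mean, Min, population standard deviation, root-mean-square,
#' quartiles (linear interpolation) and the boxplot upper adjacent value
#' (largest observation not exceeding Q3 + 1.5 x IQR).
#'
#' @param x A [LesionSample-class] or numeric vector of SUV values.
#' @return Named numeric vector with elements Max, Mean, Min, Std, RMS,
#'   FirstQuartile, Median, ThirdQuartile, UpperAdjacent.
#' @examples
#' basicStatistics(c(1, 2, 3, 4, 100))  # UpperAdjacent 4: fence is 7
#' @export
basicStatistics <- function(x) {
  s <- .asSample(x)@suv
  n <- length(s)
  m <- mean(s)
  q <- unname(quantile(s, c(0.25, 0.5, 0.75), type = 7))
  fence <- q[3] + 1.5 * (q[3] - q[1])
  c(Max = max(s), Mean = m, Min = min(s),
    Std = sqrt(sum((s - m)^2) / n),
    RMS = sqrt(mean(s^2)),
    FirstQuartile = q[1], Median = q[2], ThirdQuartile = q[3],
    UpperAdjacent = max(s[s <= fence]))
}

#' Metabolic tumor volume (ml)
#'
#' Number of lesion voxels times the single-voxel volume.
#'
#' @param sample A [LesionSample-class].
#' @return MTV in ml.
#' @export
mtv <- function(sample) length(sample@suv) * sample@voxelVolumeMl

#' Total lesion glycolysis (ml)
#'
#' Mean lesion SUV times MTV (equivalently the sum of value x voxel volume
#' over lesion voxels).
#'
#' @param sample A [LesionSample-class].
#' @return TLG in ml.
#' @export
tlg <- function(sample) mean(sample@suv) * mtv(sample)

.quarterBins <- function(s) {
  r <- max(s) - min(s)
  if (r == 0) return(rep(1L, length(s)))
  b <- as.integer(floor((s - min(s)) / r * 4)) + 1L
  pmin(b, 4L)  # the maximum falls in the closed fourth bin
}

#' Grayscale-quarter occupancy of the lesion (percent)
#'
#' The intensity range [Min, Max] is split into four equal bins (half-open
#' except the last); the percentage of lesion voxels in each bin is
#' returned. Percentages sum to 100. A constant lesion (zero range) is
#' assigned entirely to Q1.
#'
#' @param sample A [LesionSample-class] or numeric vector.
#' @return Named numeric: Q1Distribution .. Q4Distribution, in percent.
#' @export
quarterDistribution <- function(sample) {
  s <- .asSample(sample)@suv
  bins <- .quarterBins(s)
  counts <- tabulate(bins, nbins = 4L)
  setNames(100 * counts / length(s), paste0("Q", 1:4, "Distribution"))
}

#' Glycolysis contributed by each grayscale quarter (ml)
#'
#' Sum of value x voxel volume over the lesion voxels falling in each of
#' the four intensity bins of [quarterDistribution()]. The four parts sum
#' to TLG.
#'
#' @param sample A [LesionSample-class].
#' @return Named numeric: GlycolysisQ1 .. GlycolysisQ4, in ml.
#' @export
quarterGlycolysis <- function(sample) {
  s <- sample@suv
  bins <- .quarterBins(s)
  g <- vapply(1:4, function(k) sum(s[bins == k]) * sample@voxelVolumeMl, 0)
  setNames(g, paste0("GlycolysisQ", 1:4))
}
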