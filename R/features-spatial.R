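# Spatially-aware features: SUVpeak (1 cm^3 sphere), the 2-voxel rim,
# rim average (RA) and standardized added metabolic activity (SAM).

.shiftLogical <- function(m, o) {
  # translate a logical array by integer offset o, filling with FALSE
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    if (abs(o[a]) >= d[a]) return(out)
    if (o[a] >= 0) {
      dst[[a]] <- (1L + o[a]):d[a]; src[[a]] <- 1L:(d[a] - o[a])
    } else {
      dst[[a]] <- 1L:(d[a] + o[a]); src[[a]] <- (1L - o[a]):d[a]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

.neighborOffsets <- function(connectivity) {
  if (connectivity == 6L) {
    list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
         c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    g <- expand.grid(-1:1, -1:1, -1:1)
    g <- g[rowSums(abs(g)) > 0, ]
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  } else stop("connectivity must be 6 or 26")
}

.dilate <- function(m, iterations, connectivity = 6L) {
  offs <- .neighborOffsets(connectivity)
  for (i in seq_len(iterations)) {
    out <- m
    for (o in offs) out <- out | .shiftLogical(m, o)
    m <- out
  }
  m
}

#' Build the rim region surrounding a lesion
#'
#' The rim is the lesion mask dilated `widthVoxels` times with a
#' face-adjacent (6-connected) structuring element, minus the lesion
#' itself: a shell of the given voxel width hugging the lesion boundary,
#' clipped at the image edge. Width is counted in voxels, not mm, so the
#' physical rim thickness follows the (anisotropic) voxel spacing.
#'
#' @param lesion A non-empty [RegionMask-class].
#' @param widthVoxels Rim width in dilation steps (default 2).
#' @param connectivity Structuring element: 6 (faces, default) or 26
#'   (faces + edges + corners).
#' @return A [RegionMask-class] labelled "rim", disjoint from the lesion.
#' @export
buildRim <- function(lesion, widthVoxels = 2L, connectivity = 6L) {
  m <- suvValues(lesion)
  if (!any(m)) stop("empty lesion mask")
  if (widthVoxels < 1L) stop("rim width must be >= 1 voxel")
  rim <- .dilate(m, as.integer(widthVoxels), as.integer(connectivity)) & !m
  RegionMask(rim, spacing = spacing(lesion), origin = origin(lesion),
             label = "rim")
}

#' Mean uptake in the rim region (RA)
#'
#' The rim average: arithmetic mean SUV over the rim voxels. RA
#' characterizes metabolic activity in the lesion's immediate periphery
#' rather than its core.
#'
#' @param volume An [SUVolume-class].
#' @param rim A non-empty rim [RegionMask-class] on the same grid.
#' @return Mean SUV in the rim.
#' @export
rimAverage <- function(volume, rim) {
  .checkGrid(volume, rim)
  inside <- suvValues(rim)
  if (!any(inside)) stop("empty rim mask")
  mean(suvValues(volume)[inside])
}

#' Peak uptake: best 1 cm^3 sphere average (SUVpeak)
#'
#' The maximum, over spheres of volume 1 cm^3 centered on lesion voxel
#' centers, of the mean SUV of the voxels whose centers fall inside the
#' sphere. Membership is evaluated in physical mm coordinates (radius
#' (3000/(4*pi))^(1/3) ~ 6.2035 mm), so anisotropic spacing is respected.
#' Spheres may extend beyond the lesion; sphere voxels outside the image
#' grid are excluded from the average.
#'
#' @param volume An [SUVolume-class].
#' @param lesion A non-empty lesion [RegionMask-class] on the same grid.
#' @return Peak SUV.
#' @export
suvPeak <- function(volume, lesion) {
  .checkGrid(volume, lesion)
  m <- suvValues(lesion)
  if (!any(m)) stop("empty lesion mask")
  vol <- suvValues(volume)
  d <- dim(vol)
  sp <- spacing(volume)
  r <- (3000 / (4 * pi))^(1 / 3)  # 1 cm^3 = 1000 mm^3
  span <- ceiling(r / sp)
  offs <- expand.grid(i = -span[1]:span[1], j = -span[2]:span[2],
                      k = -span[3]:span[3])
  keep <- (offs$i * sp[1])^2 + (offs$j * sp[2])^2 + (offs$k * sp[3])^2 <= r^2
  offs <- offs[keep, ]
  cand <- which(m, arr.ind = TRUE)
  sums <- numeric(nrow(cand))
  cnts <- integer(nrow(cand))
  for (t in seq_len(nrow(offs))) {
    ii <- cand[, 1] + offs$i[t]
    jj <- cand[, 2] + offs$j[t]
    kk <- cand[, 3] + offs$k[t]
    ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2] & kk >= 1L & kk <= d[3]
    idx <- ii[ok] + (jj[ok] - 1L) * d[1] + (kk[ok] - 1L) * d[1] * d[2]
    sums[ok] <- sums[ok] + vol[idx]
    cnts[ok] <- cnts[ok] + 1L
  }
  max(sums / cnts)
}

#' Standardized added metabolic activity (SAM, ml)
#'
#' Total activity of the lesion-plus-rim region minus the activity that a
#' uniform background at the rim's mean uptake would contribute over the
#' same region:
#' \deqn{SAM = \sum_{v \in L \cup R} SUV(v)\,V_{vox} - RA \cdot Vol(L \cup R)}
#' which algebraically reduces to TLG - RA x MTV. SAM is a
#' partial-volume-robust surrogate for total lesion glycolysis: the rim
#' mean estimates local background, and background contribution inside the
#' measurement region cancels out.
#'
#' @param volume An [SUVolume-class].
#' @param lesion A non-empty lesion [RegionMask-class].
#' @param rim A non-empty rim mask, disjoint from the lesion.
#' @return SAM in ml.
#' @export
sam <- function(volume, lesion, rim) {
  .checkGrid(volume, lesion); .checkGrid(volume, rim)
  mL <- suvValues(lesion); mR <- suvValues(rim)
  if (!any(mL)) stop("empty lesion mask")
  if (!any(mR)) stop("empty rim mask")
  if (any(mL & mR)) stop("lesion and rim masks overlap")
  vv <- voxelVolumeMl(volume)
  vals <- suvValues(volume)
  total <- sum(vals[mL | mR]) * vv
  ra <- mean(vals[mR])
  total - ra * (sum(mL) + sum(mR)) * vv
}

#' Compute the full 22-feature panel for one lesion
#'
#' Runs every feature on the raw (un-normalized) SUV volume: the five
#' standard measures (Max, Peak, Mean, MTV, TLG), the distributional
#' statistics, the grayscale-quarter features, and the rim features RA and
#' SAM. The rim is built internally from the lesion mask.
#'
#' @param volume An [SUVolume-class].
#' @param lesion A non-empty lesion [RegionMask-class] on the same grid.
#' @param rimWidth Rim width in voxels (default 2).
#' @param connectivity Rim structuring element, 6 or 26 (default 6).
#' @param subjectId,timepoint Optional provenance recorded on the result.
#' @return A raw [FeatureVector-class].
#' @export
extractFeatures <- function(volume, lesion, rimWidth = 2L, connectivity = 6L,
                            subjectId = NA_character_,
                            timepoint = NA_character_) {
  smp <- lesionSample(volume, lesion)
  rim <- buildRim(lesion, rimWidth, connectivity)
  stats <- basicStatistics(smp)
  vals <- setNames(numeric(22L), featureNames())
  vals[names(stats)] <- stats
  vals["Peak"] <- suvPeak(volume, lesion)
  vals["MTV"] <- mtv(smp)
  vals["TLG"] <- tlg(smp)
  qd <- quarterDistribution(smp)
  vals[names(qd)] <- qd
  qg <- quarterGlycolysis(smp)
  vals[names(qg)] <- qg
  vals["RA"] <- rimAverage(volume, rim)
  vals["SAM"] <- sam(volume, lesion, rim)
  new("FeatureVector", values = vals, liverNormalized = FALSE,
      liverMeanSUV = NA_real_, subjectId = as.character(subjectId),
      timepoint = as.character(timepoint))
}
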