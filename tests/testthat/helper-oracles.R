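# Independent brute-force oracles: plain loops and sorting, no reuse of
# package internals. These define the expected behaviour that the
# vectorized implementations must match.

# descriptive statistics from the sorted list, computed longhand
oracleStats <- function(x) {
  n <- length(x)
  s <- sort(x)
  m <- 0
  for (v in s) m <- m + v
  m <- m / n
  ss <- 0
  for (v in s) ss <- ss + (v - m)^2
  sq <- 0
  for (v in s) sq <- sq + v^2
  # linear interpolation between order statistics at h = (n-1)p + 1
  qlin <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  q1 <- qlin(0.25); q3 <- qlin(0.75)
  fence <- q3 + 1.5 * (q3 - q1)
  ua <- -Inf
  for (v in s) if (v <= fence && v > ua) ua <- v
  c(Max = s[n], Mean = m, Min = s[1], Std = sqrt(ss / n),
    RMS = sqrt(sq / n), FirstQuartile = q1, Median = qlin(0.5),
    ThirdQuartile = q3, UpperAdjacent = ua)
}

# grayscale-quarter bin of each value by explicit interval comparison
oracleQuarterBins <- function(x) {
  mn <- min(x); r <- max(x) - mn
  if (r == 0) return(rep(1L, length(x)))
  bins <- integer(length(x))
  for (i in seq_along(x)) {
    b <- 4L
    for (k in 1:3) {
      lo <- mn + (k - 1) * r / 4
      hi <- mn + k * r / 4
      if (x[i] >= lo && x[i] < hi) { b <- k; break }
    }
    bins[i] <- b
  }
  bins
}

# Harrell's c by exhaustive enumeration of ordered pairs
oracleCIndex <- function(risk, time, event) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    usable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!usable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  num / den
}

# voxels within city-block distance `width` of the lesion, by exhaustive
# pairwise scan (use only on small grids)
oracleRim <- function(lesion, width) {
  d <- dim(lesion)
  rim <- array(FALSE, d)
  idx <- which(lesion, arr.ind = TRUE)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (lesion[i, j, k]) next
    best <- Inf
    for (r in seq_len(nrow(idx))) {
      dist <- abs(i - idx[r, 1]) + abs(j - idx[r, 2]) + abs(k - idx[r, 3])
      if (dist < best) best <- dist
    }
    if (best <= width) rim[i, j, k] <- TRUE
  }
  rim
}

# mean SUV over voxel centers within a 1 cm^3 sphere around each lesion
# voxel center, by explicit triple loop; returns the best sphere average
oraclePeak <- function(vol, lesion, spacing) {
  d <- dim(vol)
  r <- (3000 / (4 * pi))^(1 / 3)
  centers <- which(lesion, arr.ind = TRUE)
  best <- -Inf
  for (c in seq_len(nrow(centers))) {
    tot <- 0; cnt <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      dd <- ((i - centers[c, 1]) * spacing[1])^2 +
        ((j - centers[c, 2]) * spacing[2])^2 +
        ((k - centers[c, 3]) * spacing[3])^2
      if (dd <= r^2) { tot <- tot + vol[i, j, k]; cnt <- cnt + 1 }
    }
    if (tot / cnt > best) best <- tot / cnt
  }
  best
}

# --- fixture builders -----------------------------------------------------

randomLesionSample <- function(n = NULL, voxelVolumeMl = NULL) {
  if (is.null(n)) n <- sample(1:60, 1)
  if (is.null(voxelVolumeMl)) voxelVolumeMl <- runif(1, 0.02, 0.1)
  new("LesionSample", suv = round(runif(n, 0, 12), 3),
      voxelVolumeMl = voxelVolumeMl)
}

# random connected-ish blob mask grown from a seed voxel
randomBlobMask <- function(shape = c(9, 9, 9), nGrow = 10, spacing = c(1, 1, 1)) {
  m <- array(FALSE, shape)
  pos <- ceiling(shape / 2)
  m[pos[1], pos[2], pos[3]] <- TRUE
  for (i in seq_len(nGrow)) {
    idx <- which(m, arr.ind = TRUE)
    v <- idx[sample(nrow(idx), 1), ]
    step <- sample(1:3, 1)
    v[step] <- min(max(v[step] + sample(c(-1, 1), 1), 1), shape[step])
    m[v[1], v[2], v[3]] <- TRUE
  }
  RegionMask(m, spacing = spacing, label = "lesion")
}

# small random censored cohort for concordance checks
randomCohort <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:20, 1)
  list(risk = sample(seq(-2, 2, 0.5), n, replace = TRUE),
       time = sample(1:12, n, replace = TRUE),
       event = sample(0:1, n, replace = TRUE))
}

# path where a per-subject feature/outcome table (S1-style CSV) would be
# installed for the real-data reproduction tests
s1FilePath <- function() {
  system.file("extdata", "s1_subject_table.csv", package = "petrim")
}
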