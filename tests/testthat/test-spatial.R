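test_that("a single-voxel lesion grows a 24-voxel rim at width 2", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  lesion <- RegionMask(m, label = "lesion")
  rim <- suvValues(buildRim(lesion, widthVoxels = 2))
  expect_equal(sum(rim), 24L)  # 6 voxels at city-block distance 1, 18 at 2
  expect_identical(rim, oracleRim(m, 2))
  expect_equal(sum(suvValues(buildRim(lesion, widthVoxels = 1))), 6L)
})

test_that("rim construction matches exhaustive city-block enumeration", {
  set.seed(21)
  for (i in 1:25) {
    lesion <- randomBlobMask(nGrow = sample(3:15, 1))
    w <- sample(1:3, 1)
    rim <- buildRim(lesion, widthVoxels = w)
    expect_identical(suvValues(rim), oracleRim(suvValues(lesion), w))
    expect_false(any(suvValues(rim) & suvValues(lesion)))
    expect_identical(maskLabel(rim), "rim")
  }
})

test_that("rims are clipped at the image boundary", {
  m <- array(FALSE, c(5, 5, 5)); m[1, 1, 1] <- TRUE
  rim <- buildRim(RegionMask(m), widthVoxels = 2)
  expect_identical(suvValues(rim), oracleRim(m, 2))
  expect_equal(sum(suvValues(rim)), sum(oracleRim(m, 2)))
  expect_error(buildRim(RegionMask(array(FALSE, c(3, 3, 3)))), "empty")
})

test_that("rim average is the mean background uptake around a hard sphere", {
  ph <- makePhantom(phantomSpec(backgroundSUV = 1, lesionSUV = 8))
  rim <- buildRim(ph$lesion, 2)
  expect_equal(rimAverage(ph$volume, rim), 1.0)

  blurred <- makePhantom(phantomSpec(backgroundSUV = 1, lesionSUV = 8,
                                     profile = "gaussian"))
  rimB <- buildRim(blurred$lesion, 2)
  ra <- rimAverage(blurred$volume, rimB)
  expect_gt(ra, 1.0); expect_lt(ra, 8.0)

  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  r <- buildRim(RegionMask(m), 2)
  vol <- SUVolume(array(2, c(9, 9, 9)))
  expect_equal(rimAverage(vol, r), 2.0)
})

test_that("peak is the best 1 cc sphere average in physical coordinates", {
  sp <- c(3.5, 3.5, 3.4)
  # uniform lesion much larger than 1 cm^3: interior spheres see only c
  ph <- makePhantom(phantomSpec(spacing = sp, backgroundSUV = 0,
                                lesionSUV = 5, lesionRadius = 18))
  expect_equal(suvPeak(ph$volume, ph$lesion), 5)

  # single hot voxel in a uniform SUV-1 field: peak is the sphere average
  vol <- array(1, c(11, 11, 11)); vol[6, 6, 6] <- 10
  lesion <- array(FALSE, c(11, 11, 11)); lesion[6, 6, 6] <- TRUE
  v <- SUVolume(vol, spacing = sp)
  got <- suvPeak(v, RegionMask(lesion, spacing = sp))
  expect_lt(got, 10)
  expect_equal(got, oraclePeak(vol, lesion, sp))

  # peak never exceeds max, on random phantoms
  set.seed(31)
  for (i in 1:30) {
    shape <- c(8, 8, 8)
    rvol <- SUVolume(array(runif(prod(shape), 0, 10), shape), spacing = sp)
    rmask <- randomBlobMask(shape, nGrow = 8, spacing = sp)
    expect_lte(suvPeak(rvol, rmask), max(suvValues(rvol)))
  }
})

test_that("peak matches the exhaustive sphere oracle on random fields", {
  set.seed(57)
  for (sp in list(c(3.5, 3.5, 3.4), c(4.3, 4.3, 5.0), c(3.4, 3.4, 2.0))) {
    vol <- array(runif(7^3, 0, 8), c(7, 7, 7))
    mask <- array(FALSE, c(7, 7, 7)); mask[3:5, 3:5, 4] <- TRUE
    expect_equal(suvPeak(SUVolume(vol, spacing = sp),
                         RegionMask(mask, spacing = sp)),
                 oraclePeak(vol, mask, sp))
  }
})

test_that("SAM subtracts rim background over the lesion-plus-rim region", {
  sp <- c(3.5, 3.5, 3.4)
  # flat field: lesion indistinguishable from background, SAM = 0
  flat <- SUVolume(array(2.4, c(12, 12, 12)), spacing = sp)
  m <- array(FALSE, c(12, 12, 12)); m[5:8, 5:8, 5:8] <- TRUE
  lesion <- RegionMask(m, spacing = sp)
  rim <- buildRim(lesion, 2)
  expect_equal(sam(flat, lesion, rim), 0, tolerance = 1e-12)

  # uniform lesion L over background B: SAM = (L - B) * lesion volume,
  # cross-checked against direct voxel-wise summation
  L <- 7; B <- 1.2
  vol <- array(B, c(12, 12, 12)); vol[m] <- L
  v <- SUVolume(vol, spacing = sp)
  vv <- prod(sp) / 1000
  expected <- (L - B) * sum(m) * vv
  direct <- sum(vol[m | suvValues(rim)]) * vv -
    mean(vol[suvValues(rim)]) * (sum(m) + sum(suvValues(rim))) * vv
  expect_equal(sam(v, lesion, rim), expected, tolerance = 1e-9)
  expect_equal(sam(v, lesion, rim), direct, tolerance = 1e-12)

  # multiplicative scaling of the volume scales SAM linearly
  v3 <- SUVolume(vol * 3, spacing = sp)
  expect_equal(sam(v3, lesion, rim), 3 * sam(v, lesion, rim),
               tolerance = 1e-9)
  expect_error(sam(v, lesion, lesion), "overlap")
})

test_that("the full panel satisfies its invariants on random phantoms", {
  set.seed(77)
  for (i in 1:15) {
    spec <- phantomSpec(shape = c(24, 24, 24),
                        profile = sample(c("uniform", "gaussian",
                                           "gradient"), 1),
                        lesionRadius = runif(1, 8, 14),
                        noiseSigma = runif(1, 0, 0.3), seed = i)
    ph <- makePhantom(spec)
    fv <- featureValues(extractFeatures(ph$volume, ph$lesion))
    expect_lte(fv["Min"], fv["FirstQuartile"])
    expect_lte(fv["FirstQuartile"], fv["Median"])
    expect_lte(fv["Median"], fv["ThirdQuartile"])
    expect_lte(fv["ThirdQuartile"], fv["Max"])
    expect_lte(fv["Peak"], fv["Max"] + 1e-12)
    expect_lte(fv["Min"], fv["Mean"]); expect_lte(fv["Mean"], fv["Max"])
    expect_equal(sum(fv[paste0("Q", 1:4, "Distribution")]), 100,
                 tolerance = 1e-9)
    expect_equal(sum(fv[paste0("GlycolysisQ", 1:4)]), unname(fv["TLG"]),
                 tolerance = 1e-9)
    expect_equal(unname(fv["RMS"]^2), unname(fv["Mean"]^2 + fv["Std"]^2),
                 tolerance = 1e-9)
  }
})

test_that("uniform-sphere phantom features match their closed forms", {
  ph <- makePhantom(phantomSpec(backgroundSUV = 1, lesionSUV = 8,
                                liverSUV = 2))
  fv <- featureValues(extractFeatures(ph$volume, ph$lesion))
  tr <- ph$analyticTruth
  expect_equal(unname(fv["Mean"]), 8)
  expect_equal(unname(fv["Max"]), 8); expect_equal(unname(fv["Min"]), 8)
  expect_equal(unname(fv["Peak"]), 8)
  expect_equal(unname(fv["MTV"]), tr$MTV)
  expect_equal(unname(fv["TLG"]), tr$TLG)
  expect_equal(unname(fv["RA"]), 1)
  expect_equal(unname(fv["SAM"]), tr$SAM, tolerance = 1e-9)
  expect_equal(unname(fv["Std"]), 0)
  expect_equal(unname(fv["Q1Distribution"]), 100)
})

test_that("intensity statistics are spacing-invariant, MTV discretization-bounded", {
  for (spc in list(c(2, 2, 2), c(1.6, 1.6, 1.6))) {
    shape <- round(c(80, 80, 80) / spc[1])
    spec <- phantomSpec(shape = shape, spacing = spc, backgroundSUV = 1,
                        lesionSUV = 6, lesionRadius = 10,
                        lesionCenter = c(24, 24, 40),
                        liverCenter = c(58, 58, 40), liverRadius = 9)
    ph <- makePhantom(spec)
    fv <- featureValues(extractFeatures(ph$volume, ph$lesion))
    expect_equal(unname(fv["Mean"]), 6); expect_equal(unname(fv["Max"]), 6)
    expect_equal(unname(fv["Min"]), 6)
    analytic <- 4 / 3 * pi * 10^3 / 1000
    expect_lt(abs(fv["MTV"] - analytic) / analytic,
              if (spc[1] < 2) 0.08 else 0.12)
  }
})
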