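test_that("phantom generation is deterministic and obeys its closed forms", {
  spec <- phantomSpec(backgroundSUV = 1, lesionSUV = 8, liverSUV = 2,
                      noiseSigma = 0.15, seed = 4)
  a <- makePhantom(spec); b <- makePhantom(spec)
  expect_identical(suvValues(a$volume), suvValues(b$volume))

  clean <- makePhantom(phantomSpec(backgroundSUV = 1, lesionSUV = 8,
                                   liverSUV = 2))
  nv <- normalizeFeatures(extractFeatures(clean$volume, clean$lesion),
                          liverMean(clean$volume, clean$liver))
  expect_equal(unname(featureValues(nv)["Mean"]), 4.0)  # 8 / 2
  expect_equal(unname(featureValues(nv)["RA"]), 0.5)    # 1 / 2
  expect_error(phantomSpec(lesionCenter = c(10, 10, 10),
                           liverCenter = c(12, 12, 12)), "disjoint")
})

test_that("voxelized sphere volume converges to the analytic volume", {
  analytic <- 4 / 3 * pi * 10^3 / 1000  # 4.19 ml for r = 10 mm
  err <- sapply(c(2, 1), function(s) {
    spec <- phantomSpec(shape = round(c(60, 60, 60) / s),
                        spacing = rep(s, 3), lesionRadius = 10,
                        lesionCenter = c(18, 18, 30),
                        liverCenter = c(45, 45, 30), liverRadius = 7)
    ph <- makePhantom(spec)
    abs(ph$analyticTruth$MTV - analytic) / analytic
  })
  expect_lt(err[1], 0.12)
  expect_lt(err[2], err[1])  # finer grid, smaller discretization error
})

test_that("cohort features and outcomes follow the generating model", {
  spec <- cohortSpec(n = 500, seed = 17)
  d <- cohortData(makeCohort(spec))
  sds <- apply(d[paste0("t0_", featureNames())], 2, sd)
  expect_true(all(abs(sds - spec$sds) / spec$sds < 0.10))
  # under beta = 0 the observed time is the minimum of two exponentials
  ks <- stats::ks.test(d$time, "pexp",
                       rate = spec$baselineRate + spec$censRate)
  expect_gt(ks$p.value, 0.01)
  # censored fraction matches censRate / (baselineRate + censRate)
  expect_lt(abs(mean(d$event == 0) - spec$censRate /
                  (spec$baselineRate + spec$censRate)), 0.10)
})

test_that("the stated censoring rate yields ~57% censoring at n = 58", {
  set.seed(23)
  fracs <- sapply(1:40, function(r)
    mean(cohortData(makeCohort(cohortSpec(n = 58, seed = 900 + r)))$event == 0))
  expect_lt(abs(mean(fracs) - 0.57), 0.10)
})

test_that("a true change-in-RA effect is recovered as the top-ranked feature", {
  set.seed(19)
  wins <- 0L
  for (r in 1:30) {
    spec <- cohortSpec(n = 500, prefix = "delta_",
                       beta = c(RA = log(2)), seed = 5000 + r)
    res <- screenFeatures(makeCohort(spec), "delta")
    wins <- wins + (res$feature[1] == "RA")
  }
  expect_gte(wins, 28L)
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohortSpec(n = 1), "n >= 2")
  expect_error(cohortSpec(rho = 1.2), "positive definite")
  expect_error(cohortSpec(beta = c(XYZ = 1)), "among the generated")
  expect_error(cohortSpec(baselineRate = 0), "rates")
  expect_error(cohortSpec(residualFraction = 1.5), "residualFraction")
})

test_that("the study-shaped cohort has the right structure", {
  ct <- makePaperLikeCohort(seed = 7)
  d <- cohortData(ct)
  expect_equal(nrow(d), 58L)
  deltaCols <- grep("^delta_", names(d))
  expect_equal(sum(complete.cases(d[deltaCols])), 25L)
  # delta block is exactly t0 - t1 where present (validity also checks)
  expect_equal(d$delta_RA, d$t0_RA - d$t1_RA)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeCohortCSV(makePaperLikeCohort(seed = 7), f1)
  writeCohortCSV(makePaperLikeCohort(seed = 7), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_equal(nrow(screenFeatures(ct, "baseline")), 22L)
  expect_equal(nrow(screenFeatures(ct, "delta")), 22L)
})

test_that("event counts sit near the study's 25-of-58 and 13-of-25", {
  set.seed(29)
  tot <- resid <- numeric(30)
  for (r in 1:30) {
    d <- cohortData(makePaperLikeCohort(seed = 1000 + r))
    tot[r] <- sum(d$event)
    resid[r] <- sum(d$event[!is.na(d$delta_RA)])
  }
  expect_lt(abs(mean(tot) - 25), 5)
  expect_lt(abs(mean(resid) - 13), 4)
})
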