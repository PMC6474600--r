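test_that("per-SD Cox regression recovers a known hazard ratio", {
  set.seed(61)
  hrs <- covered <- numeric(5)
  for (r in 1:5) {
    n <- 500
    x <- rnorm(n)
    eventTime <- rexp(n, rate = 0.1 * exp(log(2) * x))
    censTime <- rexp(n, rate = 0.045)  # ~30% censoring
    res <- coxUnivariate(x, pmin(eventTime, censTime),
                         as.numeric(eventTime <= censTime), "x")
    hrs[r] <- res$hr
    covered[r] <- res$ciLow <= 2 && 2 <= res$ciHigh
  }
  expect_true(all(hrs > 1.55 & hrs < 2.55))
  expect_gt(mean(hrs), 1.7); expect_lt(mean(hrs), 2.35)
  expect_gte(sum(covered), 4)
})

test_that("degenerate Cox inputs are rejected with clear errors", {
  expect_error(coxUnivariate(rep(2, 10), 1:10, rep(1, 10)), "zero variance")
  expect_error(coxUnivariate(rnorm(10), 1:10, rep(0, 10)), "2 events")
})

test_that("monotone-likelihood non-convergence is reported, not clipped", {
  # risk perfectly separates event order: partial likelihood is monotone
  n <- 12
  expect_warning(
    res <- coxUnivariate(n:1, 1:n, rep(1, n), "sep"),
    "converge")
  expect_false(res$converged)
})

test_that("the c index behaves at its extremes", {
  # higher risk always fails first: perfect concordance
  expect_equal(cIndex(10:1, 1:10, rep(1, 10)), 1.0)
  expect_equal(cIndex(1:10, 1:10, rep(1, 10)), 0.0)
  set.seed(71)
  n <- 1000
  c0 <- cIndex(rnorm(n), rexp(n), sample(0:1, n, replace = TRUE))
  expect_lt(abs(c0 - 0.5), 0.05)
  expect_error(cIndex(c(1, 2), c(5, 5), c(0, 0)), "comparable")
})

test_that("the c index equals exhaustive pair enumeration under censoring", {
  set.seed(81)
  tested <- 0L
  for (i in 1:200) {
    co <- randomCohort()
    oracle <- if (sum(co$event) > 0)
      oracleCIndex(co$risk, co$time, co$event) else NaN
    if (!is.finite(oracle)) next  # no comparable pairs in this draw
    tested <- tested + 1L
    expect_equal(cIndex(co$risk, co$time, co$event), oracle)
  }
  expect_gt(tested, 150L)
})

test_that("the c index agrees with the survival package on tie-free data", {
  set.seed(91)
  for (i in 1:20) {
    n <- 30
    risk <- rnorm(n); time <- rexp(n) + seq_len(n) * 1e-6
    event <- sample(0:1, n, replace = TRUE, prob = c(0.3, 0.7))
    ours <- cIndex(risk, time, event)
    ref <- survival::concordance(survival::Surv(time, event) ~ risk,
                                 reverse = TRUE)$concordance
    expect_equal(ours, unname(ref), tolerance = 1e-12)
  }
})

test_that("BH adjustment has its step-up closed form and properties", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(0.3), 0.3)
  set.seed(5)
  p <- runif(22)
  q <- bhFDR(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_equal(order(q[order(p)]), seq_along(p))  # order preserved
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("tertile grouping sends cut-point ties to the lower group", {
  g <- tertileGroups(1:9)
  expect_equal(as.vector(table(g)), c(3, 3, 3))
  # value exactly at the lower cut point joins the low group
  x <- c(1, 2, 3, 3, 5, 6, 7, 8, 9)
  q <- unname(quantile(x, 1 / 3, type = 7))
  g2 <- tertileGroups(x)
  expect_true(all(g2[x == q] == "low"))
})

test_that("Kaplan-Meier tertile curves match the product-limit computation", {
  # 15 subjects, tertiles of 5; the low group has the hand-worked history
  # times {1,2,3,4,5}, events {1,0,1,1,0}: S(3) = (4/5) * (2/3)
  x <- 1:15
  time <- c(1, 2, 3, 4, 5, 10, 11, 12, 13, 14, 2, 4, 6, 8, 10)
  event <- c(1, 0, 1, 1, 0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0)
  f <- tempfile(fileext = ".png")
  km <- kmTertileCurves(x, time, event, file = f, featureName = "RA")
  expect_true(file.exists(f))
  expect_equal(as.vector(table(km$groups)), c(5, 5, 5))
  fit <- km$fit
  stratum <- rep(names(fit$strata), fit$strata)
  survAt <- function(name, t) {
    tt <- fit$time[stratum == name]; ss <- fit$surv[stratum == name]
    if (!any(tt <= t)) 1.0 else ss[max(which(tt <= t))]
  }
  expect_equal(survAt("groups=low", 3), (4 / 5) * (2 / 3),
               tolerance = 1e-12)
  # the intermediate group has no events: its curve stays at 1
  expect_true(all(fit$surv[stratum == "groups=intermediate"] == 1))
  expect_error(kmTertileCurves(c(1, 2), c(1, 2), c(1, 1)), "3 subjects")
})

test_that("feature screening adjusts, sorts and flags across the panel", {
  ct <- makePaperLikeCohort(seed = 42)
  res <- screenFeatures(ct, "delta")
  expect_equal(nrow(res), 22L)
  expect_true(all(diff(res$p) >= 0))
  expect_true(all(res$fdr >= res$p))
  expect_identical(res$significant, res$fdr < 0.10)
  expect_equal(sort(res$feature), sort(featureNames()))
  expect_error(screenFeatures(CohortTable(data.frame(
    id = "a", time = 1, event = 1)), "baseline"), "t0_Max")
})

test_that("screening a null cohort yields roughly uniform p-values", {
  set.seed(303)
  counts <- numeric(20)
  for (r in 1:20) {
    spec <- cohortSpec(n = 58, seed = 3000 + r)
    res <- screenFeatures(makeCohort(spec), "baseline")
    counts[r] <- sum(res$p < 0.05)
  }
  expect_lte(mean(counts), 2.2)
})
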