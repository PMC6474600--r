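# Univariate survival screening of imaging features: per-SD Cox hazard
# ratios, Harrell's c index, Benjamini-Hochberg FDR across the feature
# panel, and Kaplan-Meier tertile curves. Model fitting is delegated to
# the survival package (Efron ties, Wald intervals).

#' @importFrom survival coxph Surv survfit
NULL

#' Univariate Cox regression for one feature, per standard deviation
#'
#' The feature is standardized by the sample standard deviation (n - 1
#' denominator, complete cases) so the hazard ratio corresponds to a
#' one-SD increase. The proportional-hazards fit uses the Efron
#' approximation for ties; the confidence interval and p-value are Wald on
#' the log-hazard scale. Non-convergence (e.g. monotone likelihood) is
#' reported via a warning and a flag, never silently clipped.
#'
#' @param x Per-subject feature values (NAs dropped pairwise with the
#'   outcome).
#' @param time DFS time in months (> 0).
#' @param event Event indicator, 1 = recurrence or death, 0 = censored.
#' @param featureName Label carried into the result.
#' @return One-row data.frame: feature, n, nEvents, hr, ciLow, ciHigh, p,
#'   cIndex, converged.
#' @export
coxUnivariate <- function(x, time, event, featureName = "feature") {
  keep <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (sum(event) < 2) stop("need at least 2 events")
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero variance: feature '", featureName,
         "' is constant in the cohort")
  z <- x / s
  converged <- TRUE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ z, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!converged)
    warning("Cox fit for '", featureName,
            "' did not converge (possible monotone likelihood); ",
            "estimates are unreliable")
  zcrit <- qnorm(0.975)
  data.frame(
    feature = featureName,
    n = length(x), nEvents = sum(event),
    hr = exp(beta),
    ciLow = exp(beta - zcrit * se), ciHigh = exp(beta + zcrit * se),
    p = 2 * pnorm(-abs(beta / se)),
    cIndex = cIndex(beta * z, time, event),
    converged = converged,
    stringsAsFactors = FALSE)
}

#' Harrell's concordance index for censored survival data
#'
#' The probability that, of two randomly selected comparable subjects, the
#' one with the higher risk score experiences the event first. A pair is
#' comparable when the ordering of the survival times is known despite
#' censoring: the earlier time ended in an event, or the times are tied
#' with exactly one event (the censored subject is known to have survived
#' longer). Pairs tied on risk score count 1/2. Scores for which higher
#' values mean higher hazard give c > 0.5 when prognostic.
#'
#' @param risk Per-subject risk scores (higher = higher hazard).
#' @param time Survival time.
#' @param event Event indicator (1 observed, 0 censored).
#' @return Concordance probability in [0, 1].
#' @export
cIndex <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  keep <- !is.na(risk) & !is.na(time) & !is.na(event)
  risk <- risk[keep]; time <- time[keep]; event <- event[keep]
  n <- length(risk)
  # ordered pairs (i, j) in which subject i is known to fail before j
  # outlives them: t_i < t_j with an event for i, or t_i == t_j with an
  # event for i only
  ti <- matrix(time, n, n); tj <- t(ti)
  ei <- matrix(event == 1, n, n); ej <- t(ei)
  usable <- (ti < tj & ei) | (ti == tj & ei & !ej)
  diag(usable) <- FALSE
  if (!any(usable)) stop("no comparable pairs under censoring")
  ri <- matrix(risk, n, n); rj <- t(ri)
  conc <- sum(usable & ri > rj)
  ties <- sum(usable & ri == rj)
  (conc + 0.5 * ties) / sum(usable)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), computed with
#' `stats::p.adjust(method = "BH")` after validating the input range.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted values, same length and order as `p`.
#' @export
bhFDR <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Split subjects into low / intermediate / high tertile groups
#'
#' Cut points are the 33.3 and 66.7 percentiles (linear interpolation);
#' subjects exactly at a cut point fall in the lower group.
#'
#' @param x Feature values.
#' @return Factor with levels "low", "intermediate", "high".
#' @export
tertileGroups <- function(x) {
  q <- unname(quantile(x, c(1, 2) / 3, type = 7, na.rm = TRUE))
  cut(x, breaks = c(-Inf, q, Inf),
      labels = c("low", "intermediate", "high"), right = TRUE)
}

#' Kaplan-Meier survival curves by feature tertile
#'
#' Estimates product-limit disease-free survival curves for subjects
#' grouped into high / intermediate / low feature categories, and
#' optionally writes a plot with censoring marks.
#'
#' @param x Feature values (n >= 3).
#' @param time DFS time in months.
#' @param event Event indicator.
#' @param file Optional path for a PNG plot.
#' @param featureName Label used in the plot.
#' @return List with `fit` (a [survival::survfit] object), `groups`, and
#'   `cutpoints`.
#' @export
kmTertileCurves <- function(x, time, event, file = NULL,
                            featureName = "feature") {
  keep <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (length(x) < 3) stop("need at least 3 subjects for tertile groups")
  groups <- tertileGroups(x)
  fit <- survfit(Surv(time, event) ~ groups)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700, res = 120)
    on.exit(grDevices::dev.off())
    graphics::plot(fit, col = c("#1b9e77", "#d95f02", "#7570b3"),
                   lwd = 2, mark.time = TRUE, xlab = "Months",
                   ylab = "Disease-free survival",
                   main = paste("DFS by tertile of", featureName))
    graphics::legend("bottomleft", legend = levels(groups),
                     col = c("#1b9e77", "#d95f02", "#7570b3"), lwd = 2,
                     bty = "n")
  }
  list(fit = fit, groups = groups,
       cutpoints = unname(quantile(x, c(1, 2) / 3, type = 7)))
}

#' Univariate screening of a feature panel against DFS
#'
#' Fits one per-SD Cox model per feature, adjusts the p-values with
#' Benjamini-Hochberg across exactly the screened panel, computes
#' Harrell's c from each model's prognostic score, sorts by ascending
#' p-value, and flags features below the FDR threshold.
#'
#' @param cohort A [CohortTable-class].
#' @param timepoint Which feature block to screen: "baseline" (t0_
#'   columns), "post" (t1_), or "delta" (delta_).
#' @param features Feature names to screen (default the full 22-panel).
#' @param fdrThreshold Significance threshold on the adjusted values
#'   (default 0.10).
#' @return data.frame with one row per feature: feature, n, nEvents, hr,
#'   ciLow, ciHigh, p, fdr, cIndex, significant — sorted by p.
#' @export
screenFeatures <- function(cohort, timepoint = c("baseline", "post", "delta"),
                           features = featureNames(), fdrThreshold = 0.10) {
  timepoint <- match.arg(timepoint)
  prefix <- c(baseline = "t0_", post = "t1_", delta = "delta_")[[timepoint]]
  d <- cohortData(cohort)
  rows <- lapply(features, function(f) {
    col <- paste0(prefix, f)
    if (!col %in% names(d))
      stop("cohort has no column '", col, "' for feature '", f, "'")
    coxUnivariate(d[[col]], d$time, d$event, featureName = f)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bhFDR(res$p)
  res <- res[order(res$p), ]
  res$significant <- res$fdr < fdrThreshold
  rownames(res) <- NULL
  res[, c("feature", "n", "nEvents", "hr", "ciLow", "ciHigh", "p", "fdr",
          "cIndex", "significant", "converged")]
}

#' Format a screening table for reporting
#'
#' Renders "HR (95% CI)" with two decimals and p / FDR / c index with
#' three, matching the conventional presentation of univariate survival
#' tables so results can be compared against published tables by eye.
#'
#' @param results Output of [screenFeatures()].
#' @return data.frame with columns Feature, `HR (95% CI)`, `p-value`,
#'   FDR, `c Index`.
#' @export
formatResultsTable <- function(results) {
  out <- data.frame(
    Feature = results$feature,
    `HR (95% CI)` = sprintf("%.2f (%.2f, %.2f)", results$hr, results$ciLow,
                            results$ciHigh),
    `p-value` = sprintf("%.3f", results$p),
    FDR = sprintf("%.3f", results$fdr),
    `c Index` = sprintf("%.3f", results$cIndex),
    check.names = FALSE, stringsAsFactors = FALSE)
  out
}
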