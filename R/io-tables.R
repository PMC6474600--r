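# CSV I/O for feature tables and per-subject cohort tables.
# Dialect: comma-separated, UTF-8, header row, "." decimal point.

#' Default column map for cohort CSV files
#'
#' Maps the package's canonical column roles onto CSV column names. The
#' per-subject layout of external feature/outcome files varies, so the map
#' is configuration: edit the returned list (or supply your own) to match
#' the file at hand. `baseline`, `post` and `delta` are named character
#' vectors from [featureNames()] to CSV columns; missing entries are simply
#' not imported.
#'
#' @return List with elements `id`, `time`, `event`, `baseline`, `post`,
#'   `delta`.
#' @export
defaultColumnMap <- function() {
  fn <- featureNames()
  list(id = "id", time = "time", event = "event",
       baseline = setNames(paste0("t0_", fn), fn),
       post = setNames(paste0("t1_", fn), fn),
       delta = setNames(paste0("delta_", fn), fn))
}

#' Read a per-subject cohort table from CSV
#'
#' Reads subject outcomes (DFS time in months, event indicator) and any
#' mapped baseline / post-treatment / change feature columns into a
#' [CohortTable-class]. Rows with missing time or event are dropped with a
#' message giving the count.
#'
#' @param path CSV file path.
#' @param columnMap Column map as from [defaultColumnMap()]; `time` and
#'   `event` are required.
#' @return A [CohortTable-class].
#' @export
readCohortCSV <- function(path, columnMap = defaultColumnMap()) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  raw <- read.csv(path, check.names = FALSE)
  for (role in c("time", "event")) {
    col <- columnMap[[role]]
    if (is.null(col) || !col %in% names(raw))
      stop("required column '", role, "' (mapped to '",
           col %||% "<unmapped>", "') not found in '", path, "'")
  }
  keep <- !(is.na(raw[[columnMap$time]]) | is.na(raw[[columnMap$event]]))
  if (any(!keep))
    message("dropped ", sum(!keep), " row(s) with missing DFS time or event")
  raw <- raw[keep, , drop = FALSE]
  idCol <- columnMap$id
  out <- data.frame(
    id = if (!is.null(idCol) && idCol %in% names(raw))
      as.character(raw[[idCol]]) else as.character(seq_len(nrow(raw))),
    time = as.numeric(raw[[columnMap$time]]),
    event = as.numeric(raw[[columnMap$event]]),
    stringsAsFactors = FALSE)
  for (block in c("baseline", "post", "delta")) {
    prefix <- c(baseline = "t0_", post = "t1_", delta = "delta_")[[block]]
    m <- columnMap[[block]]
    for (f in names(m)) {
      if (m[[f]] %in% names(raw))
        out[[paste0(prefix, f)]] <- as.numeric(raw[[m[[f]]]])
    }
  }
  CohortTable(out)
}

#' Write a cohort table to CSV
#'
#' @param cohort A [CohortTable-class].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeCohortCSV <- function(cohort, path) {
  write.csv(cohortData(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Write feature vectors to a CSV table
#'
#' One row per lesion-timepoint, with `id`, `timepoint`,
#' `liver_normalized`, `liver_mean_suv`, then the 22 features in the fixed
#' order of [featureNames()].
#'
#' @param features A [FeatureVector-class] or list of them (non-empty).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  if (is(features, "FeatureVector")) features <- list(features)
  if (length(features) == 0L) stop("empty feature list")
  stopifnot(all(vapply(features, is, TRUE, class2 = "FeatureVector")))
  rows <- lapply(features, function(fv) {
    cbind(data.frame(id = fv@subjectId, timepoint = fv@timepoint,
                     liver_normalized = fv@liverNormalized,
                     liver_mean_suv = fv@liverMeanSUV),
          as.data.frame(as.list(fv@values), check.names = FALSE))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read feature vectors back from a CSV table
#'
#' Inverse of [writeFeatureTable()].
#'
#' @param path CSV path written by [writeFeatureTable()].
#' @return List of [FeatureVector-class] objects.
#' @export
readFeatureTable <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  missing <- setdiff(featureNames(), names(d))
  if (length(missing))
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  lapply(seq_len(nrow(d)), function(i) {
    new("FeatureVector",
        values = setNames(as.numeric(d[i, featureNames()]), featureNames()),
        liverNormalized = isTRUE(as.logical(d$liver_normalized[i])),
        liverMeanSUV = as.numeric(d$liver_mean_suv[i] %||% NA_real_),
        subjectId = as.character(d$id[i]),
        timepoint = as.character(d$timepoint[i]))
  })
}
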