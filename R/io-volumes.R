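# Volume and mask I/O: NRRD (attached raw/gzip encodings) and NIfTI-1.
# Masks must share the exact grid of their companion SUV volume; no
# resampling is performed anywhere in the package.

.nrrdTypes <- list(
  "uchar"  = list(what = "integer", size = 1L, signed = FALSE),
  "char"   = list(what = "integer", size = 1L, signed = TRUE),
  "short"  = list(what = "integer", size = 2L, signed = TRUE),
  "ushort" = list(what = "integer", size = 2L, signed = FALSE),
  "int"    = list(what = "integer", size = 4L, signed = TRUE),
  "uint"   = list(what = "integer", size = 4L, signed = TRUE),
  "float"  = list(what = "double",  size = 4L, signed = TRUE),
  "double" = list(what = "double",  size = 8L, signed = TRUE))

.normalizeNrrdType <- function(type) {
  aliases <- c("unsigned char" = "uchar", "uint8" = "uchar", "uint8_t" = "uchar",
               "int8" = "char", "signed char" = "char",
               "short int" = "short", "int16" = "short",
               "unsigned short" = "ushort", "uint16" = "ushort",
               "int32" = "int", "signed int" = "int", "uint32" = "uint")
  if (type %in% names(aliases)) unname(aliases[type]) else type
}

.parseNrrdVectorList <- function(x) {
  # "(3.5,0,0) (0,3.5,0) (0,0,3.4)" -> list of numeric vectors
  parts <- regmatches(x, gregexpr("\\(([^)]*)\\)", x))[[1]]
  lapply(parts, function(p)
    as.numeric(strsplit(gsub("[()]", "", p), ",")[[1]]))
}

.readNrrd <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  nl <- which(raw == as.raw(10L))
  # header ends at the first blank line
  hdrEnd <- NA_integer_
  prev <- 0L
  for (i in nl) {
    if (i == prev + 1L || (i == prev + 2L && raw[i - 1L] == as.raw(13L))) {
      hdrEnd <- i; break
    }
    prev <- i
  }
  if (is.na(hdrEnd)) stop("malformed NRRD: no end-of-header blank line in '",
                          path, "'")
  hdr <- strsplit(rawToChar(raw[seq_len(hdrEnd)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop("'", path, "' is not an NRRD file")
  fields <- list()
  for (line in hdr[-1]) {
    if (grepl("^#", line) || !nzchar(line)) next
    kv <- regmatches(line, regexpr(":=?", line))
    pos <- regexpr(":=?", line)
    key <- tolower(trimws(substr(line, 1, pos - 1)))
    fields[[key]] <- trimws(substr(line, pos + attr(pos, "match.length"),
                                   nchar(line)))
  }
  dimension <- as.integer(fields[["dimension"]])
  if (!identical(dimension, 3L))
    stop("expected 3D volume, got dimension ", dimension, " in '", path, "'")
  sizes <- as.integer(strsplit(fields[["sizes"]], "[ \t]+")[[1]])
  type <- .normalizeNrrdType(tolower(fields[["type"]]))
  tinfo <- .nrrdTypes[[type]]
  if (is.null(tinfo))
    stop("unsupported (non-scalar?) NRRD voxel type '", fields[["type"]], "'")
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  payload <- raw[(hdrEnd + 1L):length(raw)]
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (encoding != "raw") {
    stop("unsupported NRRD encoding '", encoding, "'")
  }
  endian <- fields[["endian"]] %||% "little"
  n <- prod(sizes)
  vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = endian)
  if (length(vals) != n)
    stop("NRRD data truncated: expected ", n, " voxels, read ", length(vals))
  spc <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- .parseNrrdVectorList(fields[["space directions"]])
    spc <- vapply(dirs, function(d) sqrt(sum(d^2)), 0)
  } else if (!is.null(fields[["spacings"]])) {
    spc <- as.numeric(strsplit(fields[["spacings"]], "[ \t]+")[[1]])
  }
  org <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    org <- .parseNrrdVectorList(fields[["space origin"]])[[1]]
  list(values = array(as.double(vals), sizes), spacing = spc, origin = org)
}

.writeNrrd <- function(values, spacing, origin, path, type = "double",
                       encoding = "gzip") {
  tinfo <- .nrrdTypes[[type]]
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           "space: left-posterior-superior",
           paste0("sizes: ", paste(dim(values), collapse = " ")),
           paste0("space directions: ",
                  sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                          spacing[1], spacing[2], spacing[3])),
           "kinds: domain domain domain",
           "endian: little",
           paste0("encoding: ", encoding),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   origin[1], origin[2], origin[3]),
           "")
  payload <- if (tinfo$what == "double")
    writeBin(as.double(as.vector(values)), raw(), size = tinfo$size,
             endian = "little")
  else
    writeBin(as.integer(as.vector(values)), raw(), size = tinfo$size,
             endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(payload, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.isNifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

.readAnyVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (.isNifti(path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) {
      img2 <- array(as.double(img), d[1:3])
    } else if (length(d) == 3L) {
      img2 <- array(as.double(img), d)
    } else {
      stop("expected 3D volume, got ", length(d), "D image in '", path, "'")
    }
    hdr <- RNifti::niftiHeader(img)
    list(values = img2, spacing = abs(hdr$pixdim[2:4]),
         origin = c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
  } else {
    .readNrrd(path)
  }
}

#' Read a 3D SUV volume from NRRD or NIfTI-1
#'
#' Voxel spacing (mm) is taken from the image header (NRRD `space
#' directions`/`spacings`, NIfTI `pixdim`); values are cast to double.
#' Only 3D scalar images are supported.
#'
#' @param path Path to a `.nrrd`/`.nhdr` or `.nii`/`.nii.gz` file.
#' @return An [SUVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nrrd")
#' writeVolume(SUVolume(array(2, c(5, 5, 5)), spacing = c(3.5, 3.5, 3.4)), f)
#' readVolume(f)
#' @export
readVolume <- function(path) {
  x <- .readAnyVolume(path)
  SUVolume(x$values, spacing = x$spacing, origin = x$origin)
}

#' Read a binary region mask from NRRD or NIfTI-1
#'
#' Non-zero voxels are inside the region. The mask must live on the same
#' grid as its companion SUV volume; this is checked at feature-extraction
#' time, not here.
#'
#' @param path Path to the mask image.
#' @param label Region label: "lesion", "rim" or "liver".
#' @return A [RegionMask-class].
#' @export
readMask <- function(path, label = "lesion") {
  x <- .readAnyVolume(path)
  RegionMask(x$values != 0, spacing = x$spacing, origin = x$origin,
             label = label)
}

#' Write a volume or mask to NRRD or NIfTI-1
#'
#' Format is chosen from the file extension. NRRD output uses gzip encoding;
#' masks are stored as unsigned bytes, SUV volumes as doubles.
#'
#' @param x An [SUVolume-class] or [RegionMask-class].
#' @param path Output path (`.nrrd`, `.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
writeVolume <- function(x, path) {
  isMask <- is(x, "RegionMask")
  if (.isNifti(path)) {
    vals <- if (isMask) array(as.integer(x@values), dim(x@values)) else x@values
    img <- RNifti::asNifti(vals)
    RNifti::pixdim(img) <- x@spacing
    RNifti::writeNifti(img, path)
  } else {
    .writeNrrd(if (isMask) x@values * 1L else x@values, x@spacing, x@origin,
               path, type = if (isMask) "uchar" else "double")
  }
  invisible(path)
}

#' Convert an activity-concentration grid to SUV (body-weight normalization)
#'
#' SUV = concentration (Bq/ml) x body weight (g) / injected dose (Bq).
#' This is a convenience for raw arrays; decay correction and DICOM-series
#' handling are out of scope.
#'
#' @param activity 3D array of activity concentration in Bq/ml.
#' @param injectedDoseBq Injected dose in Bq (> 0).
#' @param bodyWeightKg Body weight in kg (> 0).
#' @param spacing Voxel spacing in mm.
#' @param origin Physical origin in mm.
#' @return An [SUVolume-class] of unitless SUV values.
#' @examples
#' a <- array(10000, c(2, 2, 2))
#' suvValues(suvFromActivity(a, 3.7e8, 74))[1]  # SUV 2.0
#' @export
suvFromActivity <- function(activity, injectedDoseBq, bodyWeightKg,
                            spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.finite(injectedDoseBq) || injectedDoseBq <= 0)
    stop("injected dose must be > 0 Bq")
  if (!is.finite(bodyWeightKg) || bodyWeightKg <= 0)
    stop("body weight must be > 0 kg")
  SUVolume(activity * (bodyWeightKg * 1000) / injectedDoseBq,
           spacing = spacing, origin = origin)
}
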