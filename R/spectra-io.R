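# Centroided MS/MS spectra with SPE-fraction metadata: the MsSpectrum
# container, MGF (Mascot generic format) read/write, a TSV peak-list
# fallback, and tolerance-based peak matching.

#' Tolerance: a peak-matching window
#'
#' @slot mode `"da"` (absolute Da) or `"ppm"`.
#' @slot value Positive window half-width in the mode's units.
#' @export
setClass("Tolerance",
  representation(mode = "character", value = "numeric"),
  prototype(mode = "da", value = 0.5))

setValidity("Tolerance", function(object) {
  msg <- character()
  if (!object@mode %in% c("da", "ppm"))
    msg <- c(msg, "mode must be 'da' or 'ppm'")
  if (length(object@value) != 1L || !is.finite(object@value) ||
      object@value <= 0)
    msg <- c(msg, "value must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Absolute (Da) matching tolerance
#'
#' The default screening tolerance is 0.5 Da, matching the integer-level
#' reporting precision of the fraction tables.
#'
#' @param value Window half-width in Da.
#' @return A [Tolerance-class].
#' @export
toleranceDa <- function(value = 0.5) new("Tolerance", mode = "da",
                                         value = value)

#' Relative (ppm) matching tolerance
#'
#' @param value Window half-width in ppm.
#' @return A [Tolerance-class].
#' @export
tolerancePpm <- function(value) new("Tolerance", mode = "ppm", value = value)

# window half-width in Da at a given m/z
.tolWindow <- function(tol, at) {
  if (tol@mode == "da") tol@value else at * tol@value * 1e-6
}

#' MsSpectrum: a centroided MS/MS spectrum
#'
#' @slot id Spectrum identifier.
#' @slot precursorMz Precursor m/z (`[M + H]+`; positive).
#' @slot charge Precursor charge (default 1; all screened species are
#'   singly protonated).
#' @slot peaks Two-column numeric matrix (`mz`, `intensity`), rows sorted
#'   by ascending m/z, intensities non-negative.
#' @slot fraction SPE fraction label (e.g. `"40% MeOH"`), or `NA`.
#' @export
setClass("MsSpectrum",
  representation(id = "character", precursorMz = "numeric",
                 charge = "integer", peaks = "matrix",
                 fraction = "character"),
  prototype(charge = 1L, fraction = NA_character_))

setValidity("MsSpectrum", function(object) {
  msg <- character()
  if (length(object@precursorMz) != 1L || !is.finite(object@precursorMz) ||
      object@precursorMz <= 0)
    msg <- c(msg, "precursorMz must be a single positive number")
  p <- object@peaks
  if (ncol(p) != 2L)
    msg <- c(msg, "peaks must have two columns (mz, intensity)")
  else {
    if (nrow(p) && is.unsorted(p[, 1L]))
      msg <- c(msg, "peaks must be sorted by ascending m/z")
    if (nrow(p) && any(p[, 2L] < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (nrow(p) && any(p[, 1L] <= 0))
      msg <- c(msg, "peak m/z must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an MsSpectrum
#'
#' Peaks are sorted by m/z on construction.
#'
#' @param id Spectrum identifier.
#' @param precursorMz Precursor m/z.
#' @param peaks Two-column matrix or data.frame (`mz`, `intensity`).
#' @param charge Precursor charge (default 1).
#' @param fraction SPE fraction label, or `NA`.
#' @return An [MsSpectrum-class].
#' @export
msSpectrum <- function(id, precursorMz, peaks, charge = 1L,
                       fraction = NA_character_) {
  peaks <- as.matrix(peaks)
  if (length(peaks) == 0L) peaks <- matrix(numeric(), ncol = 2L)
  colnames(peaks) <- c("mz", "intensity")
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  new("MsSpectrum", id = as.character(id), precursorMz = precursorMz,
      charge = as.integer(charge), peaks = peaks,
      fraction = as.character(fraction))
}

setMethod("show", "MsSpectrum", function(object) {
  cat(sprintf("MsSpectrum '%s': precursor m/z %.4f (%d+), %d peaks",
              object@id, object@precursorMz, object@charge,
              nrow(object@peaks)))
  if (!is.na(object@fraction))
    cat(sprintf(", fraction %s", object@fraction))
  cat("\n")
})

#' @describeIn MsSpectrum accessor for the peak matrix
#' @param object An `MsSpectrum`.
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname MsSpectrum
#' @export
setMethod("peaks", "MsSpectrum", function(object) object@peaks)

#' @describeIn MsSpectrum accessor for the precursor m/z
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))

#' @rdname MsSpectrum
#' @export
setMethod("precursorMz", "MsSpectrum", function(object) object@precursorMz)

#' @describeIn MsSpectrum accessor for the SPE fraction label
#' @export
setGeneric("fractionLabel", function(object) standardGeneric("fractionLabel"))

#' @rdname MsSpectrum
#' @export
setMethod("fractionLabel", "MsSpectrum", function(object) object@fraction)

#' @describeIn MsSpectrum accessor for the spectrum id
#' @export
setGeneric("spectrumId", function(object) standardGeneric("spectrumId"))

#' @rdname MsSpectrum
#' @export
setMethod("spectrumId", "MsSpectrum", function(object) object@id)

#' Match a target m/z in a spectrum
#'
#' Returns the most intense peak within the tolerance window of `target`,
#' or `NULL` when no peak falls inside the window.  Ties in intensity are
#' broken by proximity to the target.
#'
#' @param spectrum An [MsSpectrum-class].
#' @param target Target m/z.
#' @param tol A [Tolerance-class] (default 0.5 Da).
#' @return Named numeric vector `c(mz=, intensity=)`, or `NULL`.
#' @export
matchPeak <- function(spectrum, target, tol = toleranceDa(0.5)) {
  stopifnot(is(spectrum, "MsSpectrum"), is(tol, "Tolerance"))
  p <- spectrum@peaks
  if (!nrow(p)) return(NULL)
  win <- .tolWindow(tol, target)
  dist <- abs(p[, 1L] - target)
  hit <- which(dist <= win)
  if (!length(hit)) return(NULL)
  best <- hit[order(-p[hit, 2L], dist[hit])][1L]
  c(mz = unname(p[best, 1L]), intensity = unname(p[best, 2L]))
}

#' Write spectra to an MGF file
#'
#' One `BEGIN IONS`/`END IONS` block per spectrum; the fraction label is
#' carried in the TITLE line as `FRACTION=<label>`.
#'
#' @param spectra An [MsSpectrum-class] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  if (is(spectra, "MsSpectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(is(s, "MsSpectrum"))
    title <- s@id
    if (!is.na(s@fraction))
      title <- sprintf("%s FRACTION=%s", title, s@fraction)
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=%s", title),
                 sprintf("PEPMASS=%.6f", s@precursorMz),
                 sprintf("CHARGE=%d+", s@charge),
                 sprintf("%.6f %.6f", s@peaks[, 1L], s@peaks[, 2L]),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' Parses the MGF dialect with `BEGIN IONS`/`END IONS` blocks, a required
#' `PEPMASS` header, optional `CHARGE`, and a `TITLE` whose
#' `FRACTION=<label>` suffix (if present) becomes the fraction label.
#' Unknown headers are ignored; malformed blocks raise a parse error
#' naming the offending line.
#'
#' @param path Path to an MGF file.
#' @return List of [MsSpectrum-class] objects (empty for an empty file).
#' @export
readMgf <- function(path) {
  if (!file.exists(path))
    .apStop(sprintf("file not found: %s", path), "mgfParseError")
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  inBlock <- FALSE
  blockStart <- 0L
  title <- pepmass <- charge <- NULL
  mzs <- ints <- numeric()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (inBlock)
        .apStop(sprintf("line %d: nested BEGIN IONS", i), "mgfParseError")
      inBlock <- TRUE; blockStart <- i
      title <- NULL; pepmass <- NULL; charge <- 1L
      mzs <- numeric(); ints <- numeric()
    } else if (line == "END IONS") {
      if (!inBlock)
        .apStop(sprintf("line %d: END IONS without BEGIN IONS", i),
                "mgfParseError")
      if (is.null(pepmass))
        .apStop(sprintf(
          "line %d: block starting at line %d has no PEPMASS",
          i, blockStart), "mgfParseError")
      id <- if (is.null(title)) sprintf("spectrum%d", length(spectra) + 1L)
            else title
      fraction <- NA_character_
      fr <- regmatches(id, regexec("\\bFRACTION=(.+)$", id))[[1]]
      if (length(fr) == 2L) {
        fraction <- fr[2L]
        id <- trimws(sub("\\bFRACTION=.+$", "", id))
      }
      spectra[[length(spectra) + 1L]] <-
        msSpectrum(id, pepmass, cbind(mzs, ints), charge, fraction)
      inBlock <- FALSE
    } else if (inBlock) {
      if (grepl("=", line, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", line))
        val <- sub("^[^=]*=", "", line)
        if (key == "TITLE") title <- val
        else if (key == "PEPMASS") {
          pepmass <- suppressWarnings(
            as.numeric(strsplit(trimws(val), "[ \t]+")[[1]][1]))
          if (is.na(pepmass))
            .apStop(sprintf("line %d: unparseable PEPMASS '%s'", i, val),
                    "mgfParseError")
        } else if (key == "CHARGE") {
          charge <- suppressWarnings(as.integer(gsub("[^0-9]", "", val)))
          if (is.na(charge)) charge <- 1L
        }
        # other headers ignored
      } else {
        fields <- strsplit(line, "[ \t]+")[[1]]
        vals <- suppressWarnings(as.numeric(fields))
        if (length(vals) < 2L || anyNA(vals[1:2]))
          .apStop(sprintf("line %d: unparseable peak line '%s'", i, line),
                  "mgfParseError")
        mzs <- c(mzs, vals[1L]); ints <- c(ints, vals[2L])
      }
    }
    # content outside blocks is ignored
  }
  if (inBlock)
    .apStop(sprintf("block starting at line %d not closed by END IONS",
                    blockStart), "mgfParseError")
  spectra
}

#' Read a bare TSV peak list as a spectrum
#'
#' Fallback for instruments exporting plain peak tables.  Columns `mz`
#' and `intensity` are required; precursor and metadata are supplied by
#' the caller.
#'
#' @param path Path to the tab-separated peak list.
#' @inheritParams msSpectrum
#' @return An [MsSpectrum-class].
#' @export
readPeakTable <- function(path, id, precursorMz, charge = 1L,
                          fraction = NA_character_) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(tab)))
    .apStop("peak table must have columns 'mz' and 'intensity'",
            "peakTableError")
  msSpectrum(id, precursorMz, tab[, c("mz", "intensity")], charge, fraction)
}
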