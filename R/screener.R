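# The screening procedure: gate on the Lys marker ion, collect diagnostic
# evidence, infer the exocyclic residue from its neutral loss, match
# against the compound library, name novel analogs, flag CYP-like spectra,
# and build a fraction report.

#' @include spectra-io.R scaffold-library.R
NULL

#' ScreenConfig: screener configuration
#'
#' @slot tolerance Peak-matching [Tolerance-class] (default 0.5 Da,
#'   matching the integer-level reporting of the fraction tables).
#' @slot matchThreshold Minimal fraction of predicted library fragments
#'   that must be matched for a named identification (default 0.6).
#' @slot cypDiagnostics m/z values flagged as Ahp-related cyanopeptolin
#'   diagnostics; editable, since no CYP diagnostic masses are fixed by
#'   the screening rules.
#' @slot novelRule Whether gated spectra with a recognized exocyclic loss
#'   but no library match are reported as novel analogs (default TRUE).
#' @export
setClass("ScreenConfig",
  representation(tolerance = "Tolerance", matchThreshold = "numeric",
                 cypDiagnostics = "numeric", novelRule = "logical"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (length(object@matchThreshold) != 1L ||
      object@matchThreshold <= 0 || object@matchThreshold > 1)
    msg <- c(msg, "matchThreshold must be in (0, 1]")
  if (any(object@cypDiagnostics <= 0))
    msg <- c(msg, "cypDiagnostics must be positive m/z values")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenConfig
#'
#' @param tolerance A [Tolerance-class] (default 0.5 Da absolute).
#' @param matchThreshold Library-match score threshold in (0, 1].
#' @param cypDiagnostics Numeric vector of Ahp-related diagnostic m/z
#'   values for cyanopeptolin-like flagging (empty vector disables it).
#' @param novelRule Enable the novel-analog rule.
#' @return A [ScreenConfig-class].
#' @export
screenConfig <- function(tolerance = toleranceDa(0.5),
                         matchThreshold = 0.6,
                         cypDiagnostics = c(215.14, 243.13),
                         novelRule = TRUE) {
  new("ScreenConfig", tolerance = tolerance,
      matchThreshold = matchThreshold,
      cypDiagnostics = as.numeric(cypDiagnostics), novelRule = novelRule)
}

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf(
    "ScreenConfig: tol %.3g %s, threshold %.2f, %d CYP diagnostics, novel rule %s\n",
    object@tolerance@value, object@tolerance@mode, object@matchThreshold,
    length(object@cypDiagnostics), if (object@novelRule) "on" else "off"))
})

#' Assignment: the screener's verdict for one spectrum
#'
#' @slot id Spectrum id.
#' @slot fraction SPE fraction label.
#' @slot precursorMz Precursor m/z.
#' @slot verdict One of `named_ap`, `novel_ap`, `ap_fragment`, `cyp_like`,
#'   `none`.
#' @slot proposedName Proposed compound name for AP verdicts (or
#'   `"AP fragment"` / `NA`).
#' @slot exocyclic Exocyclic-residue call: `"Arg"`, `"Tyr"` or
#'   `"undetermined"`.
#' @slot evidence Matched diagnostic labels.
#' @slot score Fraction of predicted library fragments matched, in [0, 1].
#' @export
setClass("Assignment",
  representation(id = "character", fraction = "character",
                 precursorMz = "numeric", verdict = "character",
                 proposedName = "character", exocyclic = "character",
                 evidence = "character", score = "numeric"))

setValidity("Assignment", function(object) {
  msg <- character()
  if (!object@verdict %in%
      c("named_ap", "novel_ap", "ap_fragment", "cyp_like", "none"))
    msg <- c(msg, "invalid verdict")
  if (object@verdict %in% c("named_ap", "novel_ap") &&
      !"lys_marker" %in% object@evidence)
    msg <- c(msg, "AP verdicts require the Lys marker in the evidence")
  if (object@score < 0 || object@score > 1)
    msg <- c(msg, "score must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Assignment", function(object) {
  cat(sprintf("Assignment '%s' (m/z %.1f, %s): %s",
              object@id, object@precursorMz,
              if (is.na(object@fraction)) "no fraction" else object@fraction,
              object@verdict))
  if (!is.na(object@proposedName))
    cat(sprintf(" -> %s", object@proposedName))
  cat(sprintf("\n  exocyclic: %s; score %.2f; evidence: %s\n",
              object@exocyclic, object@score,
              if (length(object@evidence))
                paste(object@evidence, collapse = ", ") else "none"))
})

#' @describeIn Assignment accessor for the verdict
#' @param object An `Assignment`.
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname Assignment
#' @export
setMethod("verdict", "Assignment", function(object) object@verdict)

#' @describeIn Assignment accessor for the proposed compound name
#' @export
setGeneric("proposedName", function(object) standardGeneric("proposedName"))

#' @rdname Assignment
#' @export
setMethod("proposedName", "Assignment", function(object) object@proposedName)

#' @describeIn Assignment accessor for the matched diagnostic labels
#' @export
setGeneric("evidenceLabels",
           function(object) standardGeneric("evidenceLabels"))

#' @rdname Assignment
#' @export
setMethod("evidenceLabels", "Assignment", function(object) object@evidence)

#' @describeIn Assignment accessor for the library-match score
#' @export
setGeneric("matchScore", function(object) standardGeneric("matchScore"))

#' @rdname Assignment
#' @export
setMethod("matchScore", "Assignment", function(object) object@score)

#' Gate on the conserved Lys marker ion
#'
#' Presence of the Lys marker ion at m/z 84.0808 is the precondition for
#' calling a spectrum a potential anabaenopeptin.
#'
#' @param spectrum An [MsSpectrum-class].
#' @param config A [ScreenConfig-class].
#' @return TRUE when a peak matches the marker within tolerance.
#' @export
gateLys <- function(spectrum, config = screenConfig()) {
  !is.null(matchPeak(spectrum, lysMarkerMz(), config@tolerance))
}

#' Collect low-mass diagnostic evidence
#'
#' Matches the Lys marker (84.0808), the Phe immonium ion (120.0808) and
#' the two Arg-related ions (175.119, 201.1) and returns the labels of
#' those found.
#'
#' @inheritParams gateLys
#' @return Character vector drawn from `lys_marker`, `phe_immonium`,
#'   `arg_175`, `arg_201`.
#' @export
collectEvidence <- function(spectrum, config = screenConfig()) {
  arg <- argDiagnosticMzs()
  targets <- c(lys_marker = lysMarkerMz(),
               phe_immonium = unname(immoniumMz("F")),
               arg_175 = unname(arg[["arg_175"]]),
               arg_201 = unname(arg[["arg_201"]]))
  found <- vapply(targets, function(t)
    !is.null(matchPeak(spectrum, t, config@tolerance)), logical(1))
  names(targets)[found]
}

#' Infer the exocyclic residue from its neutral loss
#'
#' Looks for a fragment at precursor − 200.091 (the `[Arg + CO]` loss) or
#' precursor − 181.074 (the `[Tyr + H2O]` loss).  When both losses match,
#' the more intense fragment wins (ties go to Arg, the more common loss).
#'
#' @inheritParams gateLys
#' @return `"Arg"`, `"Tyr"` or `"undetermined"`.
#' @export
inferExocyclic <- function(spectrum, config = screenConfig()) {
  k <- massConstants()
  argLoss <- unname(residueMass("R")) + k[["H2O"]] + k[["CO"]] - k[["H2"]]
  tyrLoss <- unname(residueMass("Y")) + k[["H2O"]]
  pArg <- matchPeak(spectrum, spectrum@precursorMz - argLoss,
                    config@tolerance)
  pTyr <- matchPeak(spectrum, spectrum@precursorMz - tyrLoss,
                    config@tolerance)
  if (is.null(pArg) && is.null(pTyr)) return("undetermined")
  if (is.null(pTyr)) return("Arg")
  if (is.null(pArg)) return("Tyr")
  if (pTyr[["intensity"]] > pArg[["intensity"]]) "Tyr" else "Arg"
}

#' Score a spectrum against a library compound
#'
#' The precursor must match the compound's `[M + H]+` within tolerance;
#' otherwise the score is 0 without evaluating fragments.  The score is
#' the fraction of predicted fragment entries (precursor excluded) found
#' in the spectrum.
#'
#' @inheritParams gateLys
#' @param compound An [APCompound-class].
#' @return Score in [0, 1].
#' @export
scoreLibraryMatch <- function(spectrum, compound, config = screenConfig()) {
  pm <- protonate(apNeutralMass(compound))
  if (abs(spectrum@precursorMz - pm) >
      .tolWindow(config@tolerance, pm)) return(0)
  entries <- fragmentEntries(predictFragments(compound))
  targets <- entries$mz[entries$label != "precursor"]
  hits <- vapply(targets, function(t)
    !is.null(matchPeak(spectrum, t, config@tolerance)), logical(1))
  mean(hits)
}

#' Screen one spectrum
#'
#' The decision procedure: (1) spectra passing the Lys gate are scored
#' against every library compound whose `[M + H]+` matches the precursor;
#' the best score at or above the threshold gives a `named_ap` verdict
#' (ties broken by precursor proximity, then name).  (2) Gated spectra
#' with a recognized exocyclic loss but no library match become
#' `novel_ap`, named after their nominal molecular mass.  (3) Spectra
#' whose precursor matches a library ring fragment are reported as
#' `ap_fragment`.  (4) Remaining spectra matching a configured
#' Ahp-related diagnostic are flagged `cyp_like`; all else is `none`.
#'
#' @inheritParams gateLys
#' @param library Named list of [APCompound-class] (default
#'   [apLibrary()]).
#' @return An [Assignment-class].
#' @export
screenSpectrum <- function(spectrum, library = apLibrary(),
                           config = screenConfig()) {
  stopifnot(is(spectrum, "MsSpectrum"))
  evidence <- collectEvidence(spectrum, config)
  gated <- "lys_marker" %in% evidence
  exo <- inferExocyclic(spectrum, config)
  verdict <- "none"
  proposed <- NA_character_
  score <- 0
  if (gated && length(library)) {
    scores <- vapply(library, scoreLibraryMatch, numeric(1),
                     spectrum = spectrum, config = config)
    pms <- vapply(library, function(c) protonate(apNeutralMass(c)),
                  numeric(1))
    deltas <- abs(spectrum@precursorMz - pms)
    names <- vapply(library, compoundName, character(1))
    ok <- scores >= config@matchThreshold
    if (any(ok)) {
      ord <- order(-scores, deltas, names)
      best <- ord[ok[ord]][1L]
      verdict <- "named_ap"
      proposed <- unname(names[best])
      score <- unname(scores[best])
    } else if (config@novelRule && exo != "undetermined") {
      verdict <- "novel_ap"
      proposed <- novelName(spectrum@precursorMz)
      score <- max(scores, 0)
    }
  }
  if (verdict == "none") {
    ringMzs <- vapply(library, ringFragmentMz, numeric(1))
    isFragment <- any(abs(spectrum@precursorMz - ringMzs) <=
                        .tolWindow(config@tolerance, spectrum@precursorMz))
    if (isFragment) {
      verdict <- "ap_fragment"
      proposed <- "AP fragment"
    } else if (length(config@cypDiagnostics) &&
               any(vapply(config@cypDiagnostics, function(t)
                 !is.null(matchPeak(spectrum, t, config@tolerance)),
                 logical(1)))) {
      verdict <- "cyp_like"
    }
  }
  new("Assignment", id = spectrum@id, fraction = spectrum@fraction,
      precursorMz = spectrum@precursorMz, verdict = verdict,
      proposedName = proposed, exocyclic = exo,
      evidence = evidence, score = unname(score))
}

#' ScreenReport: fraction-level screening results
#'
#' @slot table data.frame with columns `fraction`, `mz` (nominal
#'   precursor) and `proposed`, sorted by fraction then m/z, duplicate
#'   rows collapsed.
#' @slot assignments List of per-spectrum [Assignment-class] objects.
#' @export
setClass("ScreenReport",
  representation(table = "data.frame", assignments = "list"))

setMethod("show", "ScreenReport", function(object) {
  cat(sprintf("ScreenReport: %d spectra screened, %d report rows, %d distinct proposed APs\n",
              length(object@assignments), nrow(object@table),
              length(distinctCompounds(object))))
  if (nrow(object@table)) print(object@table, row.names = FALSE)
})

# numeric sort key for labels like "40% MeOH"; non-numeric labels last
.fractionKey <- function(labels) {
  key <- suppressWarnings(as.numeric(sub("^([0-9.]+).*$", "\\1", labels)))
  key[is.na(key)] <- Inf
  key
}

#' @describeIn ScreenReport accessor for the report table
#' @param object A `ScreenReport`.
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))

#' @rdname ScreenReport
#' @export
setMethod("reportTable", "ScreenReport", function(object) object@table)

#' @describeIn ScreenReport accessor for the per-spectrum assignments
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' @rdname ScreenReport
#' @export
setMethod("assignments", "ScreenReport", function(object)
  object@assignments)

#' @describeIn ScreenReport distinct proposed anabaenopeptins (named and
#'   novel; ring-fragment rows excluded)
#' @export
setGeneric("distinctCompounds",
           function(object) standardGeneric("distinctCompounds"))

#' @rdname ScreenReport
#' @export
setMethod("distinctCompounds", "ScreenReport", function(object) {
  tab <- object@table
  sort(unique(tab$proposed[tab$proposed != "AP fragment"]))
})

#' @describeIn ScreenReport fractions in which a proposed compound occurs
#' @param name Proposed compound name.
#' @export
setGeneric("compoundFractions",
           function(object, name) standardGeneric("compoundFractions"))

#' @rdname ScreenReport
#' @export
setMethod("compoundFractions", "ScreenReport", function(object, name) {
  tab <- object@table
  fr <- unique(tab$fraction[tab$proposed == name])
  fr[order(.fractionKey(fr))]
})

#' Screen a set of fraction-labelled spectra
#'
#' Screens every spectrum and assembles the fraction report: one row per
#' distinct (fraction, nominal m/z, proposed name) among AP verdicts
#' (`named_ap`, `novel_ap`, `ap_fragment`), sorted by fraction then m/z.
#'
#' @param spectra List of [MsSpectrum-class] objects carrying fraction
#'   labels.
#' @param library Named list of [APCompound-class] (default
#'   [apLibrary()]).
#' @param config A [ScreenConfig-class].
#' @return A [ScreenReport-class].
#' @export
screenFractions <- function(spectra, library = apLibrary(),
                            config = screenConfig()) {
  asn <- lapply(spectra, screenSpectrum, library = library, config = config)
  keep <- vapply(asn, function(a)
    a@verdict %in% c("named_ap", "novel_ap", "ap_fragment"), logical(1))
  if (any(keep)) {
    rows <- data.frame(
      fraction = vapply(asn[keep], function(a) a@fraction, character(1)),
      mz = vapply(asn[keep], function(a)
        as.integer(nominalMz(a@precursorMz)), integer(1)),
      proposed = vapply(asn[keep], function(a) a@proposedName,
                        character(1)),
      stringsAsFactors = FALSE)
    rows <- unique(rows)
    rows <- rows[order(.fractionKey(rows$fraction), rows$mz,
                       rows$proposed), , drop = FALSE]
    rownames(rows) <- NULL
  } else {
    rows <- data.frame(fraction = character(), mz = integer(),
                       proposed = character(), stringsAsFactors = FALSE)
  }
  new("ScreenReport", table = rows, assignments = asn)
}

#' Write a screening report as TSV
#'
#' @param report A [ScreenReport-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "ScreenReport"))
  write.table(report@table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
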