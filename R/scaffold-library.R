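# The anabaenopeptin scaffold: a five-residue ring with conserved Lys,
# joined through an ureido bond to one exocyclic residue.  Mass assembly,
# the built-in compound library, and in-silico fragment prediction.

#' @include mass-calculus.R
NULL

#' APCompound: an anabaenopeptin scaffold instance
#'
#' A five-residue ring (first residue always Lys) plus one exocyclic
#' residue joined through the ureido carbonyl.
#'
#' @slot name Compound name (e.g. `"AP B"`).
#' @slot ring Character vector of exactly five residue codes, first `"K"`.
#' @slot exocyclic Single residue code (e.g. `"R"`, `"Y"`).
#' @slot source `"literature"` or `"novel"`.
#' @export
setClass("APCompound",
  representation(name = "character", ring = "character",
                 exocyclic = "character", source = "character"),
  prototype(source = "literature"))

setValidity("APCompound", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@ring) != 5L)
    msg <- c(msg, "'ring' must contain exactly 5 residue codes")
  if (length(object@ring) >= 1L && object@ring[1L] != "K")
    msg <- c(msg, "first ring residue must be the conserved Lys ('K')")
  if (length(object@exocyclic) != 1L)
    msg <- c(msg, "'exocyclic' must be a single residue code")
  if (!object@source %in% c("literature", "novel"))
    msg <- c(msg, "'source' must be 'literature' or 'novel'")
  known <- residueTable()$code
  bad <- setdiff(c(object@ring, object@exocyclic), known)
  if (length(bad))
    msg <- c(msg, sprintf("unknown residue code(s): %s",
                          paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an APCompound
#'
#' @param name Compound name.
#' @param ring Character vector of five residue codes, first `"K"`.
#' @param exocyclic Exocyclic residue code.
#' @param source `"literature"` (default) or `"novel"`.
#' @return An [APCompound-class] object.
#' @examples
#' apB <- APCompound("AP B", c("K", "V", "Hty", "MeAla", "F"), "R")
#' nominalMz(protonate(apNeutralMass(apB)))  # 837
#' @export
APCompound <- function(name, ring, exocyclic, source = "literature") {
  new("APCompound", name = name, ring = as.character(ring),
      exocyclic = exocyclic, source = source)
}

setMethod("show", "APCompound", function(object) {
  cat(sprintf("APCompound '%s' (%s)\n", object@name, object@source))
  cat("  ring:      cyclo[", paste(object@ring, collapse = "-"), "]\n",
      sep = "")
  cat("  exocyclic:", object@exocyclic, "(ureido-linked)\n")
  cat(sprintf("  [M+H]+ : %.4f (nominal %d)\n",
              protonate(apNeutralMass(object)),
              as.integer(nominalMz(protonate(apNeutralMass(object))))))
})

#' @describeIn APCompound accessor for the compound name
#' @param object,x An `APCompound`.
#' @export
setGeneric("compoundName", function(object) standardGeneric("compoundName"))

#' @rdname APCompound
#' @export
setMethod("compoundName", "APCompound", function(object) object@name)

#' @describeIn APCompound accessor for the ring residue codes
#' @export
setGeneric("ringResidues", function(object) standardGeneric("ringResidues"))

#' @rdname APCompound
#' @export
setMethod("ringResidues", "APCompound", function(object) object@ring)

#' @describeIn APCompound accessor for the exocyclic residue code
#' @export
setGeneric("exocyclicResidue",
           function(object) standardGeneric("exocyclicResidue"))

#' @rdname APCompound
#' @export
setMethod("exocyclicResidue", "APCompound", function(object) object@exocyclic)

# Tyr-style exocyclic loss (free amino acid, complement keeps the ureido
# carbonyl); every other residue uses the Arg-style loss [residue+CO].
.TYR_STYLE <- c("Y", "Tyr")

#' Neutral monoisotopic mass of an anabaenopeptin
#'
#' Assembly rule: sum of ring residue masses (cyclic, no terminal water)
#' plus the free exocyclic amino acid (residue + H2O) plus the ureido
#' carbonyl CO, minus H2 for the two hydrogens lost in forming the ureido
#' bridge.
#'
#' @param compound An [APCompound-class].
#' @return Neutral monoisotopic mass (Da).
#' @examples
#' apA <- APCompound("AP A", c("K", "V", "Hty", "MeAla", "F"), "Y")
#' apNeutralMass(apA)  # 843.4166
#' @export
apNeutralMass <- function(compound) {
  stopifnot(is(compound, "APCompound"))
  validObject(compound)
  k <- massConstants()
  sum(residueMass(compound@ring)) +
    (unname(residueMass(compound@exocyclic)) + k[["H2O"]]) +
    k[["CO"]] - k[["H2"]]
}

#' Protonated cyclic-ring fragment m/z
#'
#' The protonated cyclic pentapeptide ring (sum of ring residue masses +
#' proton), e.g. 637.3708 for the Lys-Val-Hty-MeAla-Phe ring shared by
#' AP A and AP B.
#'
#' @inheritParams apNeutralMass
#' @return m/z of the protonated ring.
#' @export
ringFragmentMz <- function(compound) {
  stopifnot(is(compound, "APCompound"))
  validObject(compound)
  sum(residueMass(compound@ring)) + massConstants()[["proton"]]
}

#' Exocyclic neutral-loss mass
#'
#' The neutral lost from `[M + H]+` that identifies the exocyclic residue:
#' for Arg (and, by the general rule, any non-Tyr residue) the free amino
#' acid plus the ureido CO minus H2 (`[Arg + CO]`, 200.091 Da); for Tyr
#' the free amino acid alone (`[Tyr + H2O]`, 181.074 Da), leaving the
#' ureido carbonyl on the charged ring fragment.
#'
#' @inheritParams apNeutralMass
#' @return Neutral-loss mass (Da).
#' @export
exocyclicLossMass <- function(compound) {
  stopifnot(is(compound, "APCompound"))
  validObject(compound)
  k <- massConstants()
  free <- unname(residueMass(compound@exocyclic)) + k[["H2O"]]
  if (compound@exocyclic %in% .TYR_STYLE) free
  else free + k[["CO"]] - k[["H2"]]
}

#' Charged complement of the exocyclic loss
#'
#' The ring-containing fragment ion left after the exocyclic neutral loss,
#' computed structurally: the protonated ring for Arg-style losses (the CO
#' leaves with the residue), or ring + CO − H2 + proton for the Tyr-style
#' loss (the ureido carbonyl stays, e.g. 663.350 for AP A).  Satisfies
#' `protonate(apNeutralMass(c)) == exocyclicComplementMz(c) +
#' exocyclicLossMass(c)`.
#'
#' @inheritParams apNeutralMass
#' @return m/z of the complement fragment ion.
#' @export
exocyclicComplementMz <- function(compound) {
  k <- massConstants()
  base <- ringFragmentMz(compound)
  if (compound@exocyclic %in% .TYR_STYLE) base + k[["CO"]] - k[["H2"]]
  else base
}

#' PredictedSpectrum: in-silico fragment list of an anabaenopeptin
#'
#' @slot compound Name of the compound the prediction belongs to.
#' @slot entries data.frame with columns `mz` (ascending) and `label`
#'   (one of `precursor`, `ring_ion`, `lys_marker`, `immonium`,
#'   `arg_diag`, `b_ion`).
#' @export
setClass("PredictedSpectrum",
  representation(compound = "character", entries = "data.frame"))

setValidity("PredictedSpectrum", function(object) {
  e <- object@entries
  msg <- character()
  if (!all(c("mz", "label") %in% names(e)))
    msg <- c(msg, "entries must have columns 'mz' and 'label'")
  else {
    if (any(e$mz <= 0)) msg <- c(msg, "all m/z must be positive")
    if (is.unsorted(e$mz)) msg <- c(msg, "entries must be sorted by m/z")
    if (sum(e$label == "precursor") != 1L)
      msg <- c(msg, "exactly one precursor entry required")
    if (sum(e$label == "ring_ion") != 1L)
      msg <- c(msg, "exactly one ring_ion entry required")
    allowed <- c("precursor", "ring_ion", "lys_marker", "immonium",
                 "arg_diag", "b_ion")
    if (!all(e$label %in% allowed))
      msg <- c(msg, "unknown entry label")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PredictedSpectrum", function(object) {
  cat(sprintf("PredictedSpectrum for '%s': %d entries\n",
              object@compound, nrow(object@entries)))
  print(object@entries, row.names = FALSE)
})

#' @describeIn PredictedSpectrum accessor for the entry table
#' @param object A `PredictedSpectrum`.
#' @export
setGeneric("fragmentEntries",
           function(object) standardGeneric("fragmentEntries"))

#' @rdname PredictedSpectrum
#' @export
setMethod("fragmentEntries", "PredictedSpectrum",
          function(object) object@entries)

#' Predict the diagnostic fragment set of an anabaenopeptin
#'
#' Deterministically assembles the fragment ions by which AP structures
#' are recognized: the precursor `[M + H]+`; the ring-containing
#' complement of the exocyclic loss (`ring_ion`); the Lys marker at
#' 84.0808; immonium ions of every distinct ring and exocyclic residue;
#' the Arg diagnostics (175.119, 201.1) when Arg occurs anywhere in the
#' compound; and b-ions of the canonical ring linearization (ring opened
#' at the Lys alpha-amide, prefix sums + proton).
#'
#' @inheritParams apNeutralMass
#' @return A [PredictedSpectrum-class].
#' @examples
#' apB <- APCompound("AP B", c("K", "V", "Hty", "MeAla", "F"), "R")
#' fragmentEntries(predictFragments(apB))
#' @export
predictFragments <- function(compound) {
  stopifnot(is(compound, "APCompound"))
  validObject(compound)
  pm <- protonate(apNeutralMass(compound))
  entries <- data.frame(
    mz = c(pm, exocyclicComplementMz(compound), lysMarkerMz()),
    label = c("precursor", "ring_ion", "lys_marker"),
    stringsAsFactors = FALSE)
  imm <- immoniumMz(unique(c(compound@ring, compound@exocyclic)))
  entries <- rbind(entries,
                   data.frame(mz = unname(imm), label = "immonium"))
  if ("R" %in% c(compound@ring, compound@exocyclic))
    entries <- rbind(entries,
                     data.frame(mz = unname(argDiagnosticMzs()),
                                label = "arg_diag"))
  bIons <- cumsum(unname(residueMass(compound@ring)))[1:4] +
    massConstants()[["proton"]]
  entries <- rbind(entries, data.frame(mz = bIons, label = "b_ion"))
  entries <- entries[order(entries$mz, entries$label), , drop = FALSE]
  rownames(entries) <- NULL
  new("PredictedSpectrum", compound = compound@name, entries = entries)
}

#' Read a compound library from TSV
#'
#' Columns: `name`, `ring` (five residue codes, comma-joined),
#' `exocyclic`, `source`.
#'
#' @param path Path to the tab-separated library file.
#' @return Named list of [APCompound-class] objects.
#' @export
readCompoundLibrary <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("name", "ring", "exocyclic")
  if (!all(required %in% names(tab)))
    .apStop(sprintf("library must have columns %s",
                    paste(required, collapse = ", ")), "libraryError")
  if (is.null(tab$source)) tab$source <- "literature"
  lib <- lapply(seq_len(nrow(tab)), function(i)
    APCompound(tab$name[i],
               trimws(strsplit(tab$ring[i], ",", fixed = TRUE)[[1]]),
               tab$exocyclic[i], tab$source[i]))
  setNames(lib, tab$name)
}

#' Write a compound library to TSV
#'
#' @param library Named list of [APCompound-class] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCompoundLibrary <- function(library, path) {
  tab <- data.frame(
    name = vapply(library, compoundName, character(1)),
    ring = vapply(library, function(c) paste(c@ring, collapse = ","),
                  character(1)),
    exocyclic = vapply(library, exocyclicResidue, character(1)),
    source = vapply(library, function(c) c@source, character(1)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The built-in anabaenopeptin library
#'
#' The four literature anabaenopeptins used for named identification:
#' AP A (ring Lys-Val-Hty-MeAla-Phe, exocyclic Tyr, nominal `[M+H]+` 844),
#' AP B (same ring, exocyclic Arg, 837), AP F (Ile for Val, exocyclic Arg,
#' 851) and oscillamide Y (Ile ring, exocyclic Tyr, 858).
#'
#' @return Named list of [APCompound-class] objects.
#' @export
apLibrary <- function() {
  if (is.null(.apEnv$library)) {
    path <- system.file("extdata", "ap_library.tsv",
                        package = "apscreen", mustWork = TRUE)
    .apEnv$library <- readCompoundLibrary(path)
  }
  .apEnv$library
}

#' Name a novel anabaenopeptin analog after its nominal mass
#'
#' New analogs whose structures are unknown are named by their nominal
#' molecular (neutral) mass: `"AP "` followed by the nominal precursor m/z
#' minus a proton, e.g. a precursor at m/z 803 gives `"AP 802"`.
#'
#' @param precursorMz Precursor m/z of the `[M + H]+` ion (must exceed the
#'   proton mass).
#' @return Character vector of names.
#' @export
novelName <- function(precursorMz) {
  if (any(precursorMz <= massConstants()[["proton"]]))
    .apStop("precursor m/z must exceed the proton mass", "massDomainError")
  sprintf("AP %d",
          as.integer(nominalMz(precursorMz - massConstants()[["proton"]])))
}
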