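# Monoisotopic mass arithmetic: the numeric foundation for every other
# module.  All masses are monoisotopic Da (QTRAP MS/MS context); average
# masses are deliberately not offered.

# monoisotopic atomic masses, Da (IUPAC 2021 atomic mass evaluation)
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.PROTON <- 1.00727646688

#' Monoisotopic mass constants
#'
#' Constants used throughout the mass engine: the proton mass and the
#' small neutrals (CO, NH3, H2O, H2) that appear in immonium-ion formation
#' and in the exocyclic neutral losses of anabaenopeptins.
#'
#' @return Named numeric vector with elements `proton`, `CO`, `NH3`,
#'   `H2O`, `H2` (Da, monoisotopic).
#' @examples
#' massConstants()["CO"]  # 27.99491
#' @export
massConstants <- function() {
  c(
    proton = .PROTON,
    CO     = .ELEMENT_MASS[["C"]] + .ELEMENT_MASS[["O"]],
    NH3    = .ELEMENT_MASS[["N"]] + 3 * .ELEMENT_MASS[["H"]],
    H2O    = 2 * .ELEMENT_MASS[["H"]] + .ELEMENT_MASS[["O"]],
    H2     = 2 * .ELEMENT_MASS[["H"]]
  )
}

#' Monoisotopic mass of an elemental formula
#'
#' Parses compact formulas such as `"C6H12N2O"` (elements C, H, N, O, S;
#' counts default to 1) and returns the monoisotopic mass.
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of monoisotopic masses (Da).
#' @examples
#' formulaMass("C2H3NO")  # glycine residue, 57.02146
#' @export
formulaMass <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (!nzchar(f) || paste(toks, collapse = "") != f)
      .apStop(sprintf("cannot parse elemental formula '%s'", f),
              "formulaParseError")
    mass <- 0
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% names(.ELEMENT_MASS))
        .apStop(sprintf("unknown element '%s' in formula '%s'", el, f),
                "formulaParseError")
      mass <- mass + n * .ELEMENT_MASS[[el]]
    }
    mass
  }, numeric(1), USE.NAMES = FALSE)
}

.readResidueTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("code", "formula", "mono_mass")
  if (!all(required %in% names(tab)))
    .apStop(sprintf("residue table must have columns %s",
                    paste(required, collapse = ", ")),
            "residueTableError")
  if (anyDuplicated(tab$code))
    .apStop("residue codes must be unique", "residueTableError")
  if (any(tab$mono_mass <= 0))
    .apStop("residue masses must be positive", "residueTableError")
  dev <- abs(tab$mono_mass - formulaMass(tab$formula))
  if (any(dev > 1e-4))
    .apStop(sprintf(
      "residue mass inconsistent with formula for: %s",
      paste(tab$code[dev > 1e-4], collapse = ", ")), "residueTableError")
  tab
}

#' Residue mass table
#'
#' The table of residue monoisotopic masses (amino acid minus water) used
#' by all mass computations.  With no argument the packaged table is
#' returned (standard residues plus the modified residues homotyrosine
#' `Hty` and N-methylalanine `MeAla` found in anabaenopeptin rings).
#' Loading from `path` validates that every stated mass agrees with its
#' elemental formula to within 1e-4 Da.
#'
#' @param path Optional path to a custom tab-separated table with columns
#'   `code`, `formula`, `mono_mass`.
#' @return A data.frame with columns `code`, `formula`, `mono_mass`.
#' @seealso [setResidueTable()] to make a custom table the session default.
#' @export
residueTable <- function(path = NULL) {
  if (!is.null(path)) return(.readResidueTable(path))
  if (is.null(.apEnv$residues)) {
    default <- system.file("extdata", "residues.tsv",
                           package = "apscreen", mustWork = TRUE)
    .apEnv$residues <- .readResidueTable(default)
  }
  .apEnv$residues
}

#' Replace the session residue table
#'
#' Installs a custom residue table (a data.frame as returned by
#' [residueTable()], or a path to one) as the table used by all subsequent
#' mass computations.  Call with `NULL` to restore the packaged table.
#'
#' @param table A data.frame with columns `code`, `formula`, `mono_mass`,
#'   a file path, or `NULL`.
#' @return The installed table, invisibly.
#' @export
setResidueTable <- function(table) {
  if (is.null(table)) {
    .apEnv$residues <- NULL
    return(invisible(residueTable()))
  }
  if (is.character(table)) table <- .readResidueTable(table)
  if (!is.data.frame(table))
    .apStop("'table' must be a data.frame, a path, or NULL",
            "residueTableError")
  # run the same consistency checks as for a file
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write.table(table, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  .apEnv$residues <- .readResidueTable(tmp)
  invisible(.apEnv$residues)
}

#' Monoisotopic residue mass
#'
#' @param code Character vector of residue codes (e.g. `"K"`, `"Hty"`).
#' @return Numeric vector of residue masses (Da, monoisotopic).
#' @examples
#' residueMass("K")  # 128.09496
#' @export
residueMass <- function(code) {
  tab <- residueTable()
  idx <- match(code, tab$code)
  if (anyNA(idx))
    .apStop(sprintf("unknown residue code(s): %s",
                    paste(unique(code[is.na(idx)]), collapse = ", ")),
            "unknownResidueError")
  setNames(tab$mono_mass[idx], code)
}

#' Immonium ion m/z of a residue
#'
#' The singly charged immonium ion `H2N+=CHR`: residue mass − CO + proton.
#'
#' @inheritParams residueMass
#' @return Numeric vector of m/z values.
#' @examples
#' immoniumMz("F")  # 120.0808, the Phe immonium ion at nominal m/z 120
#' @export
immoniumMz <- function(code) {
  residueMass(code) - massConstants()[["CO"]] + .PROTON
}

#' The Lys marker ion (nominal m/z 84)
#'
#' The conserved low-mass diagnostic ion of the anabaenopeptin Lys:
#' the Lys immonium ion after ammonia loss (immonium − NH3 = 84.0808).
#' Its presence is the precondition for calling a spectrum a potential
#' anabaenopeptin.
#'
#' @return A single m/z value (84.0808).
#' @export
lysMarkerMz <- function() {
  unname(immoniumMz("K") - massConstants()[["NH3"]])
}

#' Arg-related diagnostic ions
#'
#' The two Arg diagnostics observed in anabaenopeptin spectra: protonated
#' free arginine (`arg_175`, residue + H2O + proton = 175.119) and the
#' carbamoyl-Arg related ion (`arg_201`).  The 201.1 value is an empirical
#' constant, not assembled from a composition.
#'
#' @return Named numeric vector `c(arg_175 = 175.119, arg_201 = 201.1)`.
#' @export
argDiagnosticMzs <- function() {
  c(arg_175 = unname(residueMass("R")) + massConstants()[["H2O"]] + .PROTON,
    arg_201 = 201.1)
}

#' Protonate a neutral mass
#'
#' @param neutralMass Positive neutral monoisotopic mass (Da).
#' @return m/z of the singly protonated species `[M + H]+`.
#' @export
protonate <- function(neutralMass) {
  if (any(!is.finite(neutralMass)) || any(neutralMass <= 0))
    .apStop("neutral mass must be positive and finite", "massDomainError")
  neutralMass + .PROTON
}

#' Nominal (integer) m/z
#'
#' Rounds to the nearest integer, half away from zero -- the reporting
#' precision of the fraction tables (e.g. 844.4239 -> 844).
#'
#' @param mz Numeric vector of non-negative m/z values.
#' @return Integer-valued numeric vector.
#' @export
nominalMz <- function(mz) {
  if (any(mz < 0)) .apStop("m/z must be non-negative", "massDomainError")
  floor(mz + 0.5)
}
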