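# Seeded simulators for every input the pipeline consumes: AP and decoy
# MS/MS spectra with controlled noise, the fraction-table fixture set,
# and assay plates generated from a known dose-response truth.

#' @include screener.R inhibition.R
NULL

#' Spectrum simulation parameters
#'
#' @param mzSigma Gaussian m/z jitter SD (Da).
#' @param dropoutP Per-fragment omission probability in [0, 1).
#' @param nNoisePeaks Number of uniform-random noise peaks.
#' @param noiseMzRange m/z range of noise peaks; the default (50, 1000)
#'   mirrors the product-ion acquisition window.
#' @param intensityMeanlog,intensitySdlog Lognormal intensity model
#'   (arbitrary units).
#' @param seed Integer seed, or `NA` to draw from the current RNG stream
#'   (used by composite generators that seed once).
#' @return A list of class `SpectrumSimParams`.
#' @export
spectrumSimParams <- function(mzSigma = 0.01, dropoutP = 0.05,
                              nNoisePeaks = 10,
                              noiseMzRange = c(50, 1000),
                              intensityMeanlog = log(1e5),
                              intensitySdlog = 1, seed = NA) {
  if (dropoutP < 0 || dropoutP >= 1)
    .apStop("dropoutP must lie in [0, 1)", "simParamError")
  if (mzSigma < 0 || nNoisePeaks < 0)
    .apStop("mzSigma and nNoisePeaks must be non-negative",
            "simParamError")
  if (length(noiseMzRange) != 2L || diff(noiseMzRange) <= 0)
    .apStop("noiseMzRange must be an increasing (lo, hi) pair",
            "simParamError")
  structure(list(mzSigma = mzSigma, dropoutP = dropoutP,
                 nNoisePeaks = as.integer(nNoisePeaks),
                 noiseMzRange = noiseMzRange,
                 intensityMeanlog = intensityMeanlog,
                 intensitySdlog = intensitySdlog, seed = seed),
            class = "SpectrumSimParams")
}

.maybeSeed <- function(seed) {
  if (!is.na(seed)) set.seed(as.integer(seed))
}

.rIntensity <- function(n, params) {
  rlnorm(n, params$intensityMeanlog, params$intensitySdlog)
}

.noisePeaks <- function(params) {
  n <- params$nNoisePeaks
  if (n == 0L) return(cbind(mz = numeric(), intensity = numeric()))
  cbind(mz = runif(n, params$noiseMzRange[1], params$noiseMzRange[2]),
        intensity = .rIntensity(n, params))
}

#' Simulate an anabaenopeptin MS/MS spectrum
#'
#' Starts from [predictFragments()]: each predicted fragment is kept
#' independently with probability `1 - dropoutP`, jittered by
#' `N(0, mzSigma)` and given a lognormal intensity; `nNoisePeaks`
#' uniform-random peaks are added; the precursor peak is always kept.
#' Deterministic under a fixed `seed`.
#'
#' @param compound An [APCompound-class].
#' @param params A [spectrumSimParams()] list.
#' @param id Spectrum id (default derived from the compound name).
#' @param fraction Fraction label to attach.
#' @return An [MsSpectrum-class].
#' @export
simulateSpectrum <- function(compound, params = spectrumSimParams(),
                             id = NULL,
                             fraction = NA_character_) {
  stopifnot(is(compound, "APCompound"),
            inherits(params, "SpectrumSimParams"))
  .maybeSeed(params$seed)
  entries <- fragmentEntries(predictFragments(compound))
  prec <- entries$mz[entries$label == "precursor"]
  frag <- entries$mz[entries$label != "precursor"]
  keep <- runif(length(frag)) >= params$dropoutP
  mz <- frag[keep] + rnorm(sum(keep), 0, params$mzSigma)
  peaks <- cbind(mz = mz, intensity = .rIntensity(sum(keep), params))
  peaks <- rbind(peaks, .noisePeaks(params),
                 cbind(mz = prec + rnorm(1, 0, params$mzSigma),
                       intensity = .rIntensity(1, params)))
  if (is.null(id)) id <- sprintf("sim_%s", gsub(" ", "_", compound@name))
  msSpectrum(id, prec, peaks, 1L, fraction)
}

#' Simulate a decoy (non-anabaenopeptin) spectrum
#'
#' Random peaks only; any peak falling within 0.5 Da of the Lys marker
#' ion (84.0808) is removed, so decoys fail the gate by construction.
#'
#' @param params A [spectrumSimParams()] list (`nNoisePeaks` controls the
#'   requested peak count).
#' @param id Spectrum id.
#' @param fraction Fraction label.
#' @param precursorRange Range the random precursor m/z is drawn from.
#' @return An [MsSpectrum-class].
#' @export
simulateDecoy <- function(params = spectrumSimParams(nNoisePeaks = 30),
                          id = "decoy", fraction = NA_character_,
                          precursorRange = c(600, 900)) {
  stopifnot(inherits(params, "SpectrumSimParams"))
  .maybeSeed(params$seed)
  peaks <- .noisePeaks(params)
  peaks <- peaks[abs(peaks[, "mz"] - lysMarkerMz()) > 0.5, ,
                 drop = FALSE]
  prec <- runif(1, precursorRange[1], precursorRange[2])
  msSpectrum(id, prec, peaks, 1L, fraction)
}

# gate ion + exocyclic-loss complement + Arg diagnostics: the generic
# novel-analog signature (the characterized novel analogs carry the
# Arg-style loss by default)
.simulateNovel <- function(precursorMz, params, id, fraction) {
  k <- massConstants()
  argLoss <- unname(residueMass("R")) + k[["H2O"]] + k[["CO"]] - k[["H2"]]
  core <- c(lysMarkerMz(), precursorMz - argLoss)   # never dropped
  optional <- c(unname(immoniumMz("F")), unname(argDiagnosticMzs()))
  keep <- runif(length(optional)) >= params$dropoutP
  mz <- c(core, optional[keep]) +
    rnorm(2L + sum(keep), 0, params$mzSigma)
  peaks <- cbind(mz = mz, intensity = .rIntensity(length(mz), params))
  peaks <- rbind(peaks, .noisePeaks(params),
                 cbind(mz = precursorMz + rnorm(1, 0, params$mzSigma),
                       intensity = .rIntensity(1, params)))
  msSpectrum(id, precursorMz, peaks, 1L, fraction)
}

# a bare ring-fragment spectrum (precursor at the fragment m/z)
.simulateFragment <- function(precursorMz, ring, params, id, fraction) {
  bIons <- cumsum(unname(residueMass(ring)))[1:4] +
    massConstants()[["proton"]]
  mz <- c(lysMarkerMz(), unname(immoniumMz("F")), bIons)
  keep <- runif(length(mz)) >= params$dropoutP
  mz <- mz[keep] + rnorm(sum(keep), 0, params$mzSigma)
  peaks <- cbind(mz = mz, intensity = .rIntensity(sum(keep), params))
  peaks <- rbind(peaks, .noisePeaks(params),
                 cbind(mz = precursorMz + rnorm(1, 0, params$mzSigma),
                       intensity = .rIntensity(1, params)))
  msSpectrum(id, precursorMz, peaks, 1L, fraction)
}

#' Build the fraction-table fixture set
#'
#' Generates one simulated spectrum per row of the reference fraction
#' table: the named library anabaenopeptins (AP A in 20-60% MeOH, AP B in
#' 40-60%, AP F in 60%, OSC Y in 30-50%), generic novel-analog spectra
#' with precursors near m/z 803 / 810 / 828 (gate ion plus the 200.091 Da
#' Arg-style loss), ring-fragment spectra at m/z 637 (70-100% MeOH), and
#' unassigned fragment-like spectra at m/z 752 (50-60%).  Mild noise
#' (m/z jitter 0.01 Da, 5% fragment dropout) is applied throughout.
#' Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @return List of [MsSpectrum-class] objects.
#' @export
buildFractionFixture <- function(seed = 1L) {
  set.seed(as.integer(seed))
  params <- spectrumSimParams(mzSigma = 0.01, dropoutP = 0.05,
                              nNoisePeaks = 5, seed = NA)
  lib <- apLibrary()
  named <- list(
    list(fr = 20, cpd = "AP A"),
    list(fr = 30, cpd = "AP A"), list(fr = 30, cpd = "OSC Y"),
    list(fr = 40, cpd = "AP B"), list(fr = 40, cpd = "AP A"),
    list(fr = 40, cpd = "OSC Y"),
    list(fr = 50, cpd = "AP B"), list(fr = 50, cpd = "AP A"),
    list(fr = 50, cpd = "OSC Y"),
    list(fr = 60, cpd = "AP B"), list(fr = 60, cpd = "AP A"),
    list(fr = 60, cpd = "AP F"))
  novel <- list(
    list(fr = 30, mz = 810.45), list(fr = 40, mz = 803.46),
    list(fr = 40, mz = 810.45), list(fr = 40, mz = 828.47),
    list(fr = 50, mz = 803.46), list(fr = 60, mz = 803.46))
  spectra <- list()
  lab <- function(fr) sprintf("%d%% MeOH", fr)
  for (row in named) {
    id <- sprintf("F%02d_%s", row$fr, gsub(" ", "_", row$cpd))
    spectra[[length(spectra) + 1L]] <-
      simulateSpectrum(lib[[row$cpd]], params, id, lab(row$fr))
  }
  for (row in novel) {
    id <- sprintf("F%02d_novel_%d", row$fr,
                  as.integer(nominalMz(row$mz)))
    spectra[[length(spectra) + 1L]] <-
      .simulateNovel(row$mz, params, id, lab(row$fr))
  }
  ringB <- ringResidues(lib[["AP B"]])
  ring637 <- ringFragmentMz(lib[["AP B"]])
  for (fr in c(70, 80, 90, 100)) {
    spectra[[length(spectra) + 1L]] <-
      .simulateFragment(ring637, ringB, params,
                        sprintf("F%03d_frag_637", fr), lab(fr))
  }
  # the 752 species is carried as an unassigned fragment-like spectrum:
  # no library ring matches it and no exocyclic loss is modelled
  for (fr in c(50, 60)) {
    spectra[[length(spectra) + 1L]] <-
      .simulateFragment(752.40, ringB, params,
                        sprintf("F%02d_frag_752", fr), lab(fr))
  }
  spectra
}

#' Plate simulation parameters
#'
#' @param model Generating dose-response model (`"linear"`,
#'   `"loglinear"`, `"quadratic"`).
#' @param coefficients Named truth coefficients (`intercept`, `slope`,
#'   and `quad` for the quadratic model).
#' @param doses Positive dose series; the default 10-60 ug/mL mirrors a
#'   standard-inhibitor dilution series.
#' @param a0 True zero-inhibitor absorbance (AU).
#' @param noiseSd Gaussian absorbance noise SD (AU).
#' @param replicates Wells per dose.
#' @param nZero Zero-inhibitor wells.
#' @param seed Integer seed, or `NA` to draw from the current stream.
#' @return A list of class `PlateSimParams`.
#' @export
plateSimParams <- function(model = "linear",
                           coefficients = c(intercept = 0, slope = 0.01),
                           doses = c(10, 20, 30, 40, 50, 60),
                           a0 = 1.0, noiseSd = 0.02, replicates = 2L,
                           nZero = 4L, seed = NA) {
  if (!model %in% .MODELS)
    .apStop(sprintf("unknown model '%s'", model), "simParamError")
  if (model == "loglinear" && any(doses <= 0))
    .apStop("loglinear truth requires positive doses", "simParamError")
  if (noiseSd < 0) .apStop("noiseSd must be non-negative", "simParamError")
  structure(list(model = model, coefficients = coefficients,
                 doses = doses, a0 = a0, noiseSd = noiseSd,
                 replicates = as.integer(replicates),
                 nZero = as.integer(nZero), seed = seed),
            class = "PlateSimParams")
}

#' True IC50 implied by plate simulation parameters
#'
#' Solves the noiseless generating curve for 50% inhibition within the
#' dose series (the quantity a recovery study compares estimates to).
#'
#' @param params A [plateSimParams()] list.
#' @return The true IC50 in dose units.
#' @export
trueIc50 <- function(params) {
  stopifnot(inherits(params, "PlateSimParams"))
  fit <- new("DoseResponseFit", model = params$model,
             coefficients = params$coefficients, mre = 0,
             n = length(params$doses), doseRange = range(params$doses),
             ic50 = NA_real_)
  ic50(fit)
}

#' Simulate an inhibition-assay plate
#'
#' Well absorbances are `a0 * (1 - inhibition(dose)) + N(0, noiseSd)`,
#' with `nZero` zero-inhibitor wells at dose 0.  Deterministic under a
#' fixed `seed`.
#'
#' @param params A [plateSimParams()] list.
#' @param enzyme,sample Labels attached to the measurements.
#' @return data.frame with columns `enzyme`, `sample`, `dose`,
#'   `absorbance`, `replicate`.
#' @export
simulatePlate <- function(params = plateSimParams(), enzyme = "enzyme",
                          sample = "sample") {
  stopifnot(inherits(params, "PlateSimParams"))
  .maybeSeed(params$seed)
  inh <- .predictInhibition(params$model, params$coefficients,
                            params$doses)
  dose <- c(rep(0, params$nZero),
            rep(params$doses, each = params$replicates))
  truth <- c(rep(0, params$nZero), rep(inh, each = params$replicates))
  replicate <- c(seq_len(params$nZero),
                 rep(seq_len(params$replicates), length(params$doses)))
  absorbance <- params$a0 * (1 - truth) +
    rnorm(length(dose), 0, params$noiseSd)
  data.frame(enzyme = enzyme, sample = sample, dose = dose,
             absorbance = pmax(absorbance, 0), replicate = replicate,
             stringsAsFactors = FALSE)
}
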