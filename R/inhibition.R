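# Enzyme-inhibition quantification: percent inhibition from plate
# absorbances, dose-response fitting (linear / loglinear / quadratic)
# selected by mean percent relative error, IC50 extraction, the
# relative-potency statistic and the significance rule.

.MODELS <- c("linear", "loglinear", "quadratic")

#' DoseResponseFit: a fitted dose-response curve
#'
#' @slot model `"linear"`, `"loglinear"` or `"quadratic"`.
#' @slot coefficients Named coefficients (`intercept`, `slope`, and
#'   `quad` for the quadratic model).  The loglinear model is linear in
#'   log10(dose).
#' @slot mre Mean percent relative error between measured and
#'   back-calculated inhibition (%).
#' @slot n Number of fitted points.
#' @slot doseRange Range of the fitted doses (interpolation domain).
#' @slot ic50 IC50 within the fitted dose range, or `NA` when the curve
#'   does not attain 50% inhibition there.
#' @export
setClass("DoseResponseFit",
  representation(model = "character", coefficients = "numeric",
                 mre = "numeric", n = "integer", doseRange = "numeric",
                 ic50 = "numeric"))

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (!object@model %in% .MODELS)
    msg <- c(msg, "unknown model")
  if (!is.na(object@ic50) && object@ic50 <= 0)
    msg <- c(msg, "ic50 must be positive when defined")
  if (is.finite(object@mre) && object@mre < 0)
    msg <- c(msg, "mean percent relative error must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf("DoseResponseFit (%s, n = %d): MRE %.3g%%\n",
              object@model, object@n, object@mre))
  print(round(object@coefficients, 6))
  cat(if (is.na(object@ic50)) "  IC50: not attained in dose range\n"
      else sprintf("  IC50: %.4g (dose range %.3g-%.3g)\n", object@ic50,
                   object@doseRange[1], object@doseRange[2]))
})

#' @describeIn DoseResponseFit accessor for the mean percent relative
#'   error
#' @param object A `DoseResponseFit`.
#' @export
setGeneric("meanRelativeError",
           function(object) standardGeneric("meanRelativeError"))

#' @rdname DoseResponseFit
#' @export
setMethod("meanRelativeError", "DoseResponseFit",
          function(object) object@mre)

#' @describeIn DoseResponseFit accessor for the model name
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))

#' @rdname DoseResponseFit
#' @export
setMethod("modelName", "DoseResponseFit", function(object) object@model)

#' Percent inhibition from mean absorbances
#'
#' `(A0 - AI) / A0`, where `A0` is the mean absorbance of the
#' zero-inhibitor wells and `AI` the mean absorbance with inhibitor or
#' fraction present.  Values above 1 or below 0 (activation) are returned
#' as-is: they signal assay problems and should not be masked.
#'
#' @param a0 Mean zero-inhibitor absorbance (must be positive).
#' @param ai Mean sample absorbance(s).
#' @return Inhibition as a fraction (0.5 = 50% inhibition).
#' @examples
#' percentInhibition(1.0, 0.25)  # 0.75
#' @export
percentInhibition <- function(a0, ai) {
  if (length(a0) != 1L || !is.finite(a0) || a0 <= 0)
    .apStop("A0 must be a single positive absorbance", "assayDomainError")
  (a0 - ai) / a0
}

# model prediction from named coefficients
.predictInhibition <- function(model, cf, dose) {
  switch(model,
    linear    = cf[["intercept"]] + cf[["slope"]] * dose,
    loglinear = cf[["intercept"]] + cf[["slope"]] * log10(dose),
    quadratic = cf[["intercept"]] + cf[["slope"]] * dose +
                cf[["quad"]] * dose^2,
    .apStop(sprintf("unknown model '%s'", model), "assayDomainError"))
}

# mean percent relative error between measured and back-calculated
# inhibition; points with measured inhibition 0 carry no relative scale
# and are excluded (degenerate all-zero data give 0 for a perfect fit)
.mre <- function(observed, predicted) {
  nz <- observed != 0
  if (!any(nz)) {
    return(if (all(abs(predicted - observed) < 1e-12)) 0 else Inf)
  }
  100 * mean(abs((predicted[nz] - observed[nz]) / observed[nz]))
}

#' Fit a dose-response regression
#'
#' Least-squares fit of inhibition on dose (`linear`), on log10(dose)
#' (`loglinear`), or on dose and dose squared (`quadratic`).  Model
#' accuracy is recorded as the mean percent relative error between
#' measured and back-calculated inhibition.
#'
#' @param dose Numeric doses (all positive for `loglinear`).
#' @param inhibition Measured inhibition fractions (from
#'   [percentInhibition()]).
#' @param model One of `"linear"`, `"loglinear"`, `"quadratic"`.
#' @return A [DoseResponseFit-class]; its `ic50` slot holds the in-range
#'   IC50 or `NA`.
#' @export
fitDoseResponse <- function(dose, inhibition,
                            model = c("linear", "loglinear", "quadratic")) {
  model <- match.arg(model)
  if (length(dose) != length(inhibition))
    .apStop("dose and inhibition must have equal length",
            "assayDomainError")
  if (length(dose) < 3L)
    .apStop("at least 3 dose-response points are required",
            "assayDomainError")
  if (model == "loglinear" && any(dose <= 0))
    .apStop("loglinear model requires strictly positive doses",
            "assayDomainError")
  fit <- switch(model,
    linear    = lm(inhibition ~ dose),
    loglinear = lm(inhibition ~ log10(dose)),
    quadratic = lm(inhibition ~ dose + I(dose^2)))
  cf <- unname(coef(fit))
  cf[is.na(cf)] <- 0  # rank-deficient (e.g. constant response): drop term
  coefficients <- switch(model,
    linear    = c(intercept = cf[1], slope = cf[2]),
    loglinear = c(intercept = cf[1], slope = cf[2]),
    quadratic = c(intercept = cf[1], slope = cf[2], quad = cf[3]))
  predicted <- .predictInhibition(model, coefficients, dose)
  obj <- new("DoseResponseFit", model = model,
             coefficients = coefficients,
             mre = .mre(inhibition, predicted),
             n = length(dose), doseRange = range(dose), ic50 = NA_real_)
  obj@ic50 <- tryCatch(ic50(obj), undefinedIc50Error = function(e) NA_real_)
  obj
}

#' Select the dose-response model by mean percent relative error
#'
#' Fits every applicable model (the loglinear model is skipped when any
#' dose is non-positive) and returns the fit with the smallest mean
#' percent relative error; effective ties (within 1e-9 percentage points)
#' go to the simplest model (linear < loglinear < quadratic).
#'
#' @inheritParams fitDoseResponse
#' @return The selected [DoseResponseFit-class].
#' @export
selectModel <- function(dose, inhibition) {
  if (length(dose) < 4L)
    .apStop("model selection requires at least 4 points",
            "assayDomainError")
  models <- .MODELS
  if (any(dose <= 0)) models <- setdiff(models, "loglinear")
  fits <- lapply(models, function(m) fitDoseResponse(dose, inhibition, m))
  mres <- vapply(fits, meanRelativeError, numeric(1))
  best <- min(mres)
  fits[[which(mres <= best + 1e-9)[1L]]]  # models ordered simplest first
}

#' IC50 from a fitted dose-response curve
#'
#' The dose at which the fitted curve predicts 50% inhibition.  By
#' default only interpolation within the fitted dose range is allowed; a
#' curve that never attains 0.5 there raises an `undefinedIc50Error`
#' (distinct from a fitting failure).  For the quadratic model the root
#' inside the data range is taken, the smaller one if both qualify.
#'
#' @param fit A [DoseResponseFit-class].
#' @param extrapolate Allow solutions outside the fitted dose range
#'   (with a warning).
#' @return The IC50 in dose units.
#' @export
ic50 <- function(fit, extrapolate = FALSE) {
  stopifnot(is(fit, "DoseResponseFit"))
  cf <- fit@coefficients
  lo <- fit@doseRange[1]; hi <- fit@doseRange[2]
  roots <- switch(fit@model,
    linear = if (cf[["slope"]] == 0) numeric()
             else (0.5 - cf[["intercept"]]) / cf[["slope"]],
    loglinear = if (cf[["slope"]] == 0) numeric()
                else 10^((0.5 - cf[["intercept"]]) / cf[["slope"]]),
    quadratic = {
      a <- cf[["quad"]]; b <- cf[["slope"]]
      c0 <- cf[["intercept"]] - 0.5
      if (a == 0) {
        if (b == 0) numeric() else -c0 / b
      } else {
        disc <- b^2 - 4 * a * c0
        if (disc < 0) numeric()
        else sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
      }
    })
  roots <- roots[is.finite(roots) & roots > 0]
  tolRange <- 1e-8 * max(abs(hi), 1)
  inRange <- roots[roots >= lo - tolRange & roots <= hi + tolRange]
  if (length(inRange)) return(min(inRange))
  if (extrapolate && length(roots)) {
    warning("IC50 obtained by extrapolation outside the fitted dose range")
    return(min(roots))
  }
  .apStop("fitted curve does not attain 50% inhibition within the dose range",
          "undefinedIc50Error")
}

#' Relative inhibitory potency against a standard inhibitor
#'
#' The fraction-vs-standard IC50 ratio expressed as a percentage.  With
#' the default direction, `100 * ic50Standard / ic50Fraction`: a fraction
#' needing more material than the standard inhibitor scores below 100%.
#' The opposite reading (`"fraction_over_standard"`) is also supported;
#' output tables name the convention in use.
#'
#' @param ic50Fraction IC50 of the fraction (dose units; positive).
#' @param ic50Standard IC50 of the standard inhibitor (same units).
#' @param direction Ratio convention.
#' @return Relative inhibition in percent.
#' @export
relativeInhibition <- function(ic50Fraction, ic50Standard,
                               direction = c("standard_over_fraction",
                                             "fraction_over_standard")) {
  direction <- match.arg(direction)
  if (any(ic50Fraction <= 0) || any(ic50Standard <= 0))
    .apStop("IC50 values must be positive", "assayDomainError")
  if (direction == "standard_over_fraction")
    100 * ic50Standard / ic50Fraction
  else
    100 * ic50Fraction / ic50Standard
}

#' Flag fractions whose inhibition differs significantly from the mean
#'
#' A fraction is flagged significant when its mean inhibition lies
#' outside the t-based 95% confidence interval of the across-fraction
#' mean (computed from the per-fraction means).  Groups with fewer than
#' two replicate values, or a design with fewer than two usable groups,
#' yield `NA` flags.
#'
#' @param groups Named list of numeric vectors: replicate inhibition
#'   values per fraction.
#' @param conf Confidence level (default 0.95).
#' @return Named logical vector of significance flags (`NA` where
#'   undefined).
#' @export
significanceFlag <- function(groups, conf = 0.95) {
  stopifnot(is.list(groups))
  flags <- setNames(rep(NA, length(groups)), names(groups))
  usable <- vapply(groups, function(g) sum(is.finite(g)) >= 2L, logical(1))
  if (sum(usable) < 2L) return(flags)
  means <- vapply(groups[usable], function(g) mean(g[is.finite(g)]),
                  numeric(1))
  k <- length(means)
  centre <- mean(means)
  half <- qt(1 - (1 - conf) / 2, df = k - 1L) * sd(means) / sqrt(k)
  flags[usable] <- means < centre - half | means > centre + half
  flags
}

#' Read a plate-measurement CSV
#'
#' Columns: `enzyme`, `sample`, `dose`, `absorbance`, `replicate`.
#' Zero-inhibitor wells carry `dose = 0`.
#'
#' @param path Path to the CSV file.
#' @return data.frame of plate measurements.
#' @export
readPlate <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("enzyme", "sample", "dose", "absorbance", "replicate")
  if (!all(required %in% names(tab)))
    .apStop(sprintf("plate file must have columns %s",
                    paste(required, collapse = ", ")), "plateFormatError")
  if (any(tab$absorbance < 0) || any(tab$dose < 0))
    .apStop("doses and absorbances must be non-negative",
            "plateFormatError")
  tab
}

#' Per-dose inhibition from plate measurements
#'
#' Averages replicate absorbances per (enzyme, sample, dose), estimates
#' `A0` per enzyme from the zero-inhibitor (`dose = 0`) wells and applies
#' [percentInhibition()].
#'
#' @param plate Plate data.frame (see [readPlate()]).
#' @return data.frame with columns `enzyme`, `sample`, `dose`,
#'   `inhibition` (dose > 0 rows only).
#' @export
plateInhibition <- function(plate) {
  required <- c("enzyme", "sample", "dose", "absorbance")
  if (!all(required %in% names(plate)))
    .apStop(sprintf("plate must have columns %s",
                    paste(required, collapse = ", ")), "plateFormatError")
  out <- lapply(split(plate, plate$enzyme), function(pz) {
    zero <- pz$absorbance[pz$dose == 0]
    if (!length(zero))
      .apStop(sprintf("no zero-inhibitor wells for enzyme '%s'",
                      pz$enzyme[1]), "plateFormatError")
    a0 <- mean(zero)
    dosed <- pz[pz$dose > 0, , drop = FALSE]
    agg <- aggregate(absorbance ~ sample + dose, dosed, mean)
    data.frame(enzyme = pz$enzyme[1], sample = agg$sample,
               dose = agg$dose,
               inhibition = percentInhibition(a0, agg$absorbance),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' IC50 of a single dose-response series from a plate
#'
#' Convenience wrapper: computes per-dose inhibition with
#' [plateInhibition()] (the plate must contain one enzyme and one
#' sample), fits the requested model (or selects one by mean percent
#' relative error) and extracts the IC50.
#'
#' @param plate Plate data.frame for one enzyme and one sample.
#' @param model `"auto"` (default; [selectModel()]) or a model name.
#' @param extrapolate Passed to [ic50()].
#' @return The IC50 in dose units.
#' @export
plateIc50 <- function(plate, model = "auto", extrapolate = FALSE) {
  inh <- plateInhibition(plate)
  if (length(unique(inh$sample)) != 1L || length(unique(inh$enzyme)) != 1L)
    .apStop("plateIc50 expects a single enzyme and sample",
            "assayDomainError")
  fit <- if (identical(model, "auto")) selectModel(inh$dose, inh$inhibition)
         else fitDoseResponse(inh$dose, inh$inhibition, model)
  ic50(fit, extrapolate = extrapolate)
}

#' Full inhibition analysis of a plate
#'
#' For every (enzyme, sample) series: fits a dose-response model
#' (selected by mean percent relative error unless `model` names one),
#' extracts the IC50 where attainable, computes the relative potency
#' against the standard inhibitor's IC50 and flags samples whose mean
#' inhibition differs from the across-sample mean at the 95% confidence
#' level.
#'
#' @param plate Plate data.frame (see [readPlate()]).
#' @param standard Sample id of the standard inhibitor.
#' @param model `"auto"` or a model name.
#' @param direction Relative-potency convention (see
#'   [relativeInhibition()]).
#' @return data.frame with one row per (enzyme, sample): `model`, `ic50`,
#'   `mre`, the relative potency column (named after the direction), and
#'   `significant`.
#' @export
analyzePlate <- function(plate, standard, model = "auto",
                         direction = c("standard_over_fraction",
                                       "fraction_over_standard")) {
  direction <- match.arg(direction)
  inh <- plateInhibition(plate)
  if (!standard %in% inh$sample)
    .apStop(sprintf("standard sample '%s' not found on the plate",
                    standard), "assayDomainError")
  relCol <- sprintf("relative_inhibition_pct_%s", direction)
  res <- lapply(split(inh, inh$enzyme), function(iz) {
    series <- split(iz, iz$sample)
    fits <- lapply(series, function(sr) {
      tryCatch({
        if (identical(model, "auto")) selectModel(sr$dose, sr$inhibition)
        else fitDoseResponse(sr$dose, sr$inhibition, model)
      }, apscreenError = function(e) NULL)
    })
    ic <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f@ic50,
                 numeric(1))
    flags <- significanceFlag(lapply(series, `[[`, "inhibition"))
    icStd <- ic[[standard]]
    rel <- vapply(ic, function(x)
      if (is.na(x) || is.na(icStd)) NA_real_
      else relativeInhibition(x, icStd, direction), numeric(1))
    out <- data.frame(
      enzyme = iz$enzyme[1], sample = names(series),
      model = vapply(fits, function(f)
        if (is.null(f)) NA_character_ else f@model, character(1)),
      ic50 = ic,
      mre = vapply(fits, function(f)
        if (is.null(f)) NA_real_ else f@mre, numeric(1)),
      stringsAsFactors = FALSE)
    out[[relCol]] <- rel
    out$significant <- unname(flags[out$sample])
    out
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}
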