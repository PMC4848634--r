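test_that("percent inhibition follows (A0 - AI) / A0", {
  expect_equal(percentInhibition(1.0, 0.25), 0.75)
  expect_equal(percentInhibition(0.9, 0.9), 0)
  expect_equal(percentInhibition(0.8, 0.88), -0.1)  # activation kept as-is
  expect_error(percentInhibition(0, 0.5), class = "assayDomainError")
  expect_error(percentInhibition(-1, 0.5), class = "assayDomainError")
})

test_that("percent inhibition is invariant to common absorbance rescaling", {
  set.seed(19)
  for (i in 1:20) {
    a0 <- runif(1, 0.2, 2); ai <- runif(1, 0, 2.5)
    k <- runif(1, 0.1, 10)
    expect_equal(percentInhibition(k * a0, k * ai),
                 percentInhibition(a0, ai), tolerance = 1e-12)
  }
})

test_that("noiseless regressions recover their generating coefficients", {
  d <- c(10, 20, 30, 40, 50, 60)
  lin <- fitDoseResponse(d, 0.01 * d, "linear")
  expect_equal(unname(lin@coefficients["slope"]), 0.01, tolerance = 1e-10)
  expect_lt(meanRelativeError(lin), 1e-8)

  ll <- fitDoseResponse(d, -0.3863 + 0.6 * log10(d), "loglinear")
  expect_equal(unname(ll@coefficients["intercept"]), -0.3863,
               tolerance = 1e-8)
  expect_equal(unname(ll@coefficients["slope"]), 0.6, tolerance = 1e-8)

  qd <- fitDoseResponse(d, 0.005 * d + 1e-4 * d^2, "quadratic")
  expect_equal(unname(qd@coefficients["quad"]), 1e-4, tolerance = 1e-10)

  expect_error(fitDoseResponse(c(1, 2), c(0.1, 0.2), "linear"),
               class = "assayDomainError")
  expect_error(fitDoseResponse(c(0, 10, 20), c(0, 0.1, 0.2), "loglinear"),
               class = "assayDomainError")
})

test_that("model selection recovers the generating model on clean data", {
  d <- c(10, 20, 30, 40, 50, 60)
  expect_identical(modelName(selectModel(d, 0.01 * d)), "linear")
  expect_identical(modelName(selectModel(d, -0.3863 + 0.6 * log10(d))),
                   "loglinear")
  expect_identical(modelName(selectModel(d, 0.005 * d + 1e-4 * d^2)),
                   "quadratic")
  # degenerate flat response: simplest model, zero slope
  flat <- selectModel(d, rep(0.2, 6))
  expect_identical(modelName(flat), "linear")
  expect_equal(unname(flat@coefficients["slope"]), 0, tolerance = 1e-12)
  expect_error(selectModel(c(1, 2, 3), c(0.1, 0.2, 0.3)),
               class = "assayDomainError")
})

test_that("IC50 extraction solves each model in closed form", {
  d <- c(10, 20, 30, 40, 50, 60)
  expect_equal(ic50(fitDoseResponse(d, 0.01 * d, "linear")), 50,
               tolerance = 1e-8)
  dl <- c(10, 30, 100, 300)
  expect_equal(ic50(fitDoseResponse(dl, 0.25 * log10(dl), "loglinear")),
               100, tolerance = 1e-6)
  # downward parabola crossing 0.5 twice inside the range: smaller root
  dq <- seq(10, 140, by = 10)
  fq <- fitDoseResponse(dq, 0.03 * dq - 2e-4 * dq^2, "quadratic")
  expect_equal(ic50(fq), (150 - sqrt(150^2 - 4 * 2500)) / 2,
               tolerance = 1e-6)
})

test_that("curves that never reach 50% raise a distinct IC50 error", {
  d <- c(10, 20, 30, 40, 50, 60)
  flat <- fitDoseResponse(d, rep(0.2, 6), "linear")
  expect_error(ic50(flat), class = "undefinedIc50Error")
  weak <- fitDoseResponse(d, 0.002 * d, "linear")  # 50% only at dose 250
  expect_error(ic50(weak), class = "undefinedIc50Error")
  expect_true(is.na(weak@ic50))
  expect_warning(est <- ic50(weak, extrapolate = TRUE), "extrapolation")
  expect_equal(est, 250, tolerance = 1e-8)
})

test_that("relative potency follows the documented IC50 ratio", {
  expect_equal(relativeInhibition(10, 10), 100)
  expect_equal(relativeInhibition(20, 10), 50)
  expect_equal(relativeInhibition(1000, 10), 1)
  expect_equal(relativeInhibition(20, 10,
                                  direction = "fraction_over_standard"),
               200)
  expect_error(relativeInhibition(-1, 10), class = "assayDomainError")
})

test_that("significance flags fractions outside the 95% CI of the mean", {
  equal <- list(a = c(0.2, 0.2), b = c(0.2, 0.2), c = c(0.2, 0.2))
  expect_true(all(!significanceFlag(equal)))
  set.seed(29)
  groups <- lapply(1:5, function(i) rnorm(4, 0.2, 0.01))
  names(groups) <- paste0("f", 1:5)
  groups$shifted <- rnorm(4, 0.2 + 10 * 0.01, 0.01)  # 10 SD shift
  flags <- significanceFlag(groups)
  expect_true(flags[["shifted"]])
  expect_true(all(!flags[paste0("f", 1:5)]))
  expect_true(is.na(significanceFlag(list(only = c(0.1, 0.2)))[[1]]))
  mixed <- significanceFlag(list(a = 0.1, b = c(0.2, 0.2),
                                 c = c(0.2, 0.2)))
  expect_true(is.na(mixed[["a"]]))
})

test_that("plate-level analysis recovers IC50s and ranks samples", {
  set.seed(37)
  std <- simulatePlate(plateSimParams(noiseSd = 0, seed = NA),
                       enzyme = "trypsin", sample = "aprotinin")
  # a fraction needing twice the dose of the standard
  frac <- simulatePlate(plateSimParams(
    coefficients = c(intercept = 0, slope = 0.005),
    doses = c(20, 40, 60, 80, 100, 120), noiseSd = 0, seed = NA),
    enzyme = "trypsin", sample = "60% MeOH")
  res <- analyzePlate(rbind(std, frac), standard = "aprotinin")
  expect_setequal(res$sample, c("aprotinin", "60% MeOH"))
  icStd <- res$ic50[res$sample == "aprotinin"]
  icFrac <- res$ic50[res$sample == "60% MeOH"]
  expect_equal(icStd, 50, tolerance = 1e-6)
  expect_equal(icFrac, 100, tolerance = 1e-6)
  rel <- res[[grep("relative_inhibition", names(res))]]
  expect_equal(rel[res$sample == "60% MeOH"], 50, tolerance = 1e-6)
  expect_equal(rel[res$sample == "aprotinin"], 100, tolerance = 1e-6)
})

test_that("plate CSV files are read and validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  plate <- simulatePlate(plateSimParams(seed = 43))
  write.csv(plate, path, row.names = FALSE)
  back <- readPlate(path)
  expect_equal(back$absorbance, plate$absorbance, tolerance = 1e-12)
  writeLines("a,b\n1,2", path)
  expect_error(readPlate(path), class = "plateFormatError")
})
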