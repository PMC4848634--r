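lib <- apLibrary()

test_that("library assembly reproduces the printed nominal [M+H]+ values", {
  nominal <- vapply(lib, function(c)
    unname(nominalMz(protonate(apNeutralMass(c)))), numeric(1))
  expect_identical(unname(nominal[c("AP A", "AP B", "AP F", "OSC Y")]),
                   c(844, 837, 851, 858))
  # independent oracle route: atomic-mass sums over the compositions
  k <- c(CO = 12 + .oracleElements[["O"]],
         H2O = 2 * .oracleElements[["H"]] + .oracleElements[["O"]],
         H2 = 2 * .oracleElements[["H"]])
  oracle <- function(ring, exo)
    sum(oracleResidueMass(ring)) + oracleResidueMass(exo) + k[["H2O"]] +
      k[["CO"]] - k[["H2"]] + .oracleProton
  expect_equal(protonate(apNeutralMass(lib[["AP A"]])),
               unname(oracle(c("K", "V", "Hty", "MeAla", "F"), "Y")),
               tolerance = 1e-4)
  expect_equal(protonate(apNeutralMass(lib[["AP B"]])),
               unname(oracle(c("K", "V", "Hty", "MeAla", "F"), "R")),
               tolerance = 1e-4)
})

test_that("neutral masses match the derived reference values", {
  expect_equal(apNeutralMass(lib[["AP B"]]), 836.4544, tolerance = 1e-4)
  expect_equal(apNeutralMass(lib[["AP A"]]), 843.4166, tolerance = 1e-4)
  # Val -> Ile substitution is one CH2
  expect_equal(apNeutralMass(lib[["AP F"]]) - apNeutralMass(lib[["AP B"]]),
               14.0157, tolerance = 1e-4)
})

test_that("ring fragment ions match the reported fragment m/z", {
  expect_equal(ringFragmentMz(lib[["AP B"]]), 637.3708, tolerance = 1e-4)
  expect_identical(unname(nominalMz(ringFragmentMz(lib[["AP B"]]))), 637)
  expect_equal(ringFragmentMz(lib[["AP F"]]), 651.386, tolerance = 1e-3)
})

test_that("exocyclic losses are 200.091 for Arg and 181.074 for Tyr", {
  expect_equal(exocyclicLossMass(lib[["AP B"]]), 200.091, tolerance = 1e-3)
  expect_identical(unname(nominalMz(exocyclicLossMass(lib[["AP B"]]))), 200)
  expect_equal(exocyclicLossMass(lib[["AP A"]]), 181.074, tolerance = 1e-3)
  expect_identical(unname(nominalMz(exocyclicLossMass(lib[["AP A"]]))), 181)
  expect_equal(exocyclicLossMass(lib[["AP F"]]), 200.091, tolerance = 1e-3)
})

test_that("the exocyclic-loss complement conserves mass for all scaffolds", {
  set.seed(23)
  cases <- c(lib, lapply(1:200, function(i) randomScaffold()))
  for (c in cases) {
    expect_equal(protonate(apNeutralMass(c)),
                 exocyclicComplementMz(c) + exocyclicLossMass(c),
                 tolerance = 1e-4, label = compoundName(c))
    if (!exocyclicResidue(c) %in% c("Y", "Tyr"))
      expect_equal(exocyclicComplementMz(c), ringFragmentMz(c),
                   tolerance = 1e-9)
  }
  # Tyr-style complement keeps the ureido carbonyl (AP A case)
  expect_equal(exocyclicComplementMz(lib[["AP A"]]), 663.350,
               tolerance = 1e-3)
})

test_that("scaffold validity enforces the conserved-Lys five-residue ring", {
  expect_error(APCompound("bad", c("K", "V", "F"), "R"), "5 residue")
  expect_error(APCompound("bad", c("V", "K", "F", "A", "G"), "R"),
               "conserved Lys")
  expect_error(APCompound("bad", c("K", "V", "F", "A", "Zz"), "R"),
               "unknown residue")
})

test_that("predicted fragment sets carry the diagnostic ions", {
  entries <- fragmentEntries(predictFragments(lib[["AP B"]]))
  has <- function(mz) any(abs(entries$mz - mz) < 5e-4)
  for (mz in c(84.0808, 120.0808, 175.119, 201.1, 637.3708, 837.4617))
    expect_true(has(mz), label = sprintf("m/z %.4f", mz))
  # AP A has no Arg anywhere: diagnostics absent
  entriesA <- fragmentEntries(predictFragments(lib[["AP A"]]))
  expect_true(any(abs(entriesA$mz - 120.0808) < 5e-4))
  expect_false(any(abs(entriesA$mz - 175.119) < 5e-3))
  expect_false(any(entriesA$label == "arg_diag"))
})

test_that("predicted spectra are sorted, bounded by the precursor and stable", {
  set.seed(31)
  for (c in c(lib, lapply(1:20, function(i) randomScaffold()))) {
    ps <- predictFragments(c)
    e <- fragmentEntries(ps)
    expect_false(is.unsorted(e$mz))
    expect_true(all(e$mz <= e$mz[e$label == "precursor"] + 1e-9))
    expect_identical(sum(e$label == "precursor"), 1L)
    expect_identical(sum(e$label == "ring_ion"), 1L)
    expect_identical(e, fragmentEntries(predictFragments(c)))
  }
})

test_that("novel analogs are named after their nominal molecular mass", {
  expect_identical(novelName(803), "AP 802")
  expect_identical(novelName(810), "AP 809")
  expect_identical(novelName(828), "AP 827")
  expect_identical(novelName(803.46), "AP 802")
  expect_error(novelName(0.5), class = "massDomainError")
})

test_that("compound libraries survive a TSV round trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCompoundLibrary(lib, path)
  back <- readCompoundLibrary(path)
  expect_identical(names(back), names(lib))
  for (nm in names(lib)) {
    expect_identical(ringResidues(back[[nm]]), ringResidues(lib[[nm]]))
    expect_identical(exocyclicResidue(back[[nm]]),
                     exocyclicResidue(lib[[nm]]))
  }
})
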