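lib <- apLibrary()
cfg <- screenConfig()

test_that("the Lys marker gate admits AP spectra and rejects decoys", {
  apB <- simulateSpectrum(lib[["AP B"]], noiselessParams(seed = 1))
  expect_true(gateLys(apB, cfg))
  decoy <- simulateDecoy(spectrumSimParams(nNoisePeaks = 30, seed = 2))
  expect_false(gateLys(decoy, cfg))
  # a peak at 85.0 misses the 84.0808 marker at 0.5 Da tolerance
  near <- msSpectrum("near", 900, cbind(85.0, 1e5))
  expect_false(gateLys(near, cfg))
})

test_that("diagnostic evidence reflects the residues present", {
  apB <- simulateSpectrum(lib[["AP B"]], noiselessParams(seed = 3))
  expect_setequal(collectEvidence(apB, cfg),
                  c("lys_marker", "phe_immonium", "arg_175", "arg_201"))
  apA <- simulateSpectrum(lib[["AP A"]], noiselessParams(seed = 4))
  evA <- collectEvidence(apA, cfg)
  expect_true(all(c("lys_marker", "phe_immonium") %in% evA))
  expect_false(any(c("arg_175", "arg_201") %in% evA))
  empty <- msSpectrum("e", 900, matrix(numeric(), ncol = 2))
  expect_identical(collectEvidence(empty, cfg), character(0))
})

test_that("the exocyclic residue is inferred from its neutral loss", {
  argCase <- msSpectrum("a", 837.4617, cbind(637.3708, 1e5))
  expect_identical(inferExocyclic(argCase, cfg), "Arg")
  tyrCase <- msSpectrum("t", 844.4239, cbind(663.350, 1e5))
  expect_identical(inferExocyclic(tyrCase, cfg), "Tyr")
  neither <- msSpectrum("n", 837.4617, cbind(500.0, 1e5))
  expect_identical(inferExocyclic(neither, cfg), "undetermined")
  # both losses present: the larger matched intensity wins
  both <- msSpectrum("b", 844.4239,
                     cbind(c(644.333, 663.350), c(1e3, 1e6)))
  expect_identical(inferExocyclic(both, cfg), "Tyr")
  both2 <- msSpectrum("b2", 844.4239,
                      cbind(c(644.333, 663.350), c(1e6, 1e3)))
  expect_identical(inferExocyclic(both2, cfg), "Arg")
})

test_that("library scoring is 1 on self-matches and 0 across precursors", {
  apB <- simulateSpectrum(lib[["AP B"]], noiselessParams(seed = 5))
  expect_equal(scoreLibraryMatch(apB, lib[["AP B"]], cfg), 1.0)
  # AP B precursor (837.46) misses AP A (844.42) by ~7 Da: gated to 0
  expect_equal(scoreLibraryMatch(apB, lib[["AP A"]], cfg), 0)
})

test_that("fragment dropout depresses the match score proportionally", {
  params <- spectrumSimParams(mzSigma = 0, dropoutP = 0.5,
                              nNoisePeaks = 0, seed = NA)
  set.seed(17)
  scores <- replicate(60, scoreLibraryMatch(
    simulateSpectrum(lib[["AP B"]], params), lib[["AP B"]], cfg))
  # expectation slightly above the 0.5 keep rate: the b1 ion and the Arg
  # immonium are 0.012 Da apart, so either peak satisfies both targets
  expect_gt(mean(scores), 0.45)
  expect_lt(mean(scores), 0.65)
})

test_that("screening names library APs, novel analogs and decoys correctly", {
  apA <- simulateSpectrum(lib[["AP A"]], noiselessParams(seed = 6))
  asnA <- screenSpectrum(apA, lib, cfg)
  expect_identical(verdict(asnA), "named_ap")
  expect_identical(proposedName(asnA), "AP A")
  expect_gte(matchScore(asnA), cfg@matchThreshold)

  set.seed(7)
  novel <- apscreen:::.simulateNovel(803.46, noiselessParams(), "nov",
                                     "40% MeOH")
  asnN <- screenSpectrum(novel, lib, cfg)
  expect_identical(verdict(asnN), "novel_ap")
  expect_identical(proposedName(asnN), "AP 802")

  decoy <- simulateDecoy(spectrumSimParams(nNoisePeaks = 20, seed = 8))
  expect_identical(verdict(screenSpectrum(decoy, lib, cfg)), "none")
})

test_that("spectra at a bare ring mass are reported as AP fragments", {
  set.seed(9)
  frag <- apscreen:::.simulateFragment(ringFragmentMz(lib[["AP B"]]),
                                       ringResidues(lib[["AP B"]]),
                                       noiselessParams(), "frag",
                                       "70% MeOH")
  asn <- screenSpectrum(frag, lib, cfg)
  expect_identical(verdict(asn), "ap_fragment")
  expect_identical(proposedName(asn), "AP fragment")
})

test_that("CYP-like flagging fires only on configured diagnostics", {
  cyp <- msSpectrum("c", 956.5, cbind(c(215.14, 400.2), c(1e5, 1e4)))
  expect_identical(verdict(screenSpectrum(cyp, lib, cfg)), "cyp_like")
  off <- screenConfig(cypDiagnostics = numeric())
  expect_identical(verdict(screenSpectrum(cyp, lib, off)), "none")
})

test_that("spectra without the gate ion never receive AP verdicts", {
  set.seed(13)
  params <- spectrumSimParams(nNoisePeaks = 40, seed = NA)
  verdicts <- replicate(500, verdict(
    screenSpectrum(simulateDecoy(params), lib, cfg)))
  expect_false(any(verdicts %in% c("named_ap", "novel_ap")))
})

test_that("noiseless screening of the library is perfectly accurate", {
  spectra <- c(
    lapply(seq_along(lib), function(i)
      simulateSpectrum(lib[[i]], noiselessParams(seed = 100 + i))),
    lapply(1:10, function(i)
      simulateDecoy(spectrumSimParams(nNoisePeaks = 25, seed = 200 + i))))
  asn <- lapply(spectra, screenSpectrum, library = lib, config = cfg)
  named <- vapply(asn, function(a) verdict(a) == "named_ap", logical(1))
  expect_identical(sum(named), length(lib))  # recall 1, precision 1
  expect_setequal(vapply(asn[named], proposedName, character(1)),
                  names(lib))
})

test_that("screening is invariant to the input order", {
  fixture <- buildFractionFixture(seed = 55)
  rep1 <- screenFractions(fixture, lib, cfg)
  set.seed(3)
  rep2 <- screenFractions(sample(fixture), lib, cfg)
  expect_identical(reportTable(rep1), reportTable(rep2))
})

test_that("raising fragment dropout never increases named identifications", {
  params <- function(p) spectrumSimParams(mzSigma = 0.01, dropoutP = p,
                                          nNoisePeaks = 5, seed = NA)
  counts <- vapply(c(0, 0.3, 0.6, 0.9), function(p) {
    set.seed(41)
    sum(replicate(30, verdict(screenSpectrum(
      simulateSpectrum(lib[["AP B"]], params(p)), lib, cfg)) == "named_ap"))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], 30)
})

test_that("empty input produces an empty report", {
  rep <- screenFractions(list(), lib, cfg)
  expect_identical(nrow(reportTable(rep)), 0L)
  expect_length(distinctCompounds(rep), 0L)
})
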