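---
title: "Screening anabaenopeptins by diagnostic ions and quantifying enzyme inhibition"
author: "apscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening anabaenopeptins by diagnostic ions and quantifying enzyme inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apscreen)
```

## The problem

Cyanobacteria produce families of cyclic nonribosomal peptides whose
MS/MS spectra are recognizable from a handful of diagnostic fragment
ions rather than from database search.  Anabaenopeptins (APs) are cyclic
hexapeptides: five residues form a ring that always contains Lys, and a
sixth, exocyclic residue hangs off the ring through an ureido
(-NH-CO-NH-) bond.  Cyanopeptolins (CYPs) are depsipeptides recognized by
ions related to their conserved 3-amino-6-hydroxy-2-piperidone (Ahp)
residue.  `apscreen` implements the complete desk workflow for screening
solid-phase-extraction (SPE) fractions for these compounds and for
quantifying the protease / phosphatase inhibition of the same fractions
on 96-well plates.

## The mass model

All chemistry is monoisotopic (singly protonated species from a
triple-quadrupole / linear ion trap instrument); average masses are not
offered.  Residue masses are the amino acid minus water, shipped as a
versioned TSV (`residueTable()`) that validates each stated mass against
its elemental formula to within 1e-4 Da and that users can extend via
`setResidueTable()`.

The diagnostic ions are:

* **Lys marker, m/z 84.0808.**  The low-mass ion conventionally called
  the Lys immonium ion in AP work is the immonium after ammonia loss:
  residue − CO + proton − NH3.  The true Lys immonium (101.107) does not
  round to the reported 84; the ammonia-loss ion does.  `lysMarkerMz()`
  implements this reading.
* **Immonium ions** (`immoniumMz()`): residue − CO + proton, e.g. Phe at
  120.0808.
* **Arg diagnostics** (`argDiagnosticMzs()`): protonated free arginine
  at 175.119, and a carbamoyl-Arg-related ion stored as the empirical
  constant 201.1.  No single elemental composition reproduces 201.1
  (plausible carbamoyl-Arg compositions give 185.1 or 203.1), so the
  observed value is kept as a constant rather than derived.

An AP's neutral mass is assembled as ring residue sum + free exocyclic
amino acid + CO − H2 (`apNeutralMass()`): the ring is a cycle (no
terminal water), and the ureido bridge contributes a carbonyl while
costing two hydrogens.  The exocyclic residue announces itself as a
neutral loss from `[M + H]+` (`exocyclicLossMass()`):

* Arg-style (default for every residue except Tyr): free residue + CO −
  H2, i.e. the `[Arg + CO]` loss of 200.091 Da leaving the bare
  protonated ring (637.371 for the Lys-Val-Hty-MeAla-Phe ring).
* Tyr-style: the free amino acid alone (181.074 Da), leaving the ureido
  carbonyl on the charged fragment (663.350 for AP A).

These two rules make the complement ion (`exocyclicComplementMz()`)
well-defined for every scaffold, and `[M+H]+ = complement + loss` is an
exact identity the test suite checks over random scaffolds.

`predictFragments()` turns a scaffold into a deterministic fragment
list: precursor, loss complement (`ring_ion`), Lys marker, immonium ions
of all distinct residues, Arg diagnostics when Arg is present, and
b-ions of one canonical ring opening (at the Lys alpha-amide).  A single
canonical opening — not all five — keeps predicted spectra small and
reproducible; with a 0.5 Da matching tolerance additional openings would
add little discriminative power at these ring sizes.

## The screening procedure

`screenSpectrum()` applies the decision rules in order:

1. **Gate.**  No Lys marker ion within tolerance, no AP verdict of any
   kind.
2. **Named identification.**  Library compounds whose `[M + H]+` matches
   the precursor are scored as the fraction of predicted fragments
   (precursor excluded) found in the spectrum; the best score at or
   above `matchThreshold` wins.  Ties break by precursor proximity,
   then name, so output is deterministic.
3. **Novel analogs.**  Gated spectra with a recognized exocyclic loss
   (Δ200.091 or Δ181.074) but no library match are named
   `"AP <nominal neutral mass>"` (`novelName()`), e.g. a precursor at
   m/z 803 becomes AP 802.
4. **Ring fragments.**  Precursors matching a library ring ion (e.g.
   637) are reported as "AP fragment" rows.
5. **CYP-like flagging.**  Remaining spectra matching any configured
   Ahp-related diagnostic m/z are flagged `cyp_like`.

Defaults and why:

* **Tolerance 0.5 Da absolute** — the screening literature this models
  reports integer m/z, so half-a-unit windows capture the intent; a ppm
  mode exists for high-accuracy synthetic tests.
* **`matchThreshold` 0.6** — no quantitative criterion exists for
  "indicative of" an AP, so the threshold is explicit configuration; 0.6
  separates noiseless library spectra (score 1) from decoys (score 0)
  with a wide margin and still tolerates ~1/3 fragment dropout.
* **CYP diagnostics `c(215.14, 243.13)`** — no CYP diagnostic masses
  are fixed by the screening rules, so the defaults are Ahp-related ions
  used in the depsipeptide literature, chosen not to collide with the AP
  diagnostic set, and fully editable (`screenConfig()`).
* **Charge 1** — every screened species is `[M + H]+`.

`screenFractions()` aggregates per-spectrum verdicts into a fraction
report (fraction, nominal m/z, proposed name), collapsing duplicates and
sorting fractions by their numeric methanol percentage.

## Synthetic data: what it emulates and what it does not

`simulateSpectrum()` perturbs a predicted fragment list with per-fragment
dropout, Gaussian m/z jitter, lognormal intensities and uniform noise
peaks in the 50–1000 Da product-ion window; `simulateDecoy()` builds
pure-noise spectra guaranteed (by construction) to fail the gate;
`buildFractionFixture()` lays simulated spectra out over the 20–100%
methanol fractions in the arrangement of the reference screening table,
including novel-analog spectra at m/z 803/810/828 (gate ion plus the
Δ200 Arg-style loss — the loss supporting two of the three novel masses
is not recorded, so the generic rule is used uniformly) and unassigned
fragment-like spectra at m/z 752.  Defaults are m/z jitter 0.01 Da, 5%
dropout and 5 noise peaks per spectrum.

Intensities are arbitrary lognormal units: no intensity model is
derivable for the instrument counts the source data report, so nothing
here should be read as quantification.  The simulator also ignores
retention time, isotope envelopes and instrument resolution; passing
tests therefore demonstrate the *logic* of the rule set, not robustness
to chimeric spectra, co-elution or calibration drift in real data.

`simulatePlate()` generates well absorbances as
`A0 * (1 - inhibition(dose)) + N(0, sd)` with zero-inhibitor wells
included.  The default conditions are a 10–60 µg/mL dose series (the
aprotinin/trypsin standard series), A0 = 1 AU, noise SD 0.02 AU, two
replicate wells per dose and four zero-inhibitor wells.  Simulation
sizes used by the acceptance checks (200 plates per model, 10,000
decoys, 1,000 random scaffolds) keep the full suite under a minute on a
single core while leaving the binomial / Gaussian error of each check
well inside its asserted band.

## Inhibition quantification

Percent inhibition is `(A0 − AI) / A0` from mean zero-inhibitor and
sample absorbances.  The printed form of this equation is typographically
ambiguous ("A0 − AI/A0"); the whole-difference reading is used because it
alone gives 0 at AI = A0 and 1 at AI = 0.  Values outside [0, 1] are
retained, not clipped — they signal assay problems and should inflate
the error statistic honestly.

Dose–response curves are least-squares fits of inhibition on dose
(`linear`), log10 dose (`loglinear` — the base is a choice; log10 reads
naturally for dilution series), or dose and dose² (`quadratic`).  Model
accuracy is the **mean percent relative error (MRE)** between measured
and back-calculated inhibition; `selectModel()` picks the smallest MRE
with effective ties (1e-9) going to the simpler model, so clean linear
data select `linear` even though the quadratic fit is equally exact.
Points with measured inhibition exactly 0 carry no relative scale and
are excluded from the MRE.

`ic50()` solves the fitted curve for 50% inhibition by interpolation
only; curves that never attain 0.5 inside the fitted dose range raise a
distinct `undefinedIc50Error` (the graceful refusal needed for
negative or flat dose–response data), and extrapolation is available
only on request, with a warning.  For quadratic fits the root inside the
data range is used, the smaller if both qualify.

Relative potency is reported as `100 × IC50_standard / IC50_fraction` by
default, so a fraction needing more material than the standard scores
below 100%; because the opposite convention is equally defensible, the
direction is an argument and the output column is named after it.

`significanceFlag()` marks a fraction significant when its mean
inhibition falls outside the t-based 95% confidence interval of the
across-fraction mean, computed from the per-fraction means pooled per
enzyme.  The reference population for this interval is a genuine design
choice (per-plate and per-enzyme pooling are both defensible);
per-enzyme pooling was chosen because fractions on the same enzyme share
the assay context that makes their means comparable.  Groups with fewer
than two replicate values, or designs with fewer than two usable groups,
return `NA` rather than a flag.

## A worked example

```{r example}
lib <- apLibrary()
vapply(lib, function(c) nominalMz(protonate(apNeutralMass(c))), numeric(1))

report <- screenFractions(buildFractionFixture(seed = 101))
distinctCompounds(report)
compoundFractions(report, "AP A")

plate <- simulatePlate(plateSimParams(noiseSd = 0.02, seed = 7),
                       enzyme = "trypsin", sample = "aprotinin")
plateIc50(plate, "linear")
```

## Known limitations

* Structures are *proposed*: fragment-rule matching cannot fix residue
  order or stereochemistry, and confirmation requires orthogonal
  techniques.  Novel-analog names encode only a nominal mass.
* CYP support is detection-only; no depsipeptide mass assembly or
  ester-bond fragmentation chemistry is modelled.
* Only singly charged, monoisotopic chemistry is handled — no isotope
  patterns, multiply charged species, or profile-mode data.
* The screener treats each spectrum independently; co-eluting mixtures
  and chimeric spectra are out of scope.
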