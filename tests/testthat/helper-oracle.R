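# Independent mass oracle: atomic masses typed from the NIST tabulation
# (more digits than the package's table) and residue compositions entered
# as count vectors, so oracle sums share no code path with formulaMass().
.oracleElements <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                     O = 15.9949146196, S = 31.97207100)
.oracleProton <- 1.007276466879

.oracleComp <- list(
  G     = c(C = 2,  H = 3,  N = 1, O = 1),
  V     = c(C = 5,  H = 9,  N = 1, O = 1),
  K     = c(C = 6,  H = 12, N = 2, O = 1),
  F     = c(C = 9,  H = 9,  N = 1, O = 1),
  R     = c(C = 6,  H = 12, N = 4, O = 1),
  Y     = c(C = 9,  H = 9,  N = 1, O = 2),
  Ile   = c(C = 6,  H = 11, N = 1, O = 1),
  Hty   = c(C = 10, H = 11, N = 1, O = 2),
  MeAla = c(C = 4,  H = 7,  N = 1, O = 1))

oracleResidueMass <- function(code) {
  vapply(code, function(cd) {
    counts <- .oracleComp[[cd]]
    sum(.oracleElements[names(counts)] * counts)
  }, numeric(1))
}

# a random valid scaffold (ring starts with the conserved Lys)
randomScaffold <- function(exocyclicPool = NULL) {
  codes <- residueTable()$code
  ring <- c("K", sample(codes, 4, replace = TRUE))
  exo <- if (is.null(exocyclicPool)) sample(codes, 1)
         else sample(exocyclicPool, 1)
  APCompound(sprintf("rand_%06d", sample.int(1e6, 1)), ring, exo, "novel")
}

# noiseless simulation parameters (degenerate: predicted peaks exactly)
noiselessParams <- function(seed = NA) {
  spectrumSimParams(mzSigma = 0, dropoutP = 0, nNoisePeaks = 0,
                    seed = seed)
}
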