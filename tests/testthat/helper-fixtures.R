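# small deterministic fixtures built in code

toyCounts <- function(nGenes = 5, nCells = 8, seed = 1, lambda = 2) {
  set.seed(seed)
  matrix(rpois(nGenes * nCells, lambda), nGenes, nCells,
         dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                         sprintf("c%02d", seq_len(nCells))))
}

toyExperiment <- function(nGenes = 5, nCells = 8, seed = 1, lambda = 2,
                          types = NULL) {
  m <- toyCounts(nGenes, nCells, seed, lambda)
  if (is.null(types)) {
    types <- rep(c("excitatory", "inhibitory"), length.out = nCells)
  }
  SenescenceExperiment(m, types)
}

smallConfig <- function(...) {
  syntheticConfig(nCells = 400, nGenes = 700,
                  panelSizes = c(CSP = 8, SIP = 10, SenMayo = 15),
                  nDeGenes = 30, ...)
}

# greedy 1-D earth mover between two equal-mass histograms: move mass
# left-to-right, accumulating |flow| across each bin boundary
greedyEmd <- function(h1, h0) {
  f1 <- h1 / sum(h1)
  f0 <- h0 / sum(h0)
  carry <- 0
  cost <- 0
  for (b in seq_along(f1)) {
    carry <- carry + f1[b] - f0[b]
    cost <- cost + abs(carry)
  }
  cost
}
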