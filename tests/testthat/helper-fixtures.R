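# Shared fixtures: a hand-picked micro corpus for cheap unit tests, a
# desk-scale model configuration, and memoised fixture corpora (the
# combinatorial pool itself is memoised inside the package).

tinyCorpus <- c("CCO", "CCN", "CCC", "COC", "C=O", "C#N", "c1ccccc1",
                "CC(C)O", "CCOC", "CC=O")

deskConfig <- function(dropout = 0) {
  modelConfig(nLayers = 2L, hiddenDim = 32L, ffnDim = 64L,
              encoderGatHeads = 1L, decoderHeads = 4L, latentDim = 16L,
              dropout = dropout)
}

.testEnv <- new.env(parent = emptyenv())

fixtureCorpus <- function(n, seed = 11L) {
  key <- paste0("fc_", n, "_", seed)
  if (is.null(.testEnv[[key]]))
    .testEnv[[key]] <- generateFixtureCorpus(n, seed = seed)
  .testEnv[[key]]
}

# a small untrained model over the micro corpus, built once
tinyModel <- function() {
  if (is.null(.testEnv$tinyModel))
    .testEnv$tinyModel <- graphVAE(tinyCorpus, deskConfig(), seed = 3L)
  .testEnv$tinyModel
}

# relabel a graph's nodes by a permutation (with consistent edge index)
permuteGraph <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  new("MolecularGraph",
      nodeSymbols = nodeSymbols(g)[perm],
      edgeIndex = matrix(inv[edgeIndex(g) + 1L] - 1L, nrow = 2),
      edgeTypes = edgeTypes(g),
      nNodes = nNodes(g))
}
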