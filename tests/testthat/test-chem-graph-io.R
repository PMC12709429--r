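# SMILES parsing, canonicalization, graph conversion, tokenization,
# vocabulary and the corpus filter.

test_that("canonicalization is unique, idempotent, and rejects bad input", {
  expect_identical(canonicalizeSmiles("OCC"), canonicalizeSmiles("CCO"))
  can <- canonicalizeSmiles("CCO")
  expect_identical(canonicalizeSmiles(can), can)
  expect_error(canonicalizeSmiles("C1CC"), class = "invalidMoleculeError")
  expect_identical(canonicalizeSmiles(c("OCC", "C1CC"), onInvalid = "na")[2],
                   NA_character_)
  expect_false(isValidSmiles("C1CC"))
})

test_that("stereochemistry is stripped before canonicalization", {
  expect_identical(canonicalizeSmiles("C[C@@H](N)C(=O)O"),
                   canonicalizeSmiles("CC(N)C(=O)O"))
  expect_identical(canonicalizeSmiles("F/C=C/F"), canonicalizeSmiles("FC=CF"))
})

test_that("graph conversion follows the three-matrix encoding", {
  g <- smilesToGraph("C")
  expect_identical(nNodes(g), 1L)
  expect_identical(ncol(edgeIndex(g)), 0L)
  expect_length(edgeTypes(g), 0L)

  g <- smilesToGraph("CC")
  expect_identical(nNodes(g), 2L)
  cols <- apply(edgeIndex(g), 2, paste, collapse = ",")
  expect_setequal(cols, c("0,1", "1,0"))
  expect_identical(edgeTypes(g), c(0L, 0L))

  g <- smilesToGraph("C#N")
  expect_true(all(edgeTypes(g) == 2L))

  g <- smilesToGraph("c1ccccc1")
  expect_identical(nNodes(g), 6L)
  expect_identical(ncol(edgeIndex(g)), 12L)
  expect_true(all(edgeTypes(g) == 3L))

  expect_error(smilesToGraph("C1CC"), class = "invalidMoleculeError")
})

test_that("kekulized aromatic input converts to code-3 bonds", {
  g <- smilesToGraph("C1=CC=CC=C1")
  expect_true(all(edgeTypes(g) == 3L))
})

test_that("graph invariants and round trip hold on a fixture sample", {
  corpus <- fixtureCorpus(60)
  graphs <- smilesToGraphs(corpus)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    expect_true(validObject(g))               # edge range, symmetry, codes
    expect_identical(graphToSmiles(g), corpus[i])
  }
})

test_that("tokenizer treats multi-character units atomically and round-trips", {
  expect_identical(smilesTokens("CCl"), c("C", "Cl"))
  expect_identical(smilesTokens("BrCC%12"), c("Br", "C", "C", "%12"))
  expect_identical(smilesTokens("C[nH]1cccc1"),
                   c("C", "[nH]", "1", "c", "c", "c", "c", "1"))
  corpus <- fixtureCorpus(100)
  vocab <- buildVocabulary(corpus)
  ids <- tokenizeSmiles(corpus, vocab)
  for (i in seq_along(corpus)) {
    expect_identical(detokenizeSmiles(ids[[i]], vocab), corpus[i])
    expect_true(MolGraphVAE:::isWellFormedTokenSequence(ids[[i]]))
  }
})

test_that("vocabulary is order-independent, covers its corpus, errors when empty", {
  v1 <- buildVocabulary(c("CC", "CCO"))
  v2 <- buildVocabulary(c("CCO", "CC"))
  expect_identical(vocabTokens(v1), vocabTokens(v2))
  expect_identical(vocabTokens(buildVocabulary("CC")),
                   c("<pad>", "<bos>", "<eos>", "<unk>", "C"))
  expect_error(buildVocabulary(character(0)))

  corpus <- fixtureCorpus(100)
  vocab <- buildVocabulary(corpus)
  unk <- MolGraphVAE:::.UNK_ID
  expect_false(any(vapply(tokenizeSmiles(corpus, vocab),
                          function(x) any(x == unk), TRUE)))
  # out-of-vocabulary tokens map to <unk> with a warning
  expect_warning(ids <- tokenizeSmiles("CI", buildVocabulary("CC")))
  expect_true(any(ids[[1]] == unk))
})

test_that("corpus filter enforces each admission rule", {
  passing <- fixtureCorpus(5)
  expect_true(all(corpusFilter(passing)))

  wide <- corpusFilterRule(mwMin = 1, mwMax = 1e4, maxRotatableBonds = 999L,
                           maxLogP = 999)
  expect_true(corpusFilter("CCO", wide))
  # molecular weight window
  expect_false(corpusFilter("CCO"))                       # MW 46 < 250
  expect_false(corpusFilter(strrep("C", 40)))             # MW > 350, logP cap too
  # charged atoms
  expect_false(corpusFilter("C[N+](C)(C)C", wide))
  expect_true(corpusFilter("C[N+](C)(C)C",
                           corpusFilterRule(mwMin = 1, mwMax = 1e4,
                                            maxRotatableBonds = 999L,
                                            maxLogP = 999,
                                            allowCharged = TRUE)))
  # ring size: cyclononane has a 9-ring
  expect_false(corpusFilter("C1CCCCCCCC1", wide))
  expect_true(corpusFilter("C1CCCCCCC1", wide))           # 8-ring passes
  # element set
  expect_false(corpusFilter("CCI", wide))                 # iodine not allowed
  # rotatable bonds
  tight <- corpusFilterRule(mwMin = 1, mwMax = 1e4, maxRotatableBonds = 1L,
                            maxLogP = 999)
  expect_false(corpusFilter("CCCCCC", tight))
  # logP cap
  lipo <- corpusFilterRule(mwMin = 1, mwMax = 1e4, maxRotatableBonds = 999L,
                           maxLogP = 1)
  expect_false(corpusFilter("CCCCCCCCCC", lipo))
  # invalid input signals the classed error
  expect_error(corpusFilter("C1CC"), class = "invalidMoleculeError")
})

test_that("ring-size detection sees through fused systems", {
  expect_identical(largestRingSize(smilesToGraph("C1CCCCCCCC1")), 9L)
  expect_identical(largestRingSize(smilesToGraph("C1CCC2CCCCC2C1")), 6L)
  expect_identical(largestRingSize(smilesToGraph("CCO")), 0L)
})

test_that("fixture generator is seeded, distinct, valid and filter-clean", {
  a <- generateFixtureCorpus(10, seed = 7)
  b <- generateFixtureCorpus(10, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generateFixtureCorpus(10, seed = 8)))
  big <- fixtureCorpus(100)
  expect_identical(anyDuplicated(big), 0L)
  expect_true(all(isValidSmiles(big)))
  expect_identical(canonicalizeSmiles(big), big)   # emitted canonical
  expect_true(all(corpusFilter(big)))
  expect_error(generateFixtureCorpus(1e6), regexp = "enumerate")
})

test_that("corpus files round-trip in both dialects", {
  smiles <- fixtureCorpus(10)
  txt <- tempfile(fileext = ".smi")
  writeSmilesCorpus(smiles, txt)
  expect_identical(readSmilesCorpus(txt), smiles)
  csv <- tempfile(fileext = ".csv")
  writeSmilesCorpus(smiles, csv, split = "train")
  expect_identical(readSmilesCorpus(csv, split = "train"), smiles)
  vpath <- tempfile(fileext = ".json")
  v <- buildVocabulary(smiles)
  writeVocabulary(v, vpath)
  expect_identical(vocabTokens(readVocabulary(vpath)), vocabTokens(v))
})
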