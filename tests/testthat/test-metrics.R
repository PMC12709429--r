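# Generation-quality metrics: validity, Unique@K, novelty, Tanimoto /
# internal diversity (with brute-force oracle), Bemis-Murcko scaffolds,
# scaffold cosine similarity, Wasserstein distance, full report assembly.

test_that("validity fraction counts parseable molecules and keeps the subset", {
  expect_equal(validityFraction(c("CCO", "C1CC1"))$validity, 1.0)
  vf <- validityFraction(c("CCO", "C1CC"))
  expect_equal(vf$validity, 0.5)
  expect_identical(vf$validSubset, canonicalizeSmiles("CCO"))
  expect_error(validityFraction(character(0)), regexp = "empty")
})

test_that("Unique@K follows the first-K rule and its fallback", {
  expect_equal(uniqueAtK(rep("CCO", 10), K = 10), 0.1)
  five <- canonicalizeSmiles(c("CCO", "CCN", "CCC", "COC", "CC=O"))
  expect_equal(uniqueAtK(five, K = 10000), 1.0)   # fewer than K: use all
  expect_equal(uniqueAtK(c(five, five), K = 10), 0.5)
  expect_error(uniqueAtK(character(0), K = 10), regexp = "valid")
})

test_that("novelty is the fraction absent from the training set", {
  train <- c("CCO", "CCN")
  expect_equal(novelty(canonicalizeSmiles(train), train), 0.0)
  expect_equal(novelty(canonicalizeSmiles(c("CCC", "COC")), train), 1.0)
  expect_equal(novelty(canonicalizeSmiles(c("CCO", "CCC")), train), 0.5)
  # spelling-invariance: a respelled training molecule is not novel
  expect_equal(novelty(canonicalizeSmiles("OCC"), "CCO"), 0.0)
})

test_that("Tanimoto similarity is reflexive, symmetric and bounded", {
  expect_equal(tanimotoSimilarity("CCO", "CCO"), 1.0)
  expect_equal(tanimotoSimilarity("CCO", "OCC"), 1.0)   # same molecule
  corpus <- fixtureCorpus(20)
  set.seed(8)
  for (k in 1:25) {
    pair <- sample(corpus, 2)
    tab <- tanimotoSimilarity(pair[1], pair[2])
    tba <- tanimotoSimilarity(pair[2], pair[1])
    expect_identical(tab, tba)
    expect_gte(tab, 0); expect_lte(tab, 1)
  }
  expect_error(tanimotoSimilarity("C1CC", "CCO"),
               class = "invalidMoleculeError")
})

test_that("internal diversity matches the brute-force double loop", {
  expect_equal(internalDiversity(c("CCO", "CCO"), p = 1), 0.0)
  corpus <- fixtureCorpus(20)
  for (p in c(1, 2)) {
    got <- internalDiversity(corpus, p = p)
    acc <- 0
    for (i in seq_along(corpus))
      for (j in seq_along(corpus))
        acc <- acc + tanimotoSimilarity(corpus[i], corpus[j])^p
    expect_equal(got, 1 - acc / length(corpus)^2, tolerance = 1e-10)
    expect_gte(got, 0); expect_lte(got, 1)
  }
  # off-diagonal variant excludes self-pairs
  d1 <- internalDiversity(corpus[1:5], p = 1, includeSelfPairs = FALSE)
  acc <- 0
  for (i in 1:5) for (j in 1:5) if (i != j)
    acc <- acc + tanimotoSimilarity(corpus[i], corpus[j])
  expect_equal(d1, 1 - acc / 20, tolerance = 1e-10)
})

test_that("Bemis-Murcko scaffolds keep frameworks and drop side chains", {
  benzene <- canonicalizeSmiles("c1ccccc1")
  expect_identical(murckoScaffold("c1ccccc1"), benzene)
  expect_identical(murckoScaffold("Cc1ccccc1"), benzene)          # toluene
  expect_identical(murckoScaffold("CCc1ccc(C)cc1"), benzene)
  expect_identical(murckoScaffold("CCO"), "")                     # acyclic
  # linker carbonyl oxygen is retained (double bond to the framework)
  expect_identical(murckoScaffold("O=C(c1ccccc1)c1ccccc1"),
                   canonicalizeSmiles("O=C(c1ccccc1)c1ccccc1"))
  # but a side-chain acetyl is removed entirely
  expect_identical(murckoScaffold("CC(=O)c1ccccc1"), benzene)
  # ring-linker-ring framework survives with its linker
  expect_identical(murckoScaffold("Cc1ccc(CCc2ccccc2)cc1"),
                   canonicalizeSmiles("c1ccc(CCc2ccccc2)cc1"))
})

test_that("scaffold similarity reproduces identities and a hand cosine", {
  A <- c("Cc1ccccc1", "CCc1ccccc1", "Cc1ccncc1")
  expect_equal(scaffoldSimilarity(A, A), 1.0)
  # disjoint scaffold universes score zero
  expect_equal(scaffoldSimilarity(c("Cc1ccccc1"), c("CC1CCCC1")), 0.0)
  # counts (2,1) vs (1,1): cos = 3 / (sqrt(5) sqrt(2))
  G <- c("Cc1ccccc1", "CCc1ccccc1", "Cc1ccncc1")
  R <- c("CCCc1ccccc1", "CCc1ccncc1")
  expect_equal(scaffoldSimilarity(G, R), 3 / sqrt(10), tolerance = 1e-6)
  expect_equal(scaffoldSimilarity(G, R), scaffoldSimilarity(R, G))
  # acyclic-only sets have no scaffold vector: defined as 0, with a message
  expect_message(s0 <- scaffoldSimilarity("CCO", "CCN"), regexp = "0")
  expect_equal(s0, 0)
})

test_that("Wasserstein distance matches the sorted-sample oracle", {
  expect_equal(wasserstein1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein1d(0, 5), 5)       # Dirac pair
  set.seed(12)
  for (k in 1:10) {
    a <- rnorm(40, sd = 2); b <- rnorm(40, mean = 1)
    # equal-size samples: W1 = mean |sorted a - sorted b|
    expect_equal(wasserstein1d(a, b), mean(abs(sort(a) - sort(b))),
                 tolerance = 1e-12)
    expect_equal(wasserstein1d(a, b), wasserstein1d(b, a))
  }
  a <- runif(30); b <- runif(17)   # unequal sizes still symmetric, >= 0
  expect_equal(wasserstein1d(a, b), wasserstein1d(b, a))
  expect_gte(wasserstein1d(a, b), 0)
  expect_error(wasserstein1d(numeric(0), 1), regexp = "empty")
})

test_that("property profile reports standard descriptors", {
  pp <- propertyProfile(c("CCO", "C1CC"))
  expect_identical(pp$valid, c(TRUE, FALSE))
  expect_equal(pp$MW[1], 46.07, tolerance = 0.01)
  expect_equal(pp$HBD[1], 1)
  expect_gte(pp$HBA[1], 1)
  expect_equal(pp$NHOH[1], 1)
  expect_identical(pp$heavyAtoms[1], 3L)
  expect_true(is.na(pp$MW[2]))
  expect_true(pp$QED[1] > 0 && pp$QED[1] < 1)
  expect_true(pp$SA[1] >= 1 && pp$SA[1] <= 10)
})

test_that("the assembled report reproduces composition identities", {
  S <- fixtureCorpus(15)
  m <- evaluateGeneration(S, train = S, test = S, scaffoldTest = NULL,
                          K = 10L)
  expect_equal(m@validity, 1.0)
  expect_equal(m@novelty, 0.0)
  expect_equal(m@uniqueAtK, 1.0)
  expect_equal(unname(m@scaffoldSimilarity["Test"]), 1.0)
  expect_true(all(m@propertyDistances < 1e-12))
  expect_true(m@intDiv1 >= 0 && m@intDiv1 <= 1)
  expect_true(m@intDiv2 >= 0 && m@intDiv2 <= 1)
  m2 <- evaluateGeneration(S, train = S, test = S, K = 10L)
  expect_equal(m@intDiv1, m2@intDiv1)   # determinism
  # report serialisation
  path <- tempfile(fileext = ".json")
  writeMetricsReport(m, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$validity, 1.0)
  expect_equal(obj$novelty, 0.0)
})
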