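# Encoder/decoder contracts: shape and finiteness, permutation invariance,
# batch independence, reparameterization, causality, seeded generation,
# and a full-loss gradient check against finite differences.

test_that("encoding degenerate and batched inputs is well-behaved", {
  m <- tinyModel()
  d <- encodeGraphs(m, "C")   # single atom, no bonds
  expect_identical(dim(latentMu(d)), c(1L, 16L))
  expect_true(all(is.finite(latentMu(d))))
  expect_true(all(is.finite(latentLogSigma(d))))
  expect_error(encodeGraphs(m, list()), regexp = "empty")

  db <- encodeGraphs(m, tinyCorpus[1:3])
  for (i in 1:3) {
    ds <- encodeGraphs(m, tinyCorpus[i])
    expect_equal(latentMu(db)[i, ], latentMu(ds)[1, ], tolerance = 1e-10)
  }
})

test_that("encoder output is invariant to node relabeling", {
  m <- tinyModel()
  set.seed(42)
  for (s in tinyCorpus) {
    g <- smilesToGraph(s)
    if (nNodes(g) < 2L) next
    perm <- sample(nNodes(g))
    d1 <- encodeGraphs(m, list(g))
    d2 <- encodeGraphs(m, list(permuteGraph(g, perm)))
    expect_equal(latentMu(d1), latentMu(d2), tolerance = 1e-6)
    expect_equal(latentLogSigma(d1), latentLogSigma(d2), tolerance = 1e-6)
  }
})

test_that("reparameterization matches z = mu + eps * sigma", {
  d <- new("LatentDistribution", mu = matrix(c(1, 2, 3), 1),
           logSigma = matrix(log(c(1, 2, 0.5)), 1))
  expect_equal(reparameterize(d, matrix(0, 1, 3)), matrix(c(1, 2, 3), 1))
  d0 <- new("LatentDistribution", mu = matrix(0, 1, 3),
            logSigma = matrix(0, 1, 3))
  eps <- matrix(c(-1, 0.5, 2), 1)
  expect_equal(reparameterize(d0, eps), eps)
  expect_error(reparameterize(d, matrix(0, 1, 2)), regexp = "shape")

  # Monte-Carlo moments: mean/SD of z match (mu, sigma) within 3 SE
  set.seed(7)
  n <- 10000
  mu <- 1.3; sigma <- 0.7
  dm <- new("LatentDistribution", mu = matrix(mu, n, 1),
            logSigma = matrix(log(sigma), n, 1))
  z <- reparameterize(dm, matrix(rnorm(n), n, 1))
  expect_lt(abs(mean(z) - mu), 3 * sigma / sqrt(n))
  expect_lt(abs(sd(z) - sigma), 3 * sigma / sqrt(2 * (n - 1)))
})

test_that("prior samples are seeded standard normal", {
  m <- tinyModel()
  expect_identical(priorSample(m, 3, seed = 1), priorSample(m, 3, seed = 1))
  z <- priorSample(m, 10000, seed = 2)
  expect_identical(dim(z), c(10000L, 16L))
  se <- 1 / sqrt(nrow(z))
  expect_true(all(abs(colMeans(z)) < 3 * se))
  expect_true(all(abs(apply(z, 2, var) - 1) < 3 * sqrt(2 / (nrow(z) - 1))))
})

test_that("teacher-forced decoding is causal, deterministic and finite", {
  m <- tinyModel()
  tok <- MolGraphVAE:::padTokenMatrix(tokenizeSmiles(tinyCorpus[1:2], m@vocab))
  z <- latentMu(encodeGraphs(m, tinyCorpus[1:2]))
  lg <- decodeTeacherForced(m, z, tok)
  expect_identical(dim(lg), c(2L, ncol(tok) - 1L, vocabSize(m@vocab)))
  expect_true(all(is.finite(lg)))
  expect_identical(decodeTeacherForced(m, z, tok), lg)
  # perturbing the target at position t leaves logits at positions <= t alone
  for (t in 2:4) {
    tok2 <- tok
    tok2[1, t] <- 5L
    lg2 <- decodeTeacherForced(m, z, tok2)
    expect_identical(lg2[1, seq_len(t - 1), ], lg[1, seq_len(t - 1), ])
    expect_gt(max(abs(lg2[1, t, ] - lg[1, t, ])), 0)
  }
  # sequences must be BOS-led and fit in maxLen
  badTok <- tok; badTok[, 1] <- 5L
  expect_error(decodeTeacherForced(m, z, badTok), regexp = "begin")
  longTok <- matrix(MolGraphVAE:::.BOS_ID, 1, m@config@maxLen + 2L)
  expect_error(decodeTeacherForced(m, latentMu(encodeGraphs(m, "C")), longTok),
               regexp = "maxLen")
})

test_that("generation is reproducible per mode and respects maxLen", {
  m <- tinyModel()
  z <- priorSample(m, 4, seed = 5)
  g1 <- generateMolecules(m, z, mode = "greedy")
  g2 <- generateMolecules(m, z, mode = "greedy")
  expect_identical(g1, g2)
  s1 <- generateMolecules(m, z, mode = "sample", seed = 9)
  s2 <- generateMolecules(m, z, mode = "sample", seed = 9)
  expect_identical(s1, s2)
  expect_false(identical(s1, generateMolecules(m, z, mode = "sample", seed = 10)))
  capped <- generateMolecules(m, z, mode = "sample", seed = 9, maxLen = 5L)
  expect_true(all(nchar(capped$smiles) <= 5))
  expect_length(capped$truncated, 4L)
})

test_that("dense connections give layer 1 a nonzero gradient path", {
  m <- tinyModel()
  ps <- MolGraphVAE:::newParamStore(m@params)
  bg <- MolGraphVAE:::.batchGraphs(smilesToGraphs(tinyCorpus[1:4]),
                                   m@atomSymbols)
  tape <- MolGraphVAE:::agTape()
  enc <- MolGraphVAE:::.encoderForward(tape, ps, bg, m@config)
  kl <- MolGraphVAE:::agKLStd(tape, enc$mu, enc$logSigma)
  grads <- MolGraphVAE:::agBackward(tape, kl)
  g1 <- grads[["enc.1.gat1.W1"]]
  expect_false(is.null(g1))
  expect_gt(sqrt(sum(g1^2)), 0)
})

test_that("over-smoothing probe: dense connections lower node-state similarity", {
  # property of the architecture at initialisation; reported, not hard-failed
  m <- tinyModel()
  ps <- MolGraphVAE:::newParamStore(m@params)
  bg <- MolGraphVAE:::.batchGraphs(smilesToGraphs(tinyCorpus), m@atomSymbols)
  meanCos <- function(dense) {
    tape <- MolGraphVAE:::agTape()
    enc <- MolGraphVAE:::.encoderForward(tape, ps, bg, m@config,
                                         denseConnections = dense)
    H <- enc$nodeStates$value
    vals <- c()
    for (b in unique(bg$gid)) {
      X <- H[bg$gid == b, , drop = FALSE]
      if (nrow(X) < 2) next
      Xn <- X / sqrt(rowSums(X^2))
      C <- Xn %*% t(Xn)
      vals <- c(vals, mean(C[upper.tri(C)]))
    }
    mean(vals)
  }
  withDense <- meanCos(TRUE)
  withoutDense <- meanCos(FALSE)
  message(sprintf("over-smoothing probe: mean pairwise cosine %.4f (dense) vs %.4f (ablated)",
                  withDense, withoutDense))
  expect_true(is.finite(withDense) && is.finite(withoutDense))
})

test_that("full-loss gradients agree with finite differences", {
  corpus <- c("CCO", "C=O", "CCN")
  cfg <- modelConfig(nLayers = 1L, hiddenDim = 8L, ffnDim = 12L,
                     encoderGatHeads = 2L, decoderHeads = 2L, latentDim = 4L,
                     dropout = 0)
  m <- graphVAE(corpus, cfg, seed = 2)
  graphs <- smilesToGraphs(corpus)
  tokAll <- MolGraphVAE:::padTokenMatrix(tokenizeSmiles(corpus, m@vocab))
  eps <- matrix(0.3, 3, cfg@latentDim)
  lossAt <- function(params) {
    ps <- MolGraphVAE:::newParamStore(params)
    bg <- MolGraphVAE:::.batchGraphs(graphs, m@atomSymbols)
    tape <- MolGraphVAE:::agTape()
    enc <- MolGraphVAE:::.encoderForward(tape, ps, bg, cfg)
    z <- MolGraphVAE:::agAdd(tape, enc$mu,
           MolGraphVAE:::agMul(tape, MolGraphVAE:::agConst(tape, eps),
                               MolGraphVAE:::agExp(tape, enc$logSigma)))
    tok <- tokAll[, -ncol(tokAll), drop = FALSE]
    tgt <- tokAll[, -1, drop = FALSE]
    logits <- MolGraphVAE:::.decoderForward(tape, ps, z, tok, cfg)
    tgtvec <- as.vector(t(tgt))
    w <- as.numeric(tgtvec != MolGraphVAE:::.PAD_ID) / 3
    recon <- MolGraphVAE:::agSoftmaxCE(tape, logits, tgtvec, w)
    kl <- MolGraphVAE:::agScalarMul(tape,
            MolGraphVAE:::agKLStd(tape, enc$mu, enc$logSigma), 1 / 3)
    list(tape = tape, loss = MolGraphVAE:::agAxpy(tape, recon, kl, 1, 0.01))
  }
  r <- lossAt(m@params)
  grads <- MolGraphVAE:::agBackward(r$tape, r$loss)
  set.seed(4)
  checkNames <- c("atomEmb", "edgeEmb", "tokEmb", "enc.1.gat1.W1",
                  "enc.1.gat2.aEdge2", "enc.1.ffn.W1", "sigma.W", "mu.W",
                  "dec.memW", "dec.1.self.Wq", "dec.1.cross.Wk",
                  "dec.1.ffn.ln.g", "out.W", "out.b")
  h <- 1e-5
  for (nm in checkNames) {
    w <- m@params[[nm]]
    i <- sample(length(w), 1L)
    p1 <- m@params; p1[[nm]][i] <- p1[[nm]][i] + h
    p2 <- m@params; p2[[nm]][i] <- p2[[nm]][i] - h
    num <- (as.numeric(lossAt(p1)$loss$value) -
            as.numeric(lossAt(p2)$loss$value)) / (2 * h)
    ana <- if (is.null(grads[[nm]])) 0 else grads[[nm]][i]
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})
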