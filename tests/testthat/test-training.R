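# Optimisation loop: reproducibility, learning, checkpoint round trip,
# schedule continuation on resume.

deskTrain <- function(epochs, seed = 5L) {
  trainConfig(epochs = epochs, batchSize = 8L, seed = seed,
              learningRate = 1e-3)
}

test_that("identical seed and config give identical training logs", {
  r1 <- fit(tinyCorpus, deskConfig(dropout = 0.1), deskTrain(4L))
  r2 <- fit(tinyCorpus, deskConfig(dropout = 0.1), deskTrain(4L))
  expect_identical(r1$log, r2$log)
  expect_identical(r1$model@params, r2$model@params)
  r3 <- fit(tinyCorpus, deskConfig(dropout = 0.1), deskTrain(4L, seed = 6L))
  expect_false(identical(r1$log$total, r3$log$total))
})

test_that("training reduces the loss and logs every component", {
  r <- fit(tinyCorpus, deskConfig(), deskTrain(25L))
  expect_named(r$log, c("epoch", "beta", "kl", "recon", "total"))
  expect_identical(nrow(r$log), 25L)
  expect_lt(r$log$total[25], r$log$total[1])
  expect_true(all(is.finite(unlist(r$log))))
  expect_equal(r$log$total, r$log$beta * r$log$kl + r$log$recon,
               tolerance = 1e-12)
  expect_true(r$bestEpoch >= 1L && r$bestEpoch <= 25L)
  expect_equal(min(r$log$total), r$log$total[r$bestEpoch])
})

test_that("unparseable corpus molecules abort with their index", {
  expect_error(fit(c("CCO", "C1CC", "CCN"), deskConfig(), deskTrain(1L)),
               regexp = "index: 2")
})

test_that("checkpoints round-trip to identical generation", {
  r <- fit(tinyCorpus, deskConfig(), deskTrain(5L))
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(r, path)
  lk <- loadCheckpoint(path)
  expect_identical(lk$model@params, r$model@params)
  expect_identical(vocabTokens(lk$model@vocab), vocabTokens(r$model@vocab))
  expect_identical(lk$model@seed, r$model@seed)
  expect_identical(lk$epochsDone, 5L)
  g1 <- generateSet(r$model, n = 20, seed = 77)
  g2 <- generateSet(path, n = 20, seed = 77)
  expect_identical(g1, g2)
  expect_length(g1, 20L)
  # corrupt checkpoints are reported as such
  bad <- tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bad)
  expect_error(loadCheckpoint(bad), regexp = "corrupt")
})

test_that("resumed training continues the beta schedule at the right step", {
  sched <- betaSchedule("monotonic", totalSteps = 9L)
  tcA <- trainConfig(epochs = 4L, batchSize = 8L, seed = 5L,
                     learningRate = 1e-3, schedule = sched)
  tcB <- trainConfig(epochs = 10L, batchSize = 8L, seed = 5L,
                     learningRate = 1e-3, schedule = sched)
  rA <- fit(tinyCorpus, deskConfig(), tcA)
  rB <- fit(tinyCorpus, deskConfig(), tcB, resume = rA)
  expect_identical(nrow(rB$log), 10L)
  expect_equal(rB$log$beta,
               vapply(0:9, function(s) betaAt(sched, s), 0))
  expect_identical(rB$log$epoch, 1:10)
})

test_that("generated sets are seeded and sized exactly", {
  r <- fit(tinyCorpus, deskConfig(), deskTrain(3L))
  a <- generateSet(r$model, n = 30, seed = 4, chunkSize = 7L)
  b <- generateSet(r$model, n = 30, seed = 4, chunkSize = 7L)
  expect_identical(a, b)
  expect_length(a, 30L)
  expect_false(identical(a, generateSet(r$model, n = 30, seed = 5,
                                        chunkSize = 7L)))
})
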