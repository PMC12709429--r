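# The ELBO pieces: closed-form KL, reconstruction NLL, beta schedule and
# loss assembly.

test_that("closed-form KL matches hand-derived values", {
  d <- new("LatentDistribution", mu = matrix(0, 1, 8), logSigma = matrix(0, 1, 8))
  expect_identical(klDivergence(d), 0)
  d <- new("LatentDistribution", mu = matrix(1), logSigma = matrix(0))
  expect_equal(klDivergence(d), 0.5)
  d <- new("LatentDistribution", mu = matrix(0), logSigma = matrix(1))
  expect_equal(klDivergence(d), 0.5 * (exp(2) - 3))   # ~ 2.19453
  # non-finite posteriors are rejected (at construction already)
  expect_error(new("LatentDistribution", mu = matrix(NaN), logSigma = matrix(0)),
               regexp = "finite")
})

test_that("KL is zero only at the prior and positive elsewhere", {
  set.seed(31)
  for (i in 1:20) {
    mu <- matrix(rnorm(4, sd = 0.5), 1)
    ls <- matrix(rnorm(4, sd = 0.3), 1)
    if (all(mu == 0) && all(ls == 0)) next
    d <- new("LatentDistribution", mu = mu, logSigma = ls)
    expect_gt(klDivergence(d), 0)
  }
})

test_that("closed-form KL agrees with a Monte-Carlo estimate", {
  # E_q[ln q(z) - ln p(z)] by simulation, the independent oracle
  # (mu, sigma) drawn away from the prior so the KL is large enough for a
  # 1e5-draw estimate to resolve 1% relative error; antithetic pairs reduce
  # the estimator variance
  set.seed(19)
  ndraws <- 1e5
  for (i in 1:20) {
    mu <- sample(c(-1, 1), 1) * runif(1, 1.5, 2.5)
    sigma <- exp(runif(1, -0.4, 0.4))
    eps <- rnorm(ndraws / 2)
    z <- mu + sigma * c(eps, -eps)
    mc <- mean(dnorm(z, mu, sigma, log = TRUE) - dnorm(z, log = TRUE))
    d <- new("LatentDistribution", mu = matrix(mu), logSigma = matrix(log(sigma)))
    expect_equal(klDivergence(d), mc, tolerance = 0.01)
  }
})

test_that("reconstruction NLL matches categorical closed forms and masks pads", {
  pad <- MolGraphVAE:::.PAD_ID; bos <- MolGraphVAE:::.BOS_ID
  eos <- MolGraphVAE:::.EOS_ID
  W <- 7L
  targets <- matrix(c(bos, 5L, 6L, eos), 1)
  uniform <- array(0, dim = c(1, 3, W))
  expect_equal(reconstructionNLL(uniform, targets), 3 * log(W))
  # a huge margin on the correct token drives the NLL to zero
  sharp <- array(0, dim = c(1, 3, W))
  for (t in 1:3) sharp[1, t, targets[1, t + 1]] <- 1e4
  expect_lt(reconstructionNLL(sharp, targets), 1e-8)
  # appending pad tokens leaves the value unchanged
  padded <- cbind(targets, pad, pad)
  uniformPadded <- array(0, dim = c(1, 5, W))
  expect_equal(reconstructionNLL(uniformPadded, padded),
               reconstructionNLL(uniform, targets))
  # NLL decreases monotonically in the correct-token logit
  vals <- vapply(c(0, 1, 2, 4), function(m) {
    lg <- array(0, dim = c(1, 3, W))
    lg[1, 1, targets[1, 2]] <- m
    reconstructionNLL(lg, targets)
  }, 0)
  expect_true(all(diff(vals) < 0))
  expect_error(reconstructionNLL(uniform, padded), regexp = "align")
})

test_that("beta schedule endpoints, monotonicity and cycle resets are exact", {
  mono <- betaSchedule("monotonic", totalSteps = 99L)
  expect_identical(betaAt(mono, 0), 5e-5)
  expect_identical(betaAt(mono, 99), 1e-4)
  vals <- vapply(0:99, function(s) betaAt(mono, s), 0)
  expect_true(all(diff(vals) >= 0))
  expect_error(betaAt(mono, 100), regexp = "step")
  expect_error(betaAt(mono, -1), regexp = "step")

  for (nc in c(2L, 4L, 8L)) {
    cyc <- betaSchedule("cyclical", nCycles = nc, totalSteps = 96L)
    v <- vapply(0:96, function(s) betaAt(cyc, s), 0)
    expect_identical(sum(v == 5e-5), as.integer(nc))   # low attained nc times
    expect_identical(v[1], 5e-5)
    # first step of every cycle resets to betaLow
    expect_identical(v[96L / nc + 1L], 5e-5)
  }
})

test_that("total loss assembles beta * kl + recon", {
  lb <- totalLoss(2, 3, 0.5)
  expect_equal(lb@total, 4)
  expect_equal(totalLoss(5, 3, 0)@total, 3)    # pure autoencoder limit
  expect_equal(totalLoss(0, 3, 123)@total, 3)
  expect_true(validObject(lb))
})
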