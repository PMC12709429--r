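# Optimization loop, checkpointing, and set-level generation.

#' TrainConfig: optimisation hyperparameters
#'
#' Defaults follow the reference setting: Adam with learning rate 3e-4 and
#' weight decay 1e-6, 100 epochs, beta advancing once per epoch along its
#' schedule.
#'
#' @slot learningRate Adam step size.
#' @slot weightDecay L2 weight decay folded into the gradient.
#' @slot epochs training epochs.
#' @slot batchSize molecules per optimisation step.
#' @slot seed the run seed (parameter init, shuffling, eps draws, dropout).
#' @slot schedule a \code{BetaSchedule}.
#' @slot gradClip global-norm gradient clip; NA disables (the default).
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", weightDecay = "numeric",
                 epochs = "integer", batchSize = "integer", seed = "integer",
                 schedule = "BetaSchedule", gradClip = "numeric"))

setValidity("TrainConfig", function(object) {
  msgs <- character(0)
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@epochs < 1L) msgs <- c(msgs, "epochs must be >= 1")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a training configuration
#'
#' @param learningRate Adam learning rate; default 3e-4.
#' @param weightDecay L2 weight decay; default 1e-6.
#' @param epochs training epochs; default 100.
#' @param batchSize molecules per step; default 256 (use ~16 at desk scale).
#' @param seed run seed; default 1.
#' @param schedule a \code{BetaSchedule}; by default a monotonic ramp over
#'   the epochs (horizon epochs - 1, so the final epoch reaches betaHigh).
#' @param gradClip global-norm clip, NA = off.
#' @return a \code{TrainConfig}
#' @export
trainConfig <- function(learningRate = 3e-4, weightDecay = 1e-6,
                        epochs = 100L, batchSize = 256L, seed = 1L,
                        schedule = NULL, gradClip = NA_real_) {
  if (is.null(schedule))
    schedule <- betaSchedule("monotonic", totalSteps = max(epochs - 1L, 1L))
  new("TrainConfig", learningRate = as.numeric(learningRate),
      weightDecay = as.numeric(weightDecay), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      schedule = schedule, gradClip = as.numeric(gradClip))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: lr %g, wd %g, %d epochs, batch %d, seed %d\n",
              object@learningRate, object@weightDecay, object@epochs,
              object@batchSize, object@seed))
  show(object@schedule)
})

# one optimisation step over a batch; returns the loss pieces
.trainStep <- function(ps, opt, graphsBatch, tokBatch, cfg, beta, gradClip,
                       atomSymbols) {
  bg <- .batchGraphs(graphsBatch, atomSymbols)
  B <- bg$B
  tape <- agTape()
  enc <- .encoderForward(tape, ps, bg, cfg, training = TRUE)
  eps <- matrix(stats::rnorm(B * cfg@latentDim), B, cfg@latentDim)
  z <- agAdd(tape, enc$mu,
             agMul(tape, agConst(tape, eps), agExp(tape, enc$logSigma)))
  tok <- tokBatch[, -ncol(tokBatch), drop = FALSE]   # inputs: drop last
  tgt <- tokBatch[, -1, drop = FALSE]                # targets: drop BOS
  logits <- .decoderForward(tape, ps, z, tok, cfg, training = TRUE)
  tgtvec <- as.vector(t(tgt))
  w <- as.numeric(tgtvec != .PAD_ID) / B
  recon <- agSoftmaxCE(tape, logits, tgtvec, w)
  kl <- agScalarMul(tape, agKLStd(tape, enc$mu, enc$logSigma), 1 / B)
  loss <- agAxpy(tape, recon, kl, 1, beta)
  if (!is.finite(loss$value))
    stop("non-finite loss (recon = ", recon$value, ", kl = ", kl$value,
         ", beta = ", beta, ")")
  grads <- agBackward(tape, loss)
  adamStep(opt, ps, grads, clipNorm = if (is.na(gradClip)) NULL else gradClip)
  c(kl = as.numeric(kl$value), recon = as.numeric(recon$value),
    total = as.numeric(loss$value))
}

#' Fit the model to a SMILES corpus
#'
#' Per epoch: seeded shuffle, disjoint-union graph batching with teacher-
#' forced token targets, the beta-weighted ELBO with \code{betaAt(schedule,
#' epoch - 1)}, one Adam step per batch. The best-total-loss parameters are
#' kept alongside the final ones, and every loss component is logged per
#' epoch. Runs with identical seed and configuration produce identical
#' logs.
#'
#' @param corpus character vector of training SMILES (all parseable).
#' @param config a \code{ModelConfig}.
#' @param train a \code{TrainConfig}.
#' @param resume optional result of a previous [fit()] call whose model and
#'   optimiser state are continued; the beta schedule resumes at the correct
#'   step and epochs continue up to \code{train@epochs}.
#' @param verbose print a line per epoch?
#' @return list with \code{model} (final weights), \code{bestModel},
#'   \code{bestEpoch}, \code{log} (data.frame: epoch, beta, kl, recon,
#'   total) and \code{epochsDone}.
#' @export
fit <- function(corpus, config = modelConfig(), train = trainConfig(),
                resume = NULL, verbose = FALSE) {
  stopifnot(length(corpus) >= 1L)
  validObject(train)
  ok <- isValidSmiles(corpus)
  if (!all(ok))
    stop("unparseable molecule(s) at index: ",
         paste(which(!ok), collapse = ", "))
  startEpoch <- 1L
  if (is.null(resume)) {
    model <- graphVAE(corpus, config, seed = train@seed)
  } else {
    model <- resume$model
    startEpoch <- resume$epochsDone + 1L
  }
  cfg <- model@config
  graphs <- smilesToGraphs(corpus)
  seqs <- tokenizeSmiles(corpus, model@vocab)
  tokAll <- padTokenMatrix(seqs)
  ps <- newParamStore(model@params)
  opt <- if (!is.null(resume) && !is.null(resume$optimizer)) resume$optimizer
         else newAdam(lr = train@learningRate, weightDecay = train@weightDecay)
  n <- length(corpus)
  log <- if (is.null(resume)) NULL else resume$log
  best <- if (is.null(resume)) Inf else min(resume$log$total)
  bestParams <- ps$val
  bestEpoch <- if (is.null(resume)) 0L else resume$bestEpoch
  set.seed(train@seed + startEpoch)
  for (epoch in seq(startEpoch, train@epochs)) {
    beta <- betaAt(train@schedule,
                   min(epoch - 1L, train@schedule@totalSteps))
    ord <- sample.int(n)
    stats <- c(kl = 0, recon = 0, total = 0)
    starts <- seq(1L, n, by = train@batchSize)
    for (s in starts) {
      idx <- ord[s:min(s + train@batchSize - 1L, n)]
      pieces <- .trainStep(ps, opt, graphs[idx], tokAll[idx, , drop = FALSE],
                           cfg, beta, train@gradClip, model@atomSymbols)
      stats <- stats + pieces * length(idx)
    }
    stats <- stats / n
    log <- rbind(log, data.frame(epoch = epoch, beta = beta,
                                 kl = stats[["kl"]], recon = stats[["recon"]],
                                 total = stats[["total"]]))
    if (stats[["total"]] < best) {
      best <- stats[["total"]]
      bestParams <- ps$val
      bestEpoch <- epoch
    }
    if (verbose)
      message(sprintf("[%s] epoch %4d beta %.3g kl %10.4f recon %10.4f total %10.4f",
                      format(Sys.time(), "%H:%M:%S"), epoch, beta,
                      stats[["kl"]], stats[["recon"]], stats[["total"]]))
  }
  rownames(log) <- NULL
  model@params <- ps$val
  bestModel <- model
  bestModel@params <- bestParams
  list(model = model, bestModel = bestModel, bestEpoch = bestEpoch,
       log = log, epochsDone = train@epochs, optimizer = opt,
       trainConfig = train)
}

#' Teacher-forced next-token accuracy
#'
#' Fraction of non-pad target positions whose argmax prediction under
#' teacher forcing equals the true next token, using each molecule's
#' posterior mean as the latent vector.
#'
#' @param model a \code{GraphVAEModel}.
#' @param corpus character vector of SMILES.
#' @return accuracy in [0, 1].
#' @export
teacherForcedAccuracy <- function(model, corpus) {
  dist <- encodeGraphs(model, corpus)
  tok <- padTokenMatrix(tokenizeSmiles(corpus, model@vocab))
  logits <- decodeTeacherForced(model, latentMu(dist), tok)
  tgt <- tok[, -1, drop = FALSE]
  hits <- 0L; tot <- 0L
  for (b in seq_len(nrow(tgt))) {
    keep <- tgt[b, ] != .PAD_ID
    pred <- apply(matrix(logits[b, , ], nrow = ncol(tgt)), 1L, which.max)
    hits <- hits + sum(pred[keep] == tgt[b, keep])
    tot <- tot + sum(keep)
  }
  hits / tot
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores configuration, weights, vocabulary, atom table and
#' seed (plus the training log when saving a [fit()] result), and restores
#' to a model that generates identically for the same seed.
#'
#' @param model a \code{GraphVAEModel} or a [fit()] result list.
#' @param path file path.
#' @return \code{loadCheckpoint} returns a list with \code{model} and,
#'   when present, \code{log} and \code{epochsDone}.
#' @export
saveCheckpoint <- function(model, path) {
  if (is.list(model)) {
    obj <- list(config = .configAsList(model$model@config),
                params = model$model@params,
                tokens = vocabTokens(model$model@vocab),
                atomSymbols = model$model@atomSymbols,
                seed = model$model@seed,
                log = model$log, epochsDone = model$epochsDone)
  } else {
    stopifnot(is(model, "GraphVAEModel"))
    obj <- list(config = .configAsList(model@config), params = model@params,
                tokens = vocabTokens(model@vocab),
                atomSymbols = model@atomSymbols, seed = model@seed)
  }
  saveRDS(obj, path)
  invisible(path)
}

.configAsList <- function(cfg) {
  list(nLayers = cfg@nLayers, hiddenDim = cfg@hiddenDim, ffnDim = cfg@ffnDim,
       encoderGatHeads = cfg@encoderGatHeads, decoderHeads = cfg@decoderHeads,
       latentDim = cfg@latentDim, vocabSize = cfg@vocabSize,
       maxLen = cfg@maxLen, dropout = cfg@dropout)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable checkpoint: ", path))
  need <- c("config", "params", "tokens", "atomSymbols", "seed")
  if (!all(need %in% names(obj)))
    stop("corrupt checkpoint (missing fields): ", path)
  cfg <- do.call(modelConfig, obj$config)
  model <- new("GraphVAEModel", config = cfg, params = obj$params,
               vocab = new("SmilesVocabulary", tokens = obj$tokens),
               atomSymbols = obj$atomSymbols, seed = as.integer(obj$seed))
  list(model = model, log = obj$log, epochsDone = obj$epochsDone)
}

#' Generate a set of molecules from the prior
#'
#' Draws \code{n} latent vectors from the standard-Gaussian prior and
#' decodes each in sample mode. Returns exactly \code{n} strings, valid or
#' not -- validity is judged downstream by the metric suite. The benchmark
#' convention is n = 30000.
#'
#' @param model a \code{GraphVAEModel} (or a checkpoint path).
#' @param n number of molecules; default 30000.
#' @param seed integer seed; draws are reproducible.
#' @param temperature sampling temperature; default 1.
#' @param chunkSize molecules decoded per batch; default 64.
#' @return character vector of n generated SMILES.
#' @export
generateSet <- function(model, n = 30000L, seed = 1L, temperature = 1.0,
                        chunkSize = 64L) {
  if (is.character(model) && length(model) == 1L)
    model <- loadCheckpoint(model)$model
  stopifnot(is(model, "GraphVAEModel"), n >= 1L)
  .withSeed(seed, {
    z <- matrix(stats::rnorm(n * model@config@latentDim),
                n, model@config@latentDim)
    out <- character(n)
    for (s in seq(1L, n, by = chunkSize)) {
      idx <- s:min(s + chunkSize - 1L, n)
      g <- generateMolecules(model, z[idx, , drop = FALSE], mode = "sample",
                             temperature = temperature, seed = NULL)
      out[idx] <- g$smiles
    }
    out
  })
}
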