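# The graph-to-sequence VAE.
#
# Encoder: a stack of layers, each = two graph-attention sublayers followed
# by a position-wise feed-forward sublayer, every sublayer wrapped in
# residual + layer norm; DenseNet-style connections feed the concatenation
# of the atom embeddings and all earlier layer outputs into each layer, so
# every layer has a direct path to the loss (over-smoothing / vanishing-
# gradient relief). Global add pooling sums node vectors per molecule, and
# two linear heads map the pooled vector to the posterior mean and log
# standard deviation.
#
# Decoder: a standard transformer decoder (sinusoidal positions, causal
# multi-head self-attention, feed-forward, post-norm residuals) whose
# cross-attention attends to the latent vector, presented as a memory
# sequence of length one.

#' ModelConfig: architecture hyperparameters
#'
#' Defaults follow the reference setting: eight encoder and decoder blocks,
#' hidden dimension 512, feed-forward dimension 1024, a single graph-
#' attention head in the encoder (2/4/8 configurable) and 16 decoder
#' attention heads. The latent dimension defaults to the hidden dimension.
#'
#' @slot nLayers encoder and decoder block count.
#' @slot hiddenDim model width; must be divisible by \code{decoderHeads}.
#' @slot ffnDim feed-forward inner width.
#' @slot encoderGatHeads graph-attention heads per GAT sublayer.
#' @slot decoderHeads decoder attention heads.
#' @slot latentDim latent-space dimensionality.
#' @slot vocabSize token vocabulary size.
#' @slot maxLen maximum decoded token count (>= longest training sequence).
#' @slot dropout dropout rate.
#' @export
setClass("ModelConfig",
  representation(nLayers = "integer", hiddenDim = "integer", ffnDim = "integer",
                 encoderGatHeads = "integer", decoderHeads = "integer",
                 latentDim = "integer", vocabSize = "integer",
                 maxLen = "integer", dropout = "numeric"))

setValidity("ModelConfig", function(object) {
  msgs <- character(0)
  dims <- c(object@nLayers, object@hiddenDim, object@ffnDim,
            object@encoderGatHeads, object@decoderHeads, object@latentDim,
            object@vocabSize, object@maxLen)
  if (any(dims <= 0L)) msgs <- c(msgs, "all dimensions must be positive")
  if (object@hiddenDim %% object@decoderHeads != 0L)
    msgs <- c(msgs, "hiddenDim must be divisible by decoderHeads")
  if (object@dropout < 0 || object@dropout >= 1)
    msgs <- c(msgs, "dropout must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a model configuration
#'
#' @param nLayers encoder/decoder block count; default 8.
#' @param hiddenDim hidden width; default 512.
#' @param ffnDim feed-forward width; default 1024.
#' @param encoderGatHeads GAT heads; default 1.
#' @param decoderHeads decoder attention heads; default 16.
#' @param latentDim latent dimension; default \code{hiddenDim}.
#' @param vocabSize vocabulary size (set automatically by [graphVAE()]).
#' @param maxLen maximum decoded length; default 128.
#' @param dropout dropout rate; default 0.1.
#' @return a \code{ModelConfig}
#' @export
modelConfig <- function(nLayers = 8L, hiddenDim = 512L, ffnDim = 1024L,
                        encoderGatHeads = 1L, decoderHeads = 16L,
                        latentDim = hiddenDim, vocabSize = 1L,
                        maxLen = 128L, dropout = 0.1) {
  new("ModelConfig", nLayers = as.integer(nLayers),
      hiddenDim = as.integer(hiddenDim), ffnDim = as.integer(ffnDim),
      encoderGatHeads = as.integer(encoderGatHeads),
      decoderHeads = as.integer(decoderHeads),
      latentDim = as.integer(latentDim), vocabSize = as.integer(vocabSize),
      maxLen = as.integer(maxLen), dropout = as.numeric(dropout))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0("ModelConfig: %d layers, hidden %d, ffn %d, GAT heads %d, ",
                     "decoder heads %d, latent %d, vocab %d, maxLen %d, dropout %g\n"),
              object@nLayers, object@hiddenDim, object@ffnDim,
              object@encoderGatHeads, object@decoderHeads, object@latentDim,
              object@vocabSize, object@maxLen, object@dropout))
})

#' GraphVAEModel: the generative model
#'
#' Bundles configuration, trainable weights, SMILES vocabulary, atom-symbol
#' table and the seed that produced the weights. Construct with
#' [graphVAE()], train with [fit()], sample with [generateMolecules()].
#'
#' @slot config a \code{ModelConfig}.
#' @slot params named list of weight matrices.
#' @slot vocab a \code{SmilesVocabulary}.
#' @slot atomSymbols element symbols the node-embedding table covers.
#' @slot seed integer seed used for weight initialisation.
#' @export
setClass("GraphVAEModel",
  representation(config = "ModelConfig", params = "list",
                 vocab = "SmilesVocabulary", atomSymbols = "character",
                 seed = "integer"))

setMethod("show", "GraphVAEModel", function(object) {
  np <- sum(vapply(object@params, length, 0L))
  cat("GraphVAEModel:", format(np, big.mark = ","), "parameters, seed",
      object@seed, "\n")
  show(object@config)
  cat("  atom table:", paste(object@atomSymbols, collapse = " "), "\n")
})

# number of distinct edge-type embeddings: bond codes 0..3 plus a self-loop
.N_EDGE_TYPES <- 5L
.SELF_LOOP_TYPE <- 5L

# ---- initialisation ------------------------------------------------------

.xavier <- function(fin, fout) {
  matrix(stats::rnorm(fin * fout, sd = sqrt(2 / (fin + fout))), fin, fout)
}
.zeros <- function(r, c) matrix(0, r, c)
.ones <- function(r, c) matrix(1, r, c)

.initParams <- function(cfg, nAtomTypes) {
  d <- cfg@hiddenDim; L <- cfg@nLayers; nh <- cfg@encoderGatHeads
  p <- list(
    atomEmb = matrix(stats::rnorm(nAtomTypes * d, sd = 0.1), nAtomTypes, d),
    edgeEmb = matrix(stats::rnorm(.N_EDGE_TYPES * d, sd = 0.1), .N_EDGE_TYPES, d),
    tokEmb  = matrix(stats::rnorm(cfg@vocabSize * d, sd = 1 / sqrt(d)),
                     cfg@vocabSize, d)
  )
  for (l in seq_len(L)) {
    pre <- paste0("enc.", l, ".")
    if (l > 1L) {
      p[[paste0(pre, "dense.W")]] <- .xavier(l * d, d)
      p[[paste0(pre, "dense.b")]] <- .zeros(1, d)
    }
    for (s in 1:2) {
      gp <- paste0(pre, "gat", s, ".")
      for (h in seq_len(nh)) {
        p[[paste0(gp, "W", h)]] <- .xavier(d, d)
        p[[paste0(gp, "aSrc", h)]] <- .xavier(d, 1)
        p[[paste0(gp, "aDst", h)]] <- .xavier(d, 1)
        p[[paste0(gp, "aEdge", h)]] <- .xavier(d, 1)
      }
      p[[paste0(gp, "Wo")]] <- .xavier(nh * d, d)
      p[[paste0(gp, "bo")]] <- .zeros(1, d)
      p[[paste0(gp, "ln.g")]] <- .ones(1, d)
      p[[paste0(gp, "ln.b")]] <- .zeros(1, d)
    }
    p[[paste0(pre, "ffn.W1")]] <- .xavier(d, cfg@ffnDim)
    p[[paste0(pre, "ffn.b1")]] <- .zeros(1, cfg@ffnDim)
    p[[paste0(pre, "ffn.W2")]] <- .xavier(cfg@ffnDim, d)
    p[[paste0(pre, "ffn.b2")]] <- .zeros(1, d)
    p[[paste0(pre, "ffn.ln.g")]] <- .ones(1, d)
    p[[paste0(pre, "ffn.ln.b")]] <- .zeros(1, d)
  }
  # posterior heads start near zero so the initial posterior sits at the
  # prior (mu ~ 0, log sigma ~ 0): global add pooling sums node vectors, and
  # full-scale head weights would push |log sigma| far enough to overflow
  # exp(2 log sigma) in the KL
  p$mu.W <- .xavier(d, cfg@latentDim) * 0.05
  p$mu.b <- .zeros(1, cfg@latentDim)
  p$sigma.W <- .xavier(d, cfg@latentDim) * 0.01
  p$sigma.b <- .zeros(1, cfg@latentDim)
  p$dec.memW <- .xavier(cfg@latentDim, d); p$dec.memb <- .zeros(1, d)
  for (l in seq_len(L)) {
    pre <- paste0("dec.", l, ".")
    for (blk in c("self", "cross")) {
      bp <- paste0(pre, blk, ".")
      for (w in c("Wq", "Wk", "Wv", "Wo"))
        p[[paste0(bp, w)]] <- .xavier(d, d)
      p[[paste0(bp, "bo")]] <- .zeros(1, d)
      p[[paste0(bp, "ln.g")]] <- .ones(1, d)
      p[[paste0(bp, "ln.b")]] <- .zeros(1, d)
    }
    p[[paste0(pre, "ffn.W1")]] <- .xavier(d, cfg@ffnDim)
    p[[paste0(pre, "ffn.b1")]] <- .zeros(1, cfg@ffnDim)
    p[[paste0(pre, "ffn.W2")]] <- .xavier(cfg@ffnDim, d)
    p[[paste0(pre, "ffn.b2")]] <- .zeros(1, d)
    p[[paste0(pre, "ffn.ln.g")]] <- .ones(1, d)
    p[[paste0(pre, "ffn.ln.b")]] <- .zeros(1, d)
  }
  p$out.W <- .xavier(d, cfg@vocabSize)
  p$out.b <- .zeros(1, cfg@vocabSize)
  p
}

#' Construct an untrained model
#'
#' Builds the vocabulary and atom-symbol table from a training corpus and
#' initialises weights from the seed. One seed controls initialisation,
#' posterior sampling and generation throughout the model's life.
#'
#' @param corpus character vector of SMILES the model will be trained on.
#' @param config a \code{ModelConfig}; \code{vocabSize} and \code{maxLen}
#'   are completed from the corpus.
#' @param seed integer seed.
#' @return a \code{GraphVAEModel}.
#' @examples
#' m <- graphVAE(c("CCO", "CCN"), modelConfig(nLayers = 1L, hiddenDim = 16L,
#'   ffnDim = 32L, decoderHeads = 4L, latentDim = 8L), seed = 1)
#' @export
graphVAE <- function(corpus, config = modelConfig(), seed = 1L) {
  stopifnot(length(corpus) >= 1L)
  vocab <- buildVocabulary(corpus)
  graphs <- smilesToGraphs(corpus)
  atomSymbols <- sort(unique(unlist(lapply(graphs, nodeSymbols))), method = "radix")
  seqLens <- vapply(tokenizeSmiles(corpus, vocab), length, 0L)
  cfg <- config
  cfg@vocabSize <- vocabSize(vocab)
  cfg@maxLen <- max(cfg@maxLen, max(seqLens))
  validObject(cfg)
  params <- .withSeed(seed, .initParams(cfg, length(atomSymbols)))
  new("GraphVAEModel", config = cfg, params = params, vocab = vocab,
      atomSymbols = atomSymbols, seed = as.integer(seed))
}

# ---- graph batching ------------------------------------------------------

# Disjoint-union batching: one block-diagonal graph with a molecule-id
# vector, so global add pooling segments per molecule. Self-loops (their
# own edge type) guarantee every node attends at least to itself.
.batchGraphs <- function(graphs, atomSymbols) {
  if (!length(graphs)) stop("empty batch")
  offs <- 0L
  sym <- integer(0); u <- integer(0); v <- integer(0); ty <- integer(0)
  gid <- integer(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (g@nNodes == 0L) stop("graph with 0 nodes in batch")
    ids <- match(g@nodeSymbols, atomSymbols)
    if (anyNA(ids))
      stop("atom symbol outside the model's embedding table: ",
           paste(unique(g@nodeSymbols[is.na(ids)]), collapse = " "))
    sym <- c(sym, ids)
    if (ncol(g@edgeIndex)) {
      u <- c(u, g@edgeIndex[1, ] + 1L + offs)
      v <- c(v, g@edgeIndex[2, ] + 1L + offs)
      ty <- c(ty, g@edgeTypes + 1L)   # codes 0..3 -> type ids 1..4
    }
    nodes <- seq_len(g@nNodes) + offs
    u <- c(u, nodes); v <- c(v, nodes)
    ty <- c(ty, rep(.SELF_LOOP_TYPE, g@nNodes))
    gid <- c(gid, rep(i, g@nNodes))
    offs <- offs + g@nNodes
  }
  list(sym = sym, u = u, v = v, ty = ty, gid = gid,
       N = offs, B = length(graphs))
}

# ---- forward passes ------------------------------------------------------

.gatSublayer <- function(tape, ps, prefix, X, bg, nheads) {
  edgeEmb <- psNode(ps, tape, "edgeEmb")
  Ee <- agRows(tape, edgeEmb, bg$ty)
  heads <- vector("list", nheads)
  for (h in seq_len(nheads)) {
    W <- psNode(ps, tape, paste0(prefix, "W", h))
    Z <- agMatmul(tape, X, W)
    sS <- agMatmul(tape, Z, psNode(ps, tape, paste0(prefix, "aSrc", h)))
    sD <- agMatmul(tape, Z, psNode(ps, tape, paste0(prefix, "aDst", h)))
    sE <- agMatmul(tape, Ee, psNode(ps, tape, paste0(prefix, "aEdge", h)))
    score <- agLeakyRelu(tape,
      agAdd(tape, agAdd(tape, agRows(tape, sS, bg$u), agRows(tape, sD, bg$v)), sE))
    alpha <- agSegSoftmax(tape, score, bg$v)
    msg <- agScaleRows(tape, agRows(tape, Z, bg$u), alpha)
    heads[[h]] <- agSegSum(tape, msg, bg$v, bg$N)
  }
  merged <- if (nheads == 1L) heads[[1]] else agConcatCols(tape, heads)
  agAddBias(tape, agMatmul(tape, merged, psNode(ps, tape, paste0(prefix, "Wo"))),
            psNode(ps, tape, paste0(prefix, "bo")))
}

.ffnSublayer <- function(tape, ps, prefix, X, training, dropout) {
  H <- agRelu(tape, agAddBias(tape,
        agMatmul(tape, X, psNode(ps, tape, paste0(prefix, "W1"))),
        psNode(ps, tape, paste0(prefix, "b1"))))
  agAddBias(tape, agMatmul(tape, H, psNode(ps, tape, paste0(prefix, "W2"))),
            psNode(ps, tape, paste0(prefix, "b2")))
}

.residualNorm <- function(tape, ps, lnPrefix, X, sub, training, dropout) {
  sub <- agDropout(tape, sub, dropout, training)
  agLayerNorm(tape, agAdd(tape, X, sub),
              psNode(ps, tape, paste0(lnPrefix, "ln.g")),
              psNode(ps, tape, paste0(lnPrefix, "ln.b")))
}

# Encoder forward: returns list(mu, logSigma, nodeStates) of tape nodes.
# denseConnections = FALSE ablates the inter-layer concatenation (the
# over-smoothing probe); layers then read the previous layer's output only.
.encoderForward <- function(tape, ps, bg, cfg, training = FALSE,
                            denseConnections = TRUE) {
  dropout <- cfg@dropout
  H0 <- agRows(tape, psNode(ps, tape, "atomEmb"), bg$sym)
  hist <- list(H0)
  X <- H0
  for (l in seq_len(cfg@nLayers)) {
    pre <- paste0("enc.", l, ".")
    if (l > 1L) {
      X <- if (denseConnections)
        agAddBias(tape, agMatmul(tape, agConcatCols(tape, hist),
                                 psNode(ps, tape, paste0(pre, "dense.W"))),
                  psNode(ps, tape, paste0(pre, "dense.b")))
      else X
    }
    for (s in 1:2) {
      gp <- paste0(pre, "gat", s, ".")
      A <- .gatSublayer(tape, ps, gp, X, bg, cfg@encoderGatHeads)
      X <- .residualNorm(tape, ps, gp, X, A, training, dropout)
    }
    FF <- .ffnSublayer(tape, ps, paste0(pre, "ffn."), X, training, dropout)
    X <- .residualNorm(tape, ps, paste0(pre, "ffn."), X, FF, training, dropout)
    hist[[l + 1L]] <- X
  }
  pooled <- agSegSum(tape, X, bg$gid, bg$B)
  mu <- agAddBias(tape, agMatmul(tape, pooled, psNode(ps, tape, "mu.W")),
                  psNode(ps, tape, "mu.b"))
  ls <- agAddBias(tape, agMatmul(tape, pooled, psNode(ps, tape, "sigma.W")),
                  psNode(ps, tape, "sigma.b"))
  list(mu = mu, logSigma = ls, nodeStates = X)
}

.sinusoidalPE <- function(Tlen, d) {
  pos <- matrix(0, Tlen, d)
  t0 <- seq_len(Tlen) - 1
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pos[, 2L * i - 1L] <- sin(t0 * freq)
    if (2L * i <= d) pos[, 2L * i] <- cos(t0 * freq)
  }
  pos
}

.mhaBlock <- function(tape, ps, prefix, Xq, Xkv, B, Tq, Tk, nheads, causal) {
  Q <- agMatmul(tape, Xq, psNode(ps, tape, paste0(prefix, "Wq")))
  K <- agMatmul(tape, Xkv, psNode(ps, tape, paste0(prefix, "Wk")))
  V <- agMatmul(tape, Xkv, psNode(ps, tape, paste0(prefix, "Wv")))
  O <- agAttention(tape, Q, K, V, B, Tq, Tk, nheads, causal)
  agAddBias(tape, agMatmul(tape, O, psNode(ps, tape, paste0(prefix, "Wo"))),
            psNode(ps, tape, paste0(prefix, "bo")))
}

# Decoder forward on teacher-forcing inputs. tok: B x T integer matrix of
# *input* tokens (BOS-led). Returns logits tape node ((B*T) x V), rows
# blocked per molecule (row = (b-1)*T + t).
.decoderForward <- function(tape, ps, z, tok, cfg, training = FALSE) {
  B <- nrow(tok); Tlen <- ncol(tok); d <- cfg@hiddenDim
  if (Tlen > cfg@maxLen) stop("sequence length ", Tlen, " exceeds maxLen ", cfg@maxLen)
  dropout <- cfg@dropout
  mem <- agAddBias(tape, agMatmul(tape, z, psNode(ps, tape, "dec.memW")),
                   psNode(ps, tape, "dec.memb"))
  tokvec <- as.vector(t(tok))
  X <- agScalarMul(tape, agRows(tape, psNode(ps, tape, "tokEmb"), tokvec), sqrt(d))
  pe <- .sinusoidalPE(Tlen, d)
  X <- agAdd(tape, X, agConst(tape, pe[rep(seq_len(Tlen), B), , drop = FALSE]))
  X <- agDropout(tape, X, dropout, training)
  for (l in seq_len(cfg@nLayers)) {
    pre <- paste0("dec.", l, ".")
    A <- .mhaBlock(tape, ps, paste0(pre, "self."), X, X, B, Tlen, Tlen,
                   cfg@decoderHeads, causal = TRUE)
    X <- .residualNorm(tape, ps, paste0(pre, "self."), X, A, training, dropout)
    Cx <- .mhaBlock(tape, ps, paste0(pre, "cross."), X, mem, B, Tlen, 1L,
                    cfg@decoderHeads, causal = FALSE)
    X <- .residualNorm(tape, ps, paste0(pre, "cross."), X, Cx, training, dropout)
    FF <- .ffnSublayer(tape, ps, paste0(pre, "ffn."), X, training, dropout)
    X <- .residualNorm(tape, ps, paste0(pre, "ffn."), X, FF, training, dropout)
  }
  agAddBias(tape, agMatmul(tape, X, psNode(ps, tape, "out.W")),
            psNode(ps, tape, "out.b"))
}

# ---- user-facing operations ----------------------------------------------

#' Encode molecules into the latent posterior
#'
#' Runs the graph-attention encoder and returns the per-molecule posterior
#' parameters (mu, log sigma). The encoding is invariant to node relabeling
#' (message passing plus sum pooling), and encoding a batch equals encoding
#' each molecule alone.
#'
#' @param model a \code{GraphVAEModel}.
#' @param graphs list of \code{MolecularGraph} (or a character vector of
#'   SMILES, converted on the fly).
#' @return a \code{LatentDistribution} with one row per molecule.
#' @export
encodeGraphs <- function(model, graphs) {
  stopifnot(is(model, "GraphVAEModel"))
  if (is.character(graphs)) graphs <- smilesToGraphs(graphs)
  if (is(graphs, "MolecularGraph")) graphs <- list(graphs)
  if (!length(graphs)) stop("empty batch")
  bg <- .batchGraphs(graphs, model@atomSymbols)
  tape <- agTape()
  ps <- newParamStore(model@params)
  enc <- .encoderForward(tape, ps, bg, model@config, training = FALSE)
  new("LatentDistribution", mu = enc$mu$value, logSigma = enc$logSigma$value)
}

#' Reparameterized sampling from the posterior
#'
#' z = mu + eps * sigma elementwise, the reparameterization trick: the
#' stochastic draw enters through the externally supplied standard-normal
#' eps while gradients flow through mu and sigma.
#'
#' @param dist a \code{LatentDistribution}.
#' @param eps numeric matrix (or vector for one molecule) of standard-normal
#'   draws, same shape as \code{latentMu(dist)}.
#' @return numeric matrix of latent vectors, one row per molecule.
#' @examples
#' d <- new("LatentDistribution", mu = matrix(0, 1, 2), logSigma = matrix(0, 1, 2))
#' reparameterize(d, matrix(c(1, -1), 1, 2))
#' @export
reparameterize <- function(dist, eps) {
  stopifnot(is(dist, "LatentDistribution"))
  if (is.vector(eps)) eps <- matrix(eps, nrow = nrow(dist@mu), byrow = TRUE)
  if (!all(dim(eps) == dim(dist@mu)))
    stop("eps has shape (", paste(dim(eps), collapse = "x"),
         ") but the distribution is (", paste(dim(dist@mu), collapse = "x"), ")")
  dist@mu + eps * exp(dist@logSigma)
}

#' Sample latent vectors from the prior
#'
#' The prior over z is standard Gaussian; draws are seeded and reproducible.
#'
#' @param model a \code{GraphVAEModel} (or an integer latent dimension).
#' @param n number of draws.
#' @param seed integer seed.
#' @return n x latentDim numeric matrix.
#' @export
priorSample <- function(model, n, seed = 1L) {
  stopifnot(n >= 1)
  ld <- if (is(model, "GraphVAEModel")) model@config@latentDim else as.integer(model)
  .withSeed(seed, matrix(stats::rnorm(n * ld), nrow = n, ncol = ld))
}

#' Teacher-forced decoding
#'
#' Computes next-token logits for every position of the target sequences:
#' entry \code{[b, t, ]} is the logit vector predicting target token t+1 of
#' molecule b from the latent vector and target tokens 1..t only (causal
#' masking), so perturbing the target at position t leaves logits at
#' positions <= t unchanged.
#'
#' @param model a \code{GraphVAEModel}.
#' @param z numeric matrix of latent vectors (B x latentDim).
#' @param targets B x T integer matrix of BOS-led, EOS-terminated, padded
#'   token ids (see [tokenizeSmiles()] and [padTokenMatrix()]).
#' @return numeric array (B, T-1, vocabSize) of logits.
#' @export
decodeTeacherForced <- function(model, z, targets) {
  stopifnot(is(model, "GraphVAEModel"), is.matrix(z), is.matrix(targets))
  if (any(targets[, 1] != .BOS_ID))
    stop("target sequences must begin with the begin-of-sequence id")
  tok <- targets[, -ncol(targets), drop = FALSE]
  tape <- agTape()
  ps <- newParamStore(model@params)
  logits <- .decoderForward(tape, ps, agConst(tape, z), tok, model@config,
                            training = FALSE)
  B <- nrow(tok); Tlen <- ncol(tok); V <- model@config@vocabSize
  aperm(array(t(logits$value), dim = c(V, Tlen, B)), c(3, 2, 1))
}

#' Autoregressive generation from latent vectors
#'
#' Decodes each latent vector token by token from the begin-of-sequence
#' marker, appending the argmax token (greedy) or a temperature-scaled
#' categorical draw (sample) until the end-of-sequence marker or
#' \code{maxLen}. Sampling with a fixed seed is reproducible. Sequences
#' that never emit the end marker are truncated and flagged.
#'
#' @param model a \code{GraphVAEModel}.
#' @param z numeric matrix of latent vectors (B x latentDim).
#' @param mode "greedy" or "sample".
#' @param temperature softmax temperature for sample mode; default 1.
#' @param seed integer seed for sample mode; NULL draws from the ambient
#'   RNG stream (used by [generateSet()] to seed a whole run once).
#' @param maxLen maximum token count; default the model's maxLen.
#' @return list with \code{smiles} (character vector, specials stripped)
#'   and \code{truncated} (logical vector).
#' @export
generateMolecules <- function(model, z, mode = c("sample", "greedy"),
                              temperature = 1.0, seed = 1L,
                              maxLen = NULL) {
  stopifnot(is(model, "GraphVAEModel"), is.matrix(z))
  mode <- match.arg(mode)
  if (is.null(maxLen)) maxLen <- model@config@maxLen
  B <- nrow(z)
  run <- function() {
    tok <- matrix(.BOS_ID, nrow = B, ncol = 1L)
    done <- rep(FALSE, B)
    ps <- newParamStore(model@params)
    while (ncol(tok) < maxLen && !all(done)) {
      tape <- agTape()
      logits <- .decoderForward(tape, ps, agConst(tape, z), tok, model@config,
                                training = FALSE)
      Tlen <- ncol(tok)
      last <- logits$value[Tlen * seq_len(B), , drop = FALSE]
      nxt <- integer(B)
      for (b in seq_len(B)) {
        if (done[b]) { nxt[b] <- .PAD_ID; next }
        lb <- last[b, ]
        if (mode == "greedy") {
          nxt[b] <- which.max(lb)
        } else {
          pr <- exp((lb - max(lb)) / temperature)
          nxt[b] <- sample.int(length(lb), 1L, prob = pr / sum(pr))
        }
        if (nxt[b] == .EOS_ID) done[b] <- TRUE
      }
      tok <- cbind(tok, nxt)
    }
    list(tok = tok, done = done)
  }
  res <- if (mode == "sample" && !is.null(seed)) .withSeed(seed, run()) else run()
  smiles <- vapply(seq_len(B), function(b)
    detokenizeSmiles(res$tok[b, ], model@vocab), "")
  list(smiles = smiles, truncated = !res$done)
}
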