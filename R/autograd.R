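# Minimal reverse-mode automatic differentiation over dense matrices.
#
# No neural-network framework is available to R here, so the model is built
# on this small tape-based engine: each op records its inputs and a backward
# closure; agBackward() walks the tape in reverse creation order (a valid
# reverse-topological order, since the graph is built forward) accumulating
# gradients. Everything is a base-R matrix, so the heavy lifting is BLAS.
#
# Ops are deliberately coarse where it pays: layer norm, multi-head
# attention, the softmax cross-entropy and the Gaussian KL are fused with
# hand-derived gradients, which keeps tapes short and fast.

agTape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t$pnodes <- list()   # one node per parameter name per tape
  t
}

.agPush <- function(tape, node) {
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    length(tape$nodes) <- 2L * length(tape$nodes)
  tape$nodes[[tape$n]] <- node
  node
}

.agNode <- function(tape, value, req, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$req <- req
  nd$backward <- backward
  .agPush(tape, nd)
}

.accum <- function(node, g) {
  if (!node$req) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

agConst <- function(tape, x) .agNode(tape, x, req = FALSE)

# Parameter stores hold the trainable matrices; psNode() materialises (at
# most once per tape) a leaf node for a named parameter.
newParamStore <- function(values = list()) {
  ps <- new.env(parent = emptyenv())
  ps$val <- values
  ps
}

psNode <- function(ps, tape, name) {
  nd <- tape$pnodes[[name]]
  if (!is.null(nd)) return(nd)
  v <- ps$val[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  nd <- .agNode(tape, v, req = TRUE)
  tape$pnodes[[name]] <- nd
  nd
}

# Run backward from a scalar loss node; returns named list of parameter
# gradients (missing parameters get NULL).
agBackward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!nd$req || is.null(nd$grad) || is.null(nd$backward)) next
    nd$backward(nd$grad)
  }
  lapply(tape$pnodes, function(p) p$grad)
}

# ---- elementwise and linear ops -----------------------------------------

agMatmul <- function(tape, a, b) {
  nd <- .agNode(tape, a$value %*% b$value, req = a$req || b$req)
  nd$backward <- function(g) {
    .accum(a, g %*% t(b$value))
    .accum(b, t(a$value) %*% g)
  }
  nd
}

agAdd <- function(tape, a, b) {
  nd <- .agNode(tape, a$value + b$value, req = a$req || b$req)
  nd$backward <- function(g) { .accum(a, g); .accum(b, g) }
  nd
}

# x + bias, bias a 1 x d matrix broadcast over rows
agAddBias <- function(tape, a, bias) {
  nd <- .agNode(tape, sweep(a$value, 2L, as.vector(bias$value), "+"),
                req = a$req || bias$req)
  nd$backward <- function(g) {
    .accum(a, g)
    .accum(bias, matrix(colSums(g), nrow = 1L))
  }
  nd
}

agMul <- function(tape, a, b) {
  nd <- .agNode(tape, a$value * b$value, req = a$req || b$req)
  nd$backward <- function(g) {
    .accum(a, g * b$value)
    .accum(b, g * a$value)
  }
  nd
}

# rows of a scaled by a column vector s (n x 1)
agScaleRows <- function(tape, a, s) {
  sv <- as.vector(s$value)
  nd <- .agNode(tape, a$value * sv, req = a$req || s$req)
  nd$backward <- function(g) {
    .accum(a, g * sv)
    .accum(s, matrix(rowSums(g * a$value), ncol = 1L))
  }
  nd
}

agScalarMul <- function(tape, a, k) {
  nd <- .agNode(tape, a$value * k, req = a$req)
  nd$backward <- function(g) .accum(a, g * k)
  nd
}

agExp <- function(tape, a) {
  v <- exp(a$value)
  nd <- .agNode(tape, v, req = a$req)
  nd$backward <- function(g) .accum(a, g * v)
  nd
}

agRelu <- function(tape, a) {
  nd <- .agNode(tape, pmax(a$value, 0), req = a$req)
  nd$backward <- function(g) .accum(a, g * (a$value > 0))
  nd
}

agLeakyRelu <- function(tape, a, alpha = 0.2) {
  v <- a$value
  nd <- .agNode(tape, ifelse(v > 0, v, alpha * v), req = a$req)
  nd$backward <- function(g) .accum(a, g * ifelse(v > 0, 1, alpha))
  nd
}

agDropout <- function(tape, a, p, training) {
  if (!training || p <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) > p) / (1 - p)
  nd <- .agNode(tape, a$value * mask, req = a$req)
  nd$backward <- function(g) .accum(a, g * mask)
  nd
}

# ---- gather / scatter ----------------------------------------------------

# gather rows: out[i, ] = a[idx[i], ]
agRows <- function(tape, a, idx) {
  idx <- as.integer(idx)
  nd <- .agNode(tape, a$value[idx, , drop = FALSE], req = a$req)
  nd$backward <- function(g) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    rs <- rowsum(g, idx)
    da[as.integer(rownames(rs)), ] <- rs
    .accum(a, da)
  }
  nd
}

# segment sum: out[k, ] = sum of rows of a with groups == k, k in 1..ngroups
agSegSum <- function(tape, a, groups, ngroups) {
  groups <- as.integer(groups)
  v <- matrix(0, ngroups, ncol(a$value))
  rs <- rowsum(a$value, groups)
  v[as.integer(rownames(rs)), ] <- rs
  nd <- .agNode(tape, v, req = a$req)
  nd$backward <- function(g) .accum(a, g[groups, , drop = FALSE])
  nd
}

# per-group softmax of a column vector of scores (n x 1)
agSegSoftmax <- function(tape, scores, groups) {
  groups <- as.integer(groups)
  s <- as.vector(scores$value)
  mx <- tapply(s, groups, max)[as.character(groups)]
  e <- exp(s - mx)
  tot <- rowsum(e, groups)[as.character(groups), 1L]
  p <- e / tot
  nd <- .agNode(tape, matrix(p, ncol = 1L), req = scores$req)
  nd$backward <- function(g) {
    gv <- as.vector(g)
    dot <- rowsum(gv * p, groups)[as.character(groups), 1L]
    .accum(scores, matrix(p * (gv - dot), ncol = 1L))
  }
  nd
}

agConcatCols <- function(tape, parts) {
  vals <- lapply(parts, function(p) p$value)
  nd <- .agNode(tape, do.call(cbind, vals),
                req = any(vapply(parts, function(p) p$req, TRUE)))
  offs <- cumsum(c(0L, vapply(vals, ncol, 0L)))
  nd$backward <- function(g) {
    for (i in seq_along(parts))
      .accum(parts[[i]], g[, (offs[i] + 1L):offs[i + 1L], drop = FALSE])
  }
  nd
}

# ---- fused layers --------------------------------------------------------

# row-wise layer normalisation with learned gain/offset (1 x d each)
agLayerNorm <- function(tape, a, gamma, beta, eps = 1e-5) {
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  gv <- as.vector(gamma$value)
  v <- sweep(xhat, 2L, gv, "*")
  v <- sweep(v, 2L, as.vector(beta$value), "+")
  nd <- .agNode(tape, v, req = a$req || gamma$req || beta$req)
  nd$backward <- function(g) {
    dxhat <- sweep(g, 2L, gv, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    .accum(a, istd * (dxhat - m1 - xhat * m2))
    .accum(gamma, matrix(colSums(g * xhat), nrow = 1L))
    .accum(beta, matrix(colSums(g), nrow = 1L))
  }
  nd
}

# Scaled-dot-product multi-head attention over padded batches.
# q: (B*Tq) x d, k, v: (B*Tk) x d, rows blocked per batch element
# (row = (b-1)*T + t). Splits d into nheads slices. causal = TRUE applies a
# lower-triangular mask (only valid when Tq == Tk).
agAttention <- function(tape, q, k, v, B, Tq, Tk, nheads, causal = FALSE) {
  d <- ncol(q$value)
  stopifnot(d %% nheads == 0L, ncol(k$value) == d, ncol(v$value) == d)
  dh <- d %/% nheads
  scale <- 1 / sqrt(dh)
  out <- matrix(0, B * Tq, d)
  Ps <- vector("list", B * nheads)
  for (b in seq_len(B)) {
    qr <- ((b - 1L) * Tq + 1L):(b * Tq)
    kr <- ((b - 1L) * Tk + 1L):(b * Tk)
    for (h in seq_len(nheads)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      S <- (q$value[qr, hc, drop = FALSE] %*%
              t(k$value[kr, hc, drop = FALSE])) * scale
      if (causal) S[upper.tri(S)] <- -Inf
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      P <- E / rowSums(E)
      Ps[[(b - 1L) * nheads + h]] <- P
      out[qr, hc] <- P %*% v$value[kr, hc, drop = FALSE]
    }
  }
  nd <- .agNode(tape, out, req = q$req || k$req || v$req)
  nd$backward <- function(g) {
    dq <- matrix(0, nrow(q$value), d)
    dk <- matrix(0, nrow(k$value), d)
    dv <- matrix(0, nrow(v$value), d)
    for (b in seq_len(B)) {
      qr <- ((b - 1L) * Tq + 1L):(b * Tq)
      kr <- ((b - 1L) * Tk + 1L):(b * Tk)
      for (h in seq_len(nheads)) {
        hc <- ((h - 1L) * dh + 1L):(h * dh)
        P <- Ps[[(b - 1L) * nheads + h]]
        gO <- g[qr, hc, drop = FALSE]
        dv[kr, hc] <- dv[kr, hc] + t(P) %*% gO
        dP <- gO %*% t(v$value[kr, hc, drop = FALSE])
        dS <- P * (dP - rowSums(dP * P))
        dq[qr, hc] <- dq[qr, hc] + (dS %*% k$value[kr, hc, drop = FALSE]) * scale
        dk[kr, hc] <- dk[kr, hc] + (t(dS) %*% q$value[qr, hc, drop = FALSE]) * scale
      }
    }
    .accum(q, dq); .accum(k, dk); .accum(v, dv)
  }
  nd
}

# Fused softmax cross-entropy: logits (N x V), targets integer N (1-based),
# weights numeric N. Value = sum_i w_i * nll_i (a 1x1 matrix).
agSoftmaxCE <- function(tape, logits, targets, weights) {
  L <- logits$value
  targets <- as.integer(targets)
  m <- apply(L, 1L, max)
  E <- exp(L - m)
  Z <- rowSums(E)
  P <- E / Z
  pick <- cbind(seq_len(nrow(L)), targets)
  nll <- log(Z) - (L[pick] - m)
  val <- sum(weights * nll)
  nd <- .agNode(tape, matrix(val, 1L, 1L), req = logits$req)
  nd$backward <- function(g) {
    gs <- as.numeric(g)
    dL <- P * (weights * gs)
    dL[pick] <- dL[pick] - weights * gs
    .accum(logits, dL)
  }
  nd
}

# Fused KL( N(mu, exp(ls)) || N(0, I) ), summed over all entries:
# sum 0.5 * (mu^2 + exp(2 ls) - 1 - 2 ls)
agKLStd <- function(tape, mu, ls) {
  e2 <- exp(2 * ls$value)
  val <- 0.5 * sum(mu$value^2 + e2 - 1 - 2 * ls$value)
  nd <- .agNode(tape, matrix(val, 1L, 1L), req = mu$req || ls$req)
  nd$backward <- function(g) {
    gs <- as.numeric(g)
    .accum(mu, gs * mu$value)
    .accum(ls, gs * (e2 - 1))
  }
  nd
}

# ka * a + kb * b for scalar nodes (loss assembly)
agAxpy <- function(tape, a, b, ka = 1, kb = 1) {
  nd <- .agNode(tape, ka * a$value + kb * b$value, req = a$req || b$req)
  nd$backward <- function(g) {
    .accum(a, ka * g)
    .accum(b, kb * g)
  }
  nd
}

# ---- optimiser -----------------------------------------------------------

# Adam with L2 weight decay folded into the gradient (classic formulation).
newAdam <- function(lr = 3e-4, beta1 = 0.9, beta2 = 0.999,
                    eps = 1e-8, weightDecay = 1e-6) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr; st$b1 <- beta1; st$b2 <- beta2; st$eps <- eps
  st$wd <- weightDecay; st$t <- 0L
  st$m <- list(); st$v <- list()
  st
}

adamStep <- function(opt, ps, grads, clipNorm = NULL) {
  opt$t <- opt$t + 1L
  if (!is.null(clipNorm)) {
    tot <- sqrt(sum(vapply(grads, function(g)
      if (is.null(g)) 0 else sum(g * g), 0)))
    if (tot > clipNorm)
      grads <- lapply(grads, function(g) if (is.null(g)) g else g * (clipNorm / tot))
  }
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    w <- ps$val[[nm]]
    if (opt$wd > 0) g <- g + opt$wd * w
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- opt$b1 * m + (1 - opt$b1) * g
    v <- opt$b2 * v + (1 - opt$b2) * g * g
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    ps$val[[nm]] <- w - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
  }
  invisible(NULL)
}
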