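# Circular (Morgan / ECFP4-style) hashed binary fingerprints, computed
# directly on the package's graph representation: per-atom invariants
# (element, degree, aromaticity, bond-order sum) are iteratively combined
# with sorted (bond-code, neighbor-hash) pairs for `radius` rounds, and
# every round's atom identifiers set a bit in a fixed-width table.
# Self-contained and deterministic, so Tanimoto similarity, internal
# diversity and nearest-neighbor searches are reproducible across platforms.

.FP_MOD <- 33554467   # < 2^25: products with small multipliers stay exact

.fpMix <- function(a, b) ((a * 31) %% .FP_MOD * 31 + b) %% .FP_MOD

# hash a non-negative integer vector to one value
.fpHashVec <- function(v) {
  h <- 7
  for (x in v) h <- .fpMix(h, x)
  h
}

.circularFingerprintGraph <- function(g, bits = 1024L, radius = 2L) {
  n <- g@nNodes
  out <- logical(bits)
  if (n == 0L) return(out)
  ei <- g@edgeIndex
  symCode <- vapply(g@nodeSymbols, function(s)
    .fpHashVec(utf8ToInt(s)), 0, USE.NAMES = FALSE)
  nbr <- vector("list", n)
  nbt <- vector("list", n)
  if (ncol(ei)) {
    u <- ei[1, ] + 1L; v <- ei[2, ] + 1L
    ord <- order(u)
    nbr <- unname(split(v[ord], factor(u[ord], levels = seq_len(n))))
    nbt <- unname(split(g@edgeTypes[ord], factor(u[ord], levels = seq_len(n))))
  } else {
    nbr <- rep(list(integer(0)), n)
    nbt <- rep(list(integer(0)), n)
  }
  deg <- lengths(nbr)
  arom <- vapply(nbt, function(t) any(t == 3L), TRUE)
  bsum <- vapply(nbt, function(t) sum(t + 1L), 0)
  h <- vapply(seq_len(n), function(i)
    .fpHashVec(c(symCode[i], deg[i], as.integer(arom[i]), bsum[i])), 0)
  out[h %% bits + 1L] <- TRUE
  for (r in seq_len(radius)) {
    hNew <- numeric(n)
    for (i in seq_len(n)) {
      pairs <- cbind(nbt[[i]], h[nbr[[i]]])
      if (nrow(pairs)) {
        ord <- order(pairs[, 1], pairs[, 2])
        hNew[i] <- .fpHashVec(c(r, h[i], t(pairs[ord, , drop = FALSE])))
      } else {
        hNew[i] <- .fpHashVec(c(r, h[i]))
      }
    }
    h <- hNew
    out[h %% bits + 1L] <- TRUE
  }
  out
}

#' Circular binary fingerprints of molecules
#'
#' Radius-2 circular substructure fingerprints hashed into 1024 bits
#' (Morgan/ECFP4-style), computed on the graph representation. Rows align
#' with the input; unparseable SMILES give NA rows.
#'
#' @param smiles character vector of SMILES.
#' @param bits fingerprint width; default 1024.
#' @param radius neighborhood radius; default 2.
#' @return numeric 0/1 matrix, length(smiles) x bits.
#' @export
circularFingerprints <- function(smiles, bits = 1024L, radius = 2L) {
  graphs <- smilesToGraphs(smiles, onInvalid = "null")
  out <- matrix(NA_real_, length(smiles), bits)
  for (i in seq_along(graphs)) {
    if (is.null(graphs[[i]])) next
    out[i, ] <- as.numeric(.circularFingerprintGraph(graphs[[i]], bits, radius))
  }
  out
}
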