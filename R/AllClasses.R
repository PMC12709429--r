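#' @import methods
NULL

#' MolecularGraph: attributed graph encoding of one molecule
#'
#' Holds the three-matrix graph representation used by the encoder: a node
#' symbol vector (one atom-symbol token per heavy atom, hydrogens implicit),
#' a 2 x e directed edge-index matrix, and a length-e bond-type code vector.
#' Every chemical bond contributes two directed columns (u,v) and (v,u) with
#' equal type codes. Node indices are 0-based parse order; bond codes are
#' single = 0, double = 1, triple = 2, aromatic = 3.
#'
#' @slot nodeSymbols character vector of atom element symbols, length n.
#' @slot edgeIndex integer matrix, 2 x e, 0-based node indices.
#' @slot edgeTypes integer vector, length e, values in 0:3.
#' @slot nNodes integer, heavy-atom count n.
#'
#' @seealso [smilesToGraph()], [graphToSmiles()]
#' @export
setClass("MolecularGraph",
  representation(
    nodeSymbols = "character",
    edgeIndex   = "matrix",
    edgeTypes   = "integer",
    nNodes      = "integer"
  )
)

setValidity("MolecularGraph", function(object) {
  msgs <- character(0)
  n <- object@nNodes
  ei <- object@edgeIndex
  et <- object@edgeTypes
  if (length(object@nodeSymbols) != n)
    msgs <- c(msgs, "nodeSymbols length must equal nNodes")
  if (nrow(ei) != 2L)
    msgs <- c(msgs, "edgeIndex must have 2 rows")
  if (ncol(ei) != length(et))
    msgs <- c(msgs, "edgeTypes length must equal number of edge columns")
  if (length(et) && (any(et < 0L) || any(et > 3L)))
    msgs <- c(msgs, "edgeTypes must be in {0,1,2,3}")
  if (ncol(ei) > 0) {
    if (any(ei < 0L) || any(ei >= n))
      msgs <- c(msgs, "edgeIndex entries must be in [0, nNodes)")
    if (ncol(ei) %% 2L != 0L)
      msgs <- c(msgs, "edge count must be even (both directions present)")
    # each directed edge must have its reverse with the same bond code
    key  <- paste(ei[1, ], ei[2, ], et, sep = ":")
    rkey <- paste(ei[2, ], ei[1, ], et, sep = ":")
    if (!all(rkey %in% key))
      msgs <- c(msgs, "every edge (u,v,code) needs a reversed (v,u,code)")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MolecularGraph number of heavy atoms
#' @param x,object a \code{MolecularGraph}
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @export
setMethod("nNodes", "MolecularGraph", function(x) x@nNodes)

#' @describeIn MolecularGraph atom element symbols in parse order
#' @export
setGeneric("nodeSymbols", function(x) standardGeneric("nodeSymbols"))

#' @export
setMethod("nodeSymbols", "MolecularGraph", function(x) x@nodeSymbols)

#' @describeIn MolecularGraph 2 x e directed edge-index matrix (0-based)
#' @export
setGeneric("edgeIndex", function(x) standardGeneric("edgeIndex"))

#' @export
setMethod("edgeIndex", "MolecularGraph", function(x) x@edgeIndex)

#' @describeIn MolecularGraph bond-type codes (0 single, 1 double, 2 triple,
#'   3 aromatic), one per directed edge column
#' @export
setGeneric("edgeTypes", function(x) standardGeneric("edgeTypes"))

#' @export
setMethod("edgeTypes", "MolecularGraph", function(x) x@edgeTypes)

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph with", object@nNodes, "nodes and",
      ncol(object@edgeIndex), "directed edges\n")
  cat("  atoms:", paste(object@nodeSymbols, collapse = " "), "\n")
  if (ncol(object@edgeIndex)) {
    tab <- table(factor(object@edgeTypes, levels = 0:3,
                        labels = c("single", "double", "triple", "aromatic")))
    tab <- tab[tab > 0]
    cat("  bonds:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
})

#' SmilesVocabulary: token/id bijection for SMILES sequences
#'
#' Integer ids are 1-based. The first four ids are reserved:
#' 1 = \code{<pad>}, 2 = \code{<bos>}, 3 = \code{<eos>}, 4 = \code{<unk>}.
#' Corpus tokens follow in lexicographic order, which makes vocabulary
#' construction order-independent and reproducible.
#'
#' @slot tokens character vector; \code{tokens[i]} is the token with id i.
#'
#' @seealso [buildVocabulary()], [tokenizeSmiles()]
#' @export
setClass("SmilesVocabulary", representation(tokens = "character"))

setValidity("SmilesVocabulary", function(object) {
  msgs <- character(0)
  tk <- object@tokens
  if (length(tk) < 4L || !identical(tk[1:4], c("<pad>", "<bos>", "<eos>", "<unk>")))
    msgs <- c(msgs, "first four tokens must be <pad>, <bos>, <eos>, <unk>")
  if (anyDuplicated(tk))
    msgs <- c(msgs, "tokens must be unique (token<->id must be a bijection)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SmilesVocabulary", function(object) {
  cat("SmilesVocabulary with", length(object@tokens), "tokens",
      "(4 reserved +", length(object@tokens) - 4L, "corpus tokens)\n")
})

#' @describeIn SmilesVocabulary number of tokens (including reserved ids)
#' @param x a \code{SmilesVocabulary}
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' @export
setMethod("vocabSize", "SmilesVocabulary", function(x) length(x@tokens))

#' @describeIn SmilesVocabulary the token character vector, index = id
#' @export
setGeneric("vocabTokens", function(x) standardGeneric("vocabTokens"))

#' @export
setMethod("vocabTokens", "SmilesVocabulary", function(x) x@tokens)

#' CorpusFilterRule: dataset admission rules for training corpora
#'
#' The default thresholds reproduce the MOSES/ZINC clean-leads filter:
#' molecular weight within [250, 350] g/mol, at most 7 rotatable bonds,
#' logP at most 3.5, elements restricted to C, N, S, O, F, Cl, Br (plus
#' implicit H), no ring larger than 8 atoms, and no formally charged atom.
#'
#' @slot mwMin,mwMax molecular-weight window in g/mol.
#' @slot maxRotatableBonds maximum rotatable-bond count.
#' @slot maxLogP maximum octanol/water partition coefficient.
#' @slot allowedElements permitted element symbols.
#' @slot maxRingSize largest admissible ring size (atoms).
#' @slot allowCharged logical; admit formally charged molecules?
#'
#' @seealso [corpusFilter()]
#' @export
setClass("CorpusFilterRule",
  representation(
    mwMin = "numeric", mwMax = "numeric",
    maxRotatableBonds = "integer",
    maxLogP = "numeric",
    allowedElements = "character",
    maxRingSize = "integer",
    allowCharged = "logical"
  ),
  prototype(
    mwMin = 250, mwMax = 350,
    maxRotatableBonds = 7L,
    maxLogP = 3.5,
    allowedElements = c("C", "N", "S", "O", "F", "Cl", "Br", "H"),
    maxRingSize = 8L,
    allowCharged = FALSE
  )
)

setValidity("CorpusFilterRule", function(object) {
  msgs <- character(0)
  if (!(object@mwMin < object@mwMax))
    msgs <- c(msgs, "mwMin must be < mwMax")
  if (object@mwMin <= 0 || object@maxRotatableBonds < 0L || object@maxRingSize <= 0L)
    msgs <- c(msgs, "thresholds must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a corpus filter rule
#'
#' @param mwMin,mwMax molecular-weight window (g/mol); defaults 250 and 350.
#' @param maxRotatableBonds maximum rotatable bonds; default 7.
#' @param maxLogP maximum logP; default 3.5.
#' @param allowedElements permitted element symbols; default
#'   C, N, S, O, F, Cl, Br, H.
#' @param maxRingSize largest admissible ring (atoms); default 8.
#' @param allowCharged admit charged molecules? default FALSE.
#' @return a \code{CorpusFilterRule}
#' @examples
#' corpusFilterRule()
#' @export
corpusFilterRule <- function(mwMin = 250, mwMax = 350,
                             maxRotatableBonds = 7L, maxLogP = 3.5,
                             allowedElements = c("C", "N", "S", "O", "F", "Cl", "Br", "H"),
                             maxRingSize = 8L, allowCharged = FALSE) {
  new("CorpusFilterRule", mwMin = as.numeric(mwMin), mwMax = as.numeric(mwMax),
      maxRotatableBonds = as.integer(maxRotatableBonds),
      maxLogP = as.numeric(maxLogP), allowedElements = allowedElements,
      maxRingSize = as.integer(maxRingSize), allowCharged = allowCharged)
}

setMethod("show", "CorpusFilterRule", function(object) {
  cat("CorpusFilterRule:\n")
  cat(sprintf("  MW in [%g, %g] g/mol, rotatable bonds <= %d, logP <= %g\n",
              object@mwMin, object@mwMax, object@maxRotatableBonds, object@maxLogP))
  cat("  elements:", paste(object@allowedElements, collapse = ","),
      "| max ring:", object@maxRingSize,
      "| charged allowed:", object@allowCharged, "\n")
})

#' BetaSchedule: KL-weight annealing policy
#'
#' The KL term of the objective is weighted by a time-varying beta.
#' The monotonic mode ramps linearly from \code{betaLow} to \code{betaHigh}
#' over the horizon; the cyclical mode splits the horizon into
#' \code{nCycles} equal cycles, each an independent linear ramp from
#' \code{betaLow} towards \code{betaHigh} that resets at the cycle boundary.
#' Default range is [5e-05, 1e-04].
#'
#' @slot mode "monotonic" or "cyclical".
#' @slot betaLow,betaHigh the beta range.
#' @slot nCycles number of cycles (cyclical mode).
#' @slot totalSteps schedule horizon in steps (epochs by default).
#'
#' @seealso [betaAt()]
#' @export
setClass("BetaSchedule",
  representation(mode = "character", betaLow = "numeric", betaHigh = "numeric",
                 nCycles = "integer", totalSteps = "integer"),
  prototype(mode = "monotonic", betaLow = 5e-5, betaHigh = 1e-4,
            nCycles = 1L, totalSteps = 99L)
)

setValidity("BetaSchedule", function(object) {
  msgs <- character(0)
  if (!object@mode %in% c("monotonic", "cyclical"))
    msgs <- c(msgs, "mode must be 'monotonic' or 'cyclical'")
  if (!(object@betaLow >= 0 && object@betaLow <= object@betaHigh))
    msgs <- c(msgs, "need 0 <= betaLow <= betaHigh")
  if (object@nCycles < 1L)
    msgs <- c(msgs, "nCycles must be >= 1")
  if (object@totalSteps < 1L)
    msgs <- c(msgs, "totalSteps must be >= 1")
  if (object@mode == "cyclical" && object@totalSteps %% object@nCycles != 0L)
    msgs <- c(msgs, "nCycles must divide totalSteps into equal cycles")
  if (length(msgs)) msgs else TRUE
})

#' Construct a beta schedule
#'
#' @param mode "monotonic" (single linear ramp) or "cyclical"
#'   (nCycles equal linear ramps, resetting at each cycle boundary).
#' @param betaLow,betaHigh beta range; defaults 5e-05 and 1e-04.
#' @param nCycles number of cycles for cyclical mode; default 1.
#' @param totalSteps schedule horizon; steps run from 0 to totalSteps.
#' @return a \code{BetaSchedule}
#' @examples
#' sch <- betaSchedule("monotonic", totalSteps = 99)
#' betaAt(sch, 0)
#' @export
betaSchedule <- function(mode = c("monotonic", "cyclical"),
                         betaLow = 5e-5, betaHigh = 1e-4,
                         nCycles = 1L, totalSteps = 99L) {
  mode <- match.arg(mode)
  new("BetaSchedule", mode = mode, betaLow = as.numeric(betaLow),
      betaHigh = as.numeric(betaHigh), nCycles = as.integer(nCycles),
      totalSteps = as.integer(totalSteps))
}

setMethod("show", "BetaSchedule", function(object) {
  cat(sprintf("BetaSchedule: %s, beta in [%g, %g], %d cycle(s), horizon %d steps\n",
              object@mode, object@betaLow, object@betaHigh,
              object@nCycles, object@totalSteps))
})

#' LatentDistribution: diagonal-Gaussian posterior parameters
#'
#' Per-molecule mean and log standard deviation of the approximate posterior
#' q(z|x) = N(mu(x), sigma(x)). One row per molecule. sigma is parameterised
#' on the log scale so it is positive by construction.
#'
#' @slot mu numeric matrix, batch x latentDim.
#' @slot logSigma numeric matrix, batch x latentDim.
#'
#' @seealso [encodeGraphs()], [reparameterize()], [klDivergence()]
#' @export
setClass("LatentDistribution",
  representation(mu = "matrix", logSigma = "matrix"))

setValidity("LatentDistribution", function(object) {
  msgs <- character(0)
  if (!all(dim(object@mu) == dim(object@logSigma)))
    msgs <- c(msgs, "mu and logSigma must have identical dimensions")
  if (!all(is.finite(object@mu)) || !all(is.finite(object@logSigma)))
    msgs <- c(msgs, "mu and logSigma must be finite")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn LatentDistribution posterior means (batch x latentDim)
#' @param x a \code{LatentDistribution}
#' @export
setGeneric("latentMu", function(x) standardGeneric("latentMu"))

#' @export
setMethod("latentMu", "LatentDistribution", function(x) x@mu)

#' @describeIn LatentDistribution posterior log standard deviations
#' @export
setGeneric("latentLogSigma", function(x) standardGeneric("latentLogSigma"))

#' @export
setMethod("latentLogSigma", "LatentDistribution", function(x) x@logSigma)

setMethod("show", "LatentDistribution", function(object) {
  cat("LatentDistribution for", nrow(object@mu), "molecule(s),",
      ncol(object@mu), "latent dimensions\n")
})

#' GenerationMetrics: quality report for a generated molecule set
#'
#' Collects the benchmark metric suite for a generated set G against
#' reference sets: validity, Unique@K, novelty (vs the training set),
#' internal diversity (p = 1 and 2), Bemis-Murcko scaffold cosine
#' similarity per reference set, and per-property Wasserstein distances.
#'
#' @slot validity fraction of generated strings that parse as valid molecules.
#' @slot uniqueAtK fraction of distinct canonical SMILES among the first K
#'   valid molecules.
#' @slot novelty fraction of valid molecules absent from the training set.
#' @slot intDiv1,intDiv2 internal diversity with fingerprint-similarity
#'   powers 1 and 2.
#' @slot scaffoldSimilarity named numeric; scaffold cosine similarity against
#'   each reference set supplied.
#' @slot propertyDistances named numeric; 1-D Wasserstein distances between
#'   generated and test-set property distributions.
#' @slot nGenerated,nValid set sizes.
#' @slot K the Unique@K cutoff used.
#'
#' @seealso [evaluateGeneration()]
#' @export
setClass("GenerationMetrics",
  representation(
    validity = "numeric", uniqueAtK = "numeric", novelty = "numeric",
    intDiv1 = "numeric", intDiv2 = "numeric",
    scaffoldSimilarity = "numeric", propertyDistances = "numeric",
    nGenerated = "integer", nValid = "integer", K = "integer"
  )
)

setValidity("GenerationMetrics", function(object) {
  fr <- c(object@validity, object@uniqueAtK, object@novelty,
          object@intDiv1, object@intDiv2, object@scaffoldSimilarity)
  if (length(fr) && (any(fr < -1e-12) || any(fr > 1 + 1e-12)))
    "all fraction metrics must lie in [0, 1]" else TRUE
})

setMethod("show", "GenerationMetrics", function(object) {
  cat("GenerationMetrics (", object@nGenerated, " generated, ",
      object@nValid, " valid)\n", sep = "")
  cat(sprintf("  validity   %.4f\n  unique@%-6d %.4f\n  novelty    %.4f\n",
              object@validity, object@K, object@uniqueAtK, object@novelty))
  cat(sprintf("  IntDiv1    %.4f\n  IntDiv2    %.4f\n",
              object@intDiv1, object@intDiv2))
  if (length(object@scaffoldSimilarity))
    cat("  scaffold similarity:",
        paste(names(object@scaffoldSimilarity),
              sprintf("%.4f", object@scaffoldSimilarity), sep = "=",
              collapse = " "), "\n")
  if (length(object@propertyDistances))
    cat("  property W1:",
        paste(names(object@propertyDistances),
              sprintf("%.3f", object@propertyDistances), sep = "=",
              collapse = " "), "\n")
})
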