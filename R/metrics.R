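# Generation-quality metric suite (MOSES conventions): validity, Unique@K,
# novelty, Tanimoto internal diversity, Bemis-Murcko scaffold cosine
# similarity, and 1-D Wasserstein property distances. All set metrics
# operate on the valid subset, in canonical form.

#' Fraction of generated strings that are valid molecules
#'
#' A generated string counts as valid when it parses and perceives as a
#' chemically consistent molecule (valence and aromatic-ring consistency per
#' the toolkit). Also returns the canonical valid subset, in generation
#' order, which downstream metrics consume.
#'
#' @param smiles character vector of generated SMILES (set G).
#' @return list with \code{validity} (fraction) and \code{validSubset}
#'   (canonical SMILES of the valid members, generation order).
#' @examples
#' validityFraction(c("CCO", "C1CC"))$validity   # 0.5
#' @export
validityFraction <- function(smiles) {
  if (!length(smiles)) stop("empty generated set")
  can <- canonicalizeSmiles(smiles, onInvalid = "na")
  list(validity = mean(!is.na(can)), validSubset = can[!is.na(can)])
}

#' Unique@K: distinct fraction among the first K valid molecules
#'
#' Counts distinct canonical molecules among the first K valid members of
#' the generated set (generation order) and divides by K. When fewer than K
#' valid molecules exist, uniqueness is computed over all of them. The
#' benchmark convention is K = 10000.
#'
#' @param validSmiles canonical SMILES of the valid subset, generation
#'   order (see [validityFraction()]).
#' @param K cutoff; default 10000.
#' @return fraction in (0, 1].
#' @examples
#' uniqueAtK(rep("CCO", 10), K = 10)   # 0.1
#' @export
uniqueAtK <- function(validSmiles, K = 10000L) {
  stopifnot(K >= 1L)
  if (!length(validSmiles)) stop("no valid molecules")
  head <- validSmiles[seq_len(min(K, length(validSmiles)))]
  length(unique(head)) / length(head)
}

#' Novelty: fraction of valid molecules absent from the training set
#'
#' Membership is decided on canonical SMILES, so spelling variants of a
#' training molecule do not count as novel.
#'
#' @param validSmiles canonical SMILES of the valid generated subset.
#' @param trainSmiles training-set SMILES (canonicalized internally).
#' @return fraction in [0, 1].
#' @examples
#' novelty(c("CCO", "CCN"), "CCO")   # 0.5
#' @export
novelty <- function(validSmiles, trainSmiles) {
  if (!length(validSmiles)) stop("no valid molecules")
  trainCan <- unique(canonicalizeSmiles(trainSmiles, onInvalid = "na"))
  mean(!(validSmiles %in% trainCan))
}

#' Tanimoto similarity between two molecules
#'
#' Jaccard similarity of binary circular-substructure fingerprints
#' (radius 2, 1024 bits; see [circularFingerprints()]).
#'
#' @param smiles1,smiles2 single SMILES strings.
#' @return similarity in [0, 1].
#' @examples
#' tanimotoSimilarity("CCO", "CCO")   # 1
#' @export
tanimotoSimilarity <- function(smiles1, smiles2) {
  fp <- circularFingerprints(c(smiles1, smiles2))
  if (anyNA(fp)) invalidMolecule(c(smiles1, smiles2)[apply(is.na(fp), 1, any)])
  a <- fp[1, ]; b <- fp[2, ]
  un <- sum(a + b > 0)
  if (un == 0) return(0)
  sum(a * b) / un
}

# Pairwise Tanimoto matrix from a binary fingerprint matrix (n x bits).
.tanimotoMatrix <- function(fp) {
  inter <- fp %*% t(fp)
  card <- rowSums(fp)
  un <- outer(card, card, "+") - inter
  Tm <- ifelse(un > 0, inter / un, 0)
  diag(Tm)[card == 0] <- 0   # empty fingerprints: define T = 0 even to self
  Tm
}

#' Internal diversity of a molecule set
#'
#' IntDivP(G) = 1 - (1/|G|^2) * sum over all ordered pairs (m1, m2),
#' self-pairs included, of T(m1, m2)^p -- the printed double-sum convention.
#' Setting \code{includeSelfPairs = FALSE} switches to the off-diagonal
#' variant used by some reference implementations.
#'
#' @param smiles valid SMILES of the set (canonical or not).
#' @param p similarity power, 1 or 2.
#' @param includeSelfPairs include the diagonal (default TRUE)?
#' @return diversity in [0, 1].
#' @examples
#' internalDiversity(c("CCO", "CCO"), p = 1)   # 0 (all pairs identical)
#' @export
internalDiversity <- function(smiles, p = 1, includeSelfPairs = TRUE) {
  stopifnot(p %in% c(1, 2))
  if (!length(smiles)) stop("empty set")
  fp <- circularFingerprints(smiles)
  if (anyNA(fp)) invalidMolecule(smiles[apply(is.na(fp), 1, any)])
  Tm <- .tanimotoMatrix(fp)^p
  n <- length(smiles)
  if (includeSelfPairs) {
    1 - sum(Tm) / n^2
  } else {
    if (n == 1L) return(0)
    1 - (sum(Tm) - sum(diag(Tm))) / (n * (n - 1))
  }
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The molecular framework: ring systems plus the linkers connecting them,
#' with side chains removed; atoms double- or triple-bonded directly to the
#' framework (e.g. a carbonyl oxygen on a linker) are retained. Acyclic
#' molecules map to the empty scaffold "".
#'
#' @param smiles a single SMILES string.
#' @return canonical scaffold SMILES ("" for acyclic molecules).
#' @examples
#' murckoScaffold("Cc1ccccc1")   # "c1ccccc1"
#' murckoScaffold("CCO")         # ""
#' @export
murckoScaffold <- function(smiles) {
  g <- smilesToGraph(smiles)
  n <- g@nNodes
  if (n == 0L || !ncol(g@edgeIndex)) return("")
  # iteratively strip terminal atoms -> framework (rings + linkers)
  keep <- rep(TRUE, n)
  undirected <- g@edgeIndex[, g@edgeIndex[1, ] < g@edgeIndex[2, ], drop = FALSE] + 1L
  repeat {
    deg <- tabulate(c(undirected[1, keep[undirected[1, ]] & keep[undirected[2, ]]],
                      undirected[2, keep[undirected[1, ]] & keep[undirected[2, ]]]),
                    nbins = n)
    leaf <- keep & deg <= 1L
    if (!any(leaf)) break
    keep[leaf] <- FALSE
    if (!any(keep)) return("")
  }
  # add back atoms multiply-bonded directly to the framework
  u <- g@edgeIndex[1, ] + 1L; v <- g@edgeIndex[2, ] + 1L
  multi <- g@edgeTypes %in% c(1L, 2L)
  attach <- u[multi & keep[v] & !keep[u]]
  keep[attach] <- TRUE
  sub <- .inducedSubgraph(g, which(keep))
  graphToSmiles(sub)
}

# scaffold frequency table (named counts), empty scaffolds excluded
.scaffoldCounts <- function(smiles) {
  sc <- vapply(smiles, murckoScaffold, "", USE.NAMES = FALSE)
  nEmpty <- sum(!nzchar(sc))
  if (nEmpty)
    message(nEmpty, " acyclic molecule(s) with empty scaffold excluded ",
            "from the scaffold frequency vector")
  table(sc[nzchar(sc)])
}

#' Scaffold cosine similarity between two molecule sets
#'
#' Cosine similarity between the Bemis-Murcko scaffold frequency vectors of
#' the two sets over the union of their scaffolds. Sets with disjoint
#' scaffolds score 0; identical sets score 1. Empty (acyclic) scaffolds are
#' excluded from the scaffold universe.
#'
#' @param smilesG,smilesR valid SMILES of the generated and reference sets.
#' @return cosine similarity in [0, 1].
#' @export
scaffoldSimilarity <- function(smilesG, smilesR) {
  if (!length(smilesG) || !length(smilesR)) stop("both sets must be non-empty")
  cg <- .scaffoldCounts(smilesG)
  cr <- .scaffoldCounts(smilesR)
  S <- union(names(cg), names(cr))
  if (!length(S)) {
    message("no ring-containing scaffolds in either set; similarity 0")
    return(0)
  }
  vg <- as.numeric(cg[S]); vg[is.na(vg)] <- 0
  vr <- as.numeric(cr[S]); vr[is.na(vr)] <- 0
  ng <- sqrt(sum(vg^2)); nr <- sqrt(sum(vr^2))
  if (ng == 0 || nr == 0) {
    message("all-zero scaffold frequency vector; similarity 0")
    return(0)
  }
  sum(vg * vr) / (ng * nr)
}

#' First-order Wasserstein distance between 1-D samples
#'
#' W1 between the two empirical distributions: the integral of
#' |F_a - F_b| over the real line.
#'
#' @param a,b non-empty numeric samples.
#' @return distance >= 0.
#' @examples
#' wasserstein1d(0, 3)   # 3
#' @export
wasserstein1d <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  av <- sort(a); bv <- sort(b)
  allv <- sort(c(av, bv))
  if (length(allv) < 2L) return(0)
  grid <- allv[-length(allv)]
  d <- diff(allv)
  Fa <- findInterval(grid, av) / length(av)
  Fb <- findInterval(grid, bv) / length(bv)
  sum(d * abs(Fa - Fb))
}

#' Evaluate a generated set against reference sets
#'
#' Assembles the full metric report: validity, Unique@K, novelty versus the
#' training set, internal diversity (p = 1, 2), scaffold cosine similarity
#' against the scaffold test set (and the test set), and Wasserstein
#' distances between generated and test-set property distributions
#' (MW, logP, QED, SA).
#'
#' @param generated character vector of generated SMILES (set G).
#' @param train training-set SMILES (novelty reference).
#' @param test test-set SMILES (property-distribution reference).
#' @param scaffoldTest scaffold-test SMILES (scaffold-similarity reference);
#'   optional.
#' @param K Unique@K cutoff; default 10000.
#' @param properties which property distributions to compare;
#'   default MW, logP, QED, SA.
#' @return a \code{GenerationMetrics}.
#' @export
evaluateGeneration <- function(generated, train, test = train,
                               scaffoldTest = NULL, K = 10000L,
                               properties = c("MW", "logP", "QED", "SA")) {
  vf <- validityFraction(generated)
  vs <- vf$validSubset
  if (!length(vs)) stop("no valid molecules in the generated set")
  scaf <- c(Test = scaffoldSimilarity(vs, test))
  if (!is.null(scaffoldTest))
    scaf <- c(scaf, TestSF = scaffoldSimilarity(vs, scaffoldTest))
  pd <- numeric(0)
  if (length(properties)) {
    pg <- propertyProfile(unique(vs))
    pt <- propertyProfile(unique(canonicalizeSmiles(test, onInvalid = "na")))
    pd <- vapply(properties, function(p)
      wasserstein1d(pg[[p]][pg$valid], pt[[p]][pt$valid]), 0)
  }
  new("GenerationMetrics",
      validity = vf$validity,
      uniqueAtK = uniqueAtK(vs, K),
      novelty = novelty(vs, train),
      intDiv1 = internalDiversity(vs, p = 1),
      intDiv2 = internalDiversity(vs, p = 2),
      scaffoldSimilarity = scaf,
      propertyDistances = pd,
      nGenerated = length(generated), nValid = length(vs),
      K = as.integer(K))
}
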