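# Molecular descriptors, the corpus filter, QED and a synthetic-
# accessibility heuristic.
#
# MW, logP, HBD/HBA, TPSA and SMARTS counts come from OpenBabel via
# ChemmineOB; ring statistics come from the package's own graph utilities.

#' Apply the dataset admission filter to SMILES
#'
#' Returns TRUE for molecules satisfying every rule: molecular weight inside
#' the window, rotatable bonds and logP under their caps, element set within
#' the allowed organic subset, no ring larger than the cap, and (by default)
#' no formally charged atom. Defaults reproduce the MOSES/ZINC clean-leads
#' rules. Unparseable SMILES signal an \code{invalidMoleculeError}.
#'
#' @param smiles character vector of SMILES.
#' @param rule a \code{CorpusFilterRule}; default [corpusFilterRule()].
#' @return logical vector, same length as the input.
#' @examples
#' corpusFilter("CCO")                      # FALSE (MW below 250)
#' @export
corpusFilter <- function(smiles, rule = corpusFilterRule()) {
  stopifnot(is(rule, "CorpusFilterRule"))
  if (!length(smiles)) return(logical(0))
  desc <- .obDescriptors(smiles, nhohCounts = FALSE)
  graphs <- smilesToGraphs(smiles, onInvalid = "null")
  bad <- vapply(desc, is.null, TRUE) | vapply(graphs, is.null, TRUE)
  if (any(bad)) invalidMolecule(smiles[bad])
  vapply(seq_along(smiles), function(i) {
    d <- desc[[i]]; g <- graphs[[i]]
    d$MW >= rule@mwMin && d$MW <= rule@mwMax &&
      d$rotatableBonds <= rule@maxRotatableBonds &&
      d$logP <= rule@maxLogP &&
      all(g@nodeSymbols %in% setdiff(rule@allowedElements, "H")) &&
      largestRingSize(g) <= rule@maxRingSize &&
      (rule@allowCharged || d$chargedAtoms == 0)
  }, TRUE)
}

# ---- QED -----------------------------------------------------------------

# Asymmetric double sigmoid parameters (a, b, c, d, e, f, dmax) and weights
# of the eight QED descriptors, from the published QED parameterisation.
.QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.990000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140)
)
.QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# Structural-alert SMARTS (a compact subset of the usual undesirable-group
# alerts, restricted to patterns the OpenBabel SMARTS engine handles).
.QED_ALERT_SMARTS <- c(
  "[#6]=[#6]=[#6]",            # allene
  "N=[N+]=[N-]", "N=N",        # azide / azo
  "OO", "SS",                  # peroxide / disulfide
  "[SH]",                      # thiol
  "[CX3H1](=O)",               # aldehyde
  "C(=O)Cl", "C(=O)Br",        # acyl halide
  "[CH2]Cl", "[CH2]Br", "[CH2]I",  # alkyl halide
  "C=[N!R]O",                  # acyclic oxime
  "[N!R]=[N!R]",               # acyclic imine chain
  "C1OC1",                     # epoxide
  "S(=O)(=O)O"                 # sulfonic ester/acid
)

.ads <- function(x, p) {
  p[1] + p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
    (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))
}

.qedFromDescriptors <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts) {
  vals <- c(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd,
            PSA = psa, ROTB = rotb, AROM = arom, ALERTS = alerts)
  d <- vapply(names(vals), function(k) {
    p <- .QED_ADS[[k]]
    max(.ads(vals[[k]], p) / p[7], 0.003)
  }, 0)
  d <- pmin(d, 1)
  w <- .QED_WEIGHTS
  exp(sum(w * log(d)) / sum(w))
}

# ---- synthetic-accessibility heuristic -----------------------------------

# A self-contained 1 (easy) .. 10 (hard) synthetic-accessibility heuristic
# built from molecular complexity terms: size, ring fusion, macrocycles,
# branching and heteroatom load. It is *not* the fragment-database SA score;
# it ranks simple, drug-like molecules low and strained/fused/branched
# structures high and is monotone in each complexity term.
.saHeuristic <- function(g, desc) {
  n <- g@nNodes
  sizeTerm <- max(n - 20, 0) * 0.06
  rs <- ringBondSizes(g)
  ringBonds <- sum(is.finite(rs))
  nRings <- max(0L, as.integer(ncol(g@edgeIndex) / 2L - n + 1L))
  macro <- sum(unique(rs[is.finite(rs)]) > 8) * 1.5
  # fusion: ring atoms shared by >2 ring bonds
  deg <- tabulate(c(g@edgeIndex[1, g@edgeTypes >= 0L] + 1L), nbins = n)
  branching <- sum(deg > 3) * 0.25
  hetero <- sum(!g@nodeSymbols %in% "C") / max(n, 1)
  raw <- 1 + sizeTerm + 0.45 * nRings + macro + branching + 2.2 * hetero
  min(max(raw, 1), 10)
}

#' Physicochemical property profile of molecules
#'
#' Per-molecule descriptor table: molecular weight (g/mol), logP, QED,
#' synthetic-accessibility heuristic, hydrogen-bond donors and acceptors,
#' NH/OH hydrogen count, heavy-atom count, plus TPSA, rotatable bonds and
#' aromatic ring count. Invalid SMILES yield a row of NAs flagged in the
#' \code{valid} column and are excluded from summaries downstream.
#'
#' @param smiles character vector of SMILES.
#' @param alerts logical; screen the structural-alert SMARTS set and feed the
#'   count into QED? Off by default (the alert term is then neutral at 0),
#'   since the screen costs one SMARTS pass per pattern per molecule.
#' @return data.frame with one row per input molecule.
#' @examples
#' propertyProfile("CCO")[, c("MW", "HBD", "heavyAtoms")]
#' @export
propertyProfile <- function(smiles, alerts = FALSE) {
  desc <- .obDescriptors(smiles)
  graphs <- smilesToGraphs(smiles, onInvalid = "null")
  alertCounts <- if (alerts) countStructuralAlerts(smiles) else rep(0L, length(smiles))
  rows <- lapply(seq_along(smiles), function(i) {
    d <- desc[[i]]; g <- graphs[[i]]
    if (is.null(d) || is.null(g))
      return(data.frame(smiles = smiles[i], valid = FALSE, MW = NA_real_,
                        logP = NA_real_, QED = NA_real_, SA = NA_real_,
                        HBD = NA_real_, HBA = NA_real_, NHOH = NA_real_,
                        heavyAtoms = NA_integer_, TPSA = NA_real_,
                        rotatableBonds = NA_real_, aromaticRings = NA_integer_))
    arom <- aromaticRingCount(g)
    data.frame(
      smiles = smiles[i], valid = TRUE,
      MW = d$MW, logP = d$logP,
      QED = .qedFromDescriptors(d$MW, d$logP, d$HBA, d$HBD, d$TPSA,
                                d$rotatableBonds, arom, alertCounts[i]),
      SA = .saHeuristic(g, d),
      HBD = d$HBD, HBA = d$HBA, NHOH = d$nhoh,
      heavyAtoms = g@nNodes, TPSA = d$TPSA,
      rotatableBonds = d$rotatableBonds, aromaticRings = arom
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Count structural alerts for a batch of SMILES (one OB pass per pattern).
countStructuralAlerts <- function(smiles) {
  counts <- rep(0L, length(smiles))
  res <- .obForEach(smiles, function(mol, p) {
    s <- 0L
    for (pat in .QED_ALERT_SMARTS) {
      hit <- tryCatch(
        ChemmineOB::smartsSearch_OB(list(mol), pat, uniqueMatches = TRUE),
        error = function(e) 0)
      s <- s + as.integer(hit > 0)
    }
    s
  })
  for (i in seq_along(res)) if (!is.null(res[[i]])) counts[i] <- res[[i]]
  counts
}
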