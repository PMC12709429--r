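# Low-level wrappers around ChemmineOB / OpenBabel.
#
# OpenBabel reports parse failures by emitting nothing for the offending
# record (plus a C-level stderr warning), so every wrapper here converts
# "no output" into a classed invalidMoleculeError, and batch calls attach an
# index title to every record so that valid records stay aligned after
# failures are dropped (OB option -e = continue on error).

invalidMolecule <- function(smiles) {
  stop(errorCondition(
    paste0("invalid molecule: ", paste(smiles, collapse = ", ")),
    class = c("invalidMoleculeError", "error", "condition")
  ))
}

.obOptions <- function(...) {
  nm <- c(...)
  if (!length(nm)) return(data.frame(names = character(0), args = character(0)))
  data.frame(names = nm, args = rep("", length(nm)), stringsAsFactors = FALSE)
}

# Stereochemistry is outside the representation (no wedge/slash/@ in the
# graph or the token stream): strip it before any parsing. Removing '@'
# inside brackets can leave trivial brackets like [CH] / [C]; un-bracket the
# neutral organic-subset leftovers so OB re-derives implicit hydrogens.
stripStereo <- function(smiles) {
  x <- gsub("[/\\\\]", "", smiles)
  x <- gsub("@", "", x, fixed = TRUE)
  gsub("\\[(C|N|O|S)H?\\]", "\\1", x)
}

# Batch SMILES -> canonical SMILES. Returns a character vector aligned with
# the input; unparseable entries are NA.
.obCanonical <- function(smiles) {
  if (!length(smiles)) return(character(0))
  x <- stripStereo(smiles)
  bad <- !nzchar(x) | grepl("[ \t]", x)
  out <- rep(NA_character_, length(smiles))
  idx <- which(!bad)
  if (length(idx)) {
    src <- paste0(paste0(x[idx], " i", idx, collapse = "\n"), "\n")
    res <- ChemmineOB::convertFormat("SMI", "CAN", src, options = .obOptions("e"))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      ok <- lengths(parts) == 2L
      parts <- parts[ok]
      ids <- as.integer(sub("^i", "", vapply(parts, `[`, "", 2L)))
      out[ids] <- vapply(parts, `[`, "", 1L)
    }
  }
  out
}

#' Canonicalize SMILES strings
#'
#' Maps every input SMILES to its unique canonical form (OpenBabel canonical
#' SMILES), after stripping stereochemistry annotations. Canonicalization is
#' idempotent, so two spellings of the same molecule map to the same string;
#' all set-membership metrics (novelty, uniqueness) operate on canonical
#' forms.
#'
#' @param smiles character vector of SMILES strings.
#' @param onInvalid "error" (default) signals an \code{invalidMoleculeError}
#'   naming the offending string; "na" returns NA for unparseable entries.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO"))   # both "CCO"
#' @export
canonicalizeSmiles <- function(smiles, onInvalid = c("error", "na")) {
  onInvalid <- match.arg(onInvalid)
  out <- .obCanonical(smiles)
  if (onInvalid == "error" && anyNA(out))
    invalidMolecule(smiles[is.na(out)])
  out
}

#' Test whether SMILES strings parse as valid molecules
#'
#' A string is valid when the toolkit parses and perceives it as a molecule
#' (ring closures matched, symbols recognised, aromatic systems consistent).
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, same length as the input.
#' @examples
#' isValidSmiles(c("CCO", "C1CC"))   # TRUE FALSE
#' @export
isValidSmiles <- function(smiles) {
  !is.na(.obCanonical(smiles))
}

# Iterate OpenBabel molecule refs over a batch of SMILES, calling
# fn(molRef) for each parseable entry. Returns a list aligned with the
# input (NULL for unparseable entries). Unparseable records would abort the
# whole OB read loop, so validity is screened first; alignment then uses
# molecule titles.
.obForEach <- function(smiles, fn) {
  x <- stripStereo(smiles)
  out <- vector("list", length(smiles))
  ok <- !is.na(.obCanonical(smiles))
  idx <- which(ok)
  if (!length(idx)) return(out)
  src <- paste0(paste0(x[idx], " i", idx, collapse = "\n"), "\n")
  ChemmineOB::forEachMol("SMILES", src, function(mol) {
    p <- ChemmineOB::prop_OB(mol)
    i <- suppressWarnings(as.integer(sub("^i", "", p$title)))
    if (!is.na(i)) out[[i]] <<- fn(mol, p)
  })
  out
}

# Named descriptor rows (MW, logP, HBD, HBA, TPSA, rotors, charge count,
# NH/OH hydrogen count) for a batch. NULL for invalid entries. The NH/OH
# hydrogen tally costs six SMARTS passes per molecule, so it is optional.
.obDescriptors <- function(smiles, nhohCounts = TRUE) {
  rotSmarts <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"
  .obForEach(smiles, function(mol, p) {
    nhoh <- 0L
    if (nhohCounts) {
      for (h in 1:3) {
        nhoh <- nhoh + h * (
          ChemmineOB::smartsSearch_OB(list(mol), sprintf("[#7H%d]", h), uniqueMatches = TRUE) +
          ChemmineOB::smartsSearch_OB(list(mol), sprintf("[#8H%d]", h), uniqueMatches = TRUE))
      }
    }
    list(
      MW = p$MW, logP = p$logP, HBD = p$HBD, HBA = p$HBA1, TPSA = p$TPSA,
      rotatableBonds = ChemmineOB::smartsSearch_OB(list(mol), rotSmarts, uniqueMatches = TRUE),
      chargedAtoms = ChemmineOB::smartsSearch_OB(list(mol), "[!+0]", uniqueMatches = TRUE),
      nhoh = as.integer(nhoh)
    )
  })
}

# (Circular fingerprints live in R/fingerprints.R, computed on the graph
# representation rather than through fingerprint_OB: the OB fingerprint
# bridge retains per-molecule native memory, which pairwise-similarity
# workloads cannot afford.)
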