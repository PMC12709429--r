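# SMILES <-> MolecularGraph conversion.
#
# Molecules are parsed by OpenBabel; the MOL2 dialect is used as the bridge
# because its bond table carries the perceived aromaticity explicitly
# ("ar" bond type), which maps onto bond code 3. Heavy atoms only; node
# order is SMILES parse order (0-based); every chemical bond contributes a
# forward and a reversed directed column with equal bond codes.

.BOND_CODE <- c("1" = 0L, "2" = 1L, "3" = 2L, "ar" = 3L, "am" = 0L)

# Parse one @<TRIPOS> MOL2 record into a MolecularGraph, or NULL.
.mol2ToGraph <- function(rec) {
  lines <- strsplit(rec, "\n", fixed = TRUE)[[1]]
  sect <- grep("^@<TRIPOS>", lines)
  aStart <- match("@<TRIPOS>ATOM", lines)
  bStart <- match("@<TRIPOS>BOND", lines)
  if (is.na(aStart)) return(NULL)
  # each section ends at the next @<TRIPOS> marker (charged molecules get a
  # UNITY_ATOM_ATTR section between ATOM and BOND)
  sectionEnd <- function(start) {
    nxt <- sect[sect > start]
    if (length(nxt)) nxt[1] - 1L else length(lines)
  }
  atomLines <- grep("^\\s*\\d", lines[seq(aStart + 1L, sectionEnd(aStart))],
                    value = TRUE)
  if (!length(atomLines)) return(NULL)
  atomFields <- strsplit(trimws(atomLines), "\\s+")
  # field 6 is the SYBYL atom type, element before the dot
  syms <- vapply(atomFields, function(f) sub("\\..*$", "", f[6]), "")
  n <- length(syms)
  ei <- matrix(integer(0), nrow = 2)
  et <- integer(0)
  if (!is.na(bStart) && bStart < length(lines)) {
    bondLines <- grep("^\\s*\\d", lines[seq(bStart + 1L, sectionEnd(bStart))],
                      value = TRUE)
    if (length(bondLines)) {
      bf <- strsplit(trimws(bondLines), "\\s+")
      u <- vapply(bf, function(f) as.integer(f[2]), 0L) - 1L
      v <- vapply(bf, function(f) as.integer(f[3]), 0L) - 1L
      ty <- vapply(bf, function(f) f[4], "")
      if (!all(ty %in% names(.BOND_CODE)))
        return(NULL)   # du/un/nc bond types fall outside the representation
      code <- unname(.BOND_CODE[ty])
      ei <- cbind(rbind(u, v), rbind(v, u))
      et <- c(code, code)
    }
  }
  dimnames(ei) <- NULL
  new("MolecularGraph", nodeSymbols = syms, edgeIndex = ei,
      edgeTypes = et, nNodes = as.integer(n))
}

#' Convert SMILES to molecular graphs
#'
#' Converts each molecule into the attributed-graph encoding consumed by the
#' encoder: heavy atoms become nodes in parse order, each chemical bond
#' contributes two directed edge columns (forward and reversed) with equal
#' bond-type codes (single = 0, double = 1, triple = 2, aromatic = 3).
#' Aromaticity follows the toolkit's perception model; kekulized input is
#' re-aromatized before conversion.
#'
#' @param smiles character vector of SMILES strings.
#' @return for \code{smilesToGraph} a single \code{MolecularGraph}; for
#'   \code{smilesToGraphs} a list of them, aligned with the input.
#' @examples
#' g <- smilesToGraph("c1ccccc1")
#' nNodes(g)          # 6
#' table(edgeTypes(g))  # 12 aromatic edges
#' @export
smilesToGraph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  g <- smilesToGraphs(smiles)[[1]]
  if (is.null(g)) invalidMolecule(smiles)
  g
}

#' @rdname smilesToGraph
#' @param onInvalid "error" or "null" (NULL entries for unparseable input).
#' @export
smilesToGraphs <- function(smiles, onInvalid = c("error", "null")) {
  onInvalid <- match.arg(onInvalid)
  out <- vector("list", length(smiles))
  if (!length(smiles)) return(out)
  x <- stripStereo(smiles)
  ok <- nzchar(x) & !grepl("[ \t]", x)
  idx <- which(ok)
  if (length(idx)) {
    src <- paste0(paste0(x[idx], " i", idx, collapse = "\n"), "\n")
    res <- ChemmineOB::convertFormat("SMI", "MOL2", src, options = .obOptions("e"))
    recs <- strsplit(res, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
    recs <- recs[nzchar(trimws(recs))]
    for (rec in recs) {
      lines <- strsplit(rec, "\n", fixed = TRUE)[[1]]
      lines <- lines[nzchar(trimws(lines))]
      title <- trimws(lines[1])
      i <- suppressWarnings(as.integer(sub("^i", "", title)))
      if (is.na(i)) next
      out[[i]] <- .mol2ToGraph(rec)
    }
  }
  if (onInvalid == "error") {
    bad <- vapply(out, is.null, TRUE)
    if (any(bad)) invalidMolecule(smiles[bad])
  }
  out
}

# Serialize a MolecularGraph as an SDF/V2000 molblock. Aromatic bonds are
# written with order 4, which OpenBabel reads back as aromatic.
.graphToMolblock <- function(g) {
  n <- g@nNodes
  ei <- g@edgeIndex
  et <- g@edgeTypes
  keep <- logical(0)
  u <- v <- o <- integer(0)
  if (ncol(ei)) {
    keep <- ei[1, ] < ei[2, ]          # one record per undirected bond
    u <- ei[1, keep] + 1L
    v <- ei[2, keep] + 1L
    o <- c(1L, 2L, 3L, 4L)[et[keep] + 1L]
  }
  lines <- c(
    "molgraph", "  rebuilt from graph", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, length(u)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, g@nodeSymbols),
    if (length(u))
      sprintf("%3d%3d%3d  0  0  0  0", u, v, o),
    "M  END", "$$$$"
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Rebuild a canonical SMILES from a molecular graph
#'
#' Inverts [smilesToGraph()]: the node symbols, edge index and bond codes are
#' reassembled into a molecule (implicit hydrogens restored from standard
#' valence, aromatic systems from code-3 bonds) and canonicalized. For every
#' molecule expressible in the representation,
#' \code{graphToSmiles(smilesToGraph(s))} equals \code{canonicalizeSmiles(s)}.
#'
#' @param graph a \code{MolecularGraph}.
#' @return canonical SMILES string.
#' @examples
#' graphToSmiles(smilesToGraph("OCC"))  # "CCO"
#' @export
graphToSmiles <- function(graph) {
  stopifnot(is(graph, "MolecularGraph"))
  validObject(graph)
  if (graph@nNodes == 0L) return("")
  res <- ChemmineOB::convertFormat("SDF", "CAN", .graphToMolblock(graph))
  out <- trimws(strsplit(res, "\n", fixed = TRUE)[[1]][1])
  out <- sub("\tmolgraph$", "", out)
  out <- strsplit(out, "\t", fixed = TRUE)[[1]][1]
  if (is.na(out) || !nzchar(out))
    stop("graph could not be reassembled into a molecule")
  out
}

# --- pure graph utilities -------------------------------------------------

# Adjacency list (1-based) from the directed edge set.
.adjacency <- function(g) {
  adj <- vector("list", g@nNodes)
  if (ncol(g@edgeIndex)) {
    u <- g@edgeIndex[1, ] + 1L
    v <- g@edgeIndex[2, ] + 1L
    adj <- split(v, factor(u, levels = seq_len(g@nNodes)))
  } else if (g@nNodes > 0) {
    adj <- rep(list(integer(0)), g@nNodes)
  }
  adj
}

# BFS shortest path length between a and b, optionally forbidding the
# direct edge a-b. Inf when unreachable.
.bfsDist <- function(adj, a, b, skipDirect = FALSE) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[a] <- 0
  queue <- a
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    for (y in adj[[x]]) {
      if (skipDirect && x == a && y == b) next
      if (is.infinite(dist[y])) {
        dist[y] <- dist[x] + 1
        if (y == b) return(dist[b])
        queue <- c(queue, y)
      }
    }
  }
  dist[b]
}

# Size of the smallest ring through each undirected bond (Inf for acyclic
# bonds); the max over bonds is the size of the largest relevant ring.
ringBondSizes <- function(g) {
  if (!ncol(g@edgeIndex)) return(numeric(0))
  adj <- .adjacency(g)
  keep <- g@edgeIndex[1, ] < g@edgeIndex[2, ]
  u <- g@edgeIndex[1, keep] + 1L
  v <- g@edgeIndex[2, keep] + 1L
  vapply(seq_along(u), function(k) {
    d <- .bfsDist(adj, u[k], v[k], skipDirect = TRUE)
    if (is.infinite(d)) Inf else d + 1
  }, 0)
}

#' Largest ring size of a molecule graph
#'
#' Size (in atoms) of the largest smallest-ring any bond participates in;
#' 0 for acyclic molecules. Used by the corpus filter's max-ring-size rule.
#'
#' @param graph a \code{MolecularGraph}.
#' @return integer ring size (0 if acyclic).
#' @examples
#' largestRingSize(smilesToGraph("C1CCCCCCCC1"))  # 9
#' @export
largestRingSize <- function(graph) {
  rs <- ringBondSizes(graph)
  rs <- rs[is.finite(rs)]
  if (!length(rs)) 0L else as.integer(max(rs))
}

# Induced subgraph on a 1-based node index set, preserving edge codes.
.inducedSubgraph <- function(g, nodes) {
  nodes <- sort(unique(nodes))
  remap <- integer(g@nNodes)
  remap[nodes] <- seq_along(nodes)
  keep <- logical(ncol(g@edgeIndex))
  if (ncol(g@edgeIndex)) {
    u <- g@edgeIndex[1, ] + 1L
    v <- g@edgeIndex[2, ] + 1L
    keep <- u %in% nodes & v %in% nodes
  }
  ei <- if (any(keep))
    rbind(remap[g@edgeIndex[1, keep] + 1L] - 1L,
          remap[g@edgeIndex[2, keep] + 1L] - 1L)
  else matrix(integer(0), nrow = 2)
  dimnames(ei) <- NULL
  new("MolecularGraph", nodeSymbols = g@nodeSymbols[nodes],
      edgeIndex = ei, edgeTypes = g@edgeTypes[keep],
      nNodes = length(nodes))
}

# Number of independent rings in the subgraph of aromatic (code 3) bonds;
# the cyclomatic number e - n + components of that subgraph.
aromaticRingCount <- function(g) {
  if (!ncol(g@edgeIndex)) return(0L)
  keep <- g@edgeTypes == 3L & g@edgeIndex[1, ] < g@edgeIndex[2, ]
  if (!any(keep)) return(0L)
  u <- g@edgeIndex[1, keep] + 1L
  v <- g@edgeIndex[2, keep] + 1L
  nodes <- sort(unique(c(u, v)))
  remap <- integer(g@nNodes); remap[nodes] <- seq_along(nodes)
  nn <- length(nodes)
  parent <- seq_len(nn)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  comp <- nn
  for (k in seq_along(u)) {
    a <- find(remap[u[k]]); b <- find(remap[v[k]])
    if (a != b) { parent[a] <- b; comp <- comp - 1L }
  }
  as.integer(length(u) - nn + comp)
}
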