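# Deterministic fixture corpora.
#
# A seeded combinatorial enumerator over a scaffold + substituent grammar
# stands in for a large screening corpus: aryl amide / sulfonamide / urea /
# ether scaffolds over the neutral C,N,S,O,F,Cl,Br organic subset, decorated
# with small substituents. The grammar is sized so that, in strict mode,
# every emitted molecule passes the dataset admission filter (MW 250-350,
# rotatable bonds <= 7, logP <= 3.5, rings <= 8 atoms, no charges).

.FIXTURE_TEMPLATES <- c(
  "O=C(Nc1ccc({A})cc1)c1ccc({B})cc1",
  "O=C(Nc1cccc({A})c1)c1ccc({B})cc1",
  "O=C(Nc1ccc({A})cc1)c1ccc({B})cn1",
  "O=S(=O)(Nc1ccc({A})cc1)c1ccc({B})cc1",
  "O=C(c1ccc({A})cc1)N1CCN(c2ccc({B})cc2)CC1",
  "O=C(Nc1ccc({A})cc1)c1ccc({B})s1",
  "O=C(NCc1ccc({A})cc1)c1ccc({B})cc1",
  "O=C(Nc1ccc({A})cc1)Nc1ccc({B})cc1",
  "O=C(N1CCCCC1)c1ccc({A})c({B})c1",
  "O(Cc1ccc({A})cc1)c1ccc({B})cc1",
  "O=C(N1CCOCC1)c1ccc({A})c({B})c1",
  "O=C(Nc1ccc({A})cc1F)c1ccc({B})cc1",
  "O=S(=O)(N1CCN(c2ccc({A})cc2)CC1)c1ccc({B})cc1",
  "O=C(NCCN1CCOCC1)c1ccc({A})c({B})c1",
  "O=C(Nc1ccc(N2CCOCC2)cc1)c1ccc({A})c({B})c1",
  "O=C(NC1CCCCC1)c1ccc({A})c({B})c1",
  "O=C(N(C)Cc1ccc({A})cc1)c1ccc({B})cc1",
  "O=S(=O)(NCc1ccc({A})cc1)c1ccc({B})cc1",
  "O=C(Nc1ccc({A})cc1C)c1ccc({B})cc1",
  "O=C(Nc1ccc2ccccc2c1)c1ccc({A})c({B})c1"
)

.FIXTURE_SUBSTITUENTS <- c(
  "", "F", "Cl", "Br", "C", "CC", "C(C)C", "OC", "OCC", "O", "N",
  "C#N", "NC(C)=O", "S(C)(=O)=O", "C(F)(F)F"
)

.fixtureEnv <- new.env(parent = emptyenv())

# Evaluate expr with a private, restored RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.substitute <- function(template, key, value) {
  if (nzchar(value))
    sub(paste0("{", key, "}"), value, template, fixed = TRUE)
  else
    sub(paste0("({", key, "})"), "", template, fixed = TRUE)
}

# Enumerate, canonicalize, de-duplicate and (strict mode) filter the whole
# grammar. Deterministic; memoised per mode.
.fixturePool <- function(strict = TRUE, rule = corpusFilterRule()) {
  key <- paste0("pool_", strict)
  if (!is.null(.fixtureEnv[[key]])) return(.fixtureEnv[[key]])
  combos <- expand.grid(A = .FIXTURE_SUBSTITUENTS, B = .FIXTURE_SUBSTITUENTS,
                        tpl = .FIXTURE_TEMPLATES, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  raw <- vapply(seq_len(nrow(combos)), function(i) {
    .substitute(.substitute(combos$tpl[i], "A", combos$A[i]), "B", combos$B[i])
  }, "")
  can <- canonicalizeSmiles(raw, onInvalid = "na")
  can <- unique(can[!is.na(can)])
  can <- sort(can, method = "radix")
  if (strict) can <- can[corpusFilter(can, rule)]
  .fixtureEnv[[key]] <- can
  can
}

#' Generate a deterministic fixture corpus
#'
#' Draws \code{n} distinct, valid, canonical SMILES from a seeded
#' combinatorial enumerator (aryl scaffold + substituent grammar over the
#' neutral C,N,S,O,F,Cl,Br subset). The same seed always yields the same
#' corpus. In strict mode (default) every molecule passes [corpusFilter()]
#' with the given rule; with \code{strict = FALSE} the whole enumerable
#' space is sampled.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed controlling the draw.
#' @param strict restrict to molecules passing the admission filter?
#' @param rule a \code{CorpusFilterRule} used in strict mode.
#' @return character vector of \code{n} distinct canonical SMILES.
#' @examples
#' generateFixtureCorpus(3, seed = 7)
#' @export
generateFixtureCorpus <- function(n, seed = 1L, strict = TRUE,
                                  rule = corpusFilterRule()) {
  stopifnot(n >= 1)
  pool <- .fixturePool(strict, rule)
  if (n > length(pool))
    stop("requested ", n, " molecules but the fixture grammar can only ",
         "enumerate ", length(pool),
         if (strict) " filter-passing" else "", " distinct molecules")
  .withSeed(seed, sample(pool, n))
}
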