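# SMILES tokenization and vocabulary handling.
#
# Regex tokenization: bracket expressions, the two-letter halogens Cl/Br,
# two-digit ring closures (%nn), and every remaining single character are
# each one token. Character-level splitting would corrupt Cl/Br, so those
# are matched before single characters. Detokenization is plain
# concatenation, which makes the round trip exact by construction.

.SMILES_TOKEN_RE <- "\\[[^][]*\\]|Br|Cl|%[0-9]{2}|."

.PAD_ID <- 1L
.BOS_ID <- 2L
.EOS_ID <- 3L
.UNK_ID <- 4L
.RESERVED_TOKENS <- c("<pad>", "<bos>", "<eos>", "<unk>")

#' Split a SMILES string into tokens
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens whose concatenation is the input.
#' @examples
#' smilesTokens("CCl")  # "C" "Cl"
#' @export
smilesTokens <- function(smiles) {
  stopifnot(length(smiles) == 1L, is.character(smiles))
  if (!nzchar(smiles)) return(character(0))
  m <- gregexpr(.SMILES_TOKEN_RE, smiles)[[1]]
  regmatches(smiles, list(m))[[1]]
}

#' Build a vocabulary from a SMILES corpus
#'
#' The vocabulary covers every token occurring in the corpus plus the four
#' reserved ids (pad, begin, end, unknown). Corpus tokens are sorted
#' lexicographically, so the result is independent of corpus order.
#'
#' @param corpus character vector of SMILES strings (non-empty).
#' @return a \code{SmilesVocabulary}.
#' @examples
#' v <- buildVocabulary(c("CC", "CCO"))
#' vocabTokens(v)
#' @export
buildVocabulary <- function(corpus) {
  if (!length(corpus)) stop("cannot build a vocabulary from an empty corpus")
  toks <- unique(unlist(lapply(corpus, smilesTokens)))
  toks <- sort(toks, method = "radix")   # locale-independent ordering
  new("SmilesVocabulary", tokens = c(.RESERVED_TOKENS, toks))
}

.tokenIds <- function(vocab) {
  ids <- seq_along(vocab@tokens)
  names(ids) <- vocab@tokens
  ids
}

#' Tokenize SMILES to id sequences
#'
#' Each string becomes an integer id vector beginning with the begin-of-
#' sequence id and ending with the single end-of-sequence id. Tokens absent
#' from the vocabulary map to the unknown id (a warning lists them).
#'
#' @param smiles character vector of SMILES strings.
#' @param vocab a \code{SmilesVocabulary}.
#' @return list of integer vectors (one per input string).
#' @examples
#' v <- buildVocabulary("CCO")
#' tokenizeSmiles("CCO", v)[[1]]   # bos C C O eos
#' @export
tokenizeSmiles <- function(smiles, vocab) {
  stopifnot(is(vocab, "SmilesVocabulary"))
  map <- .tokenIds(vocab)
  unknown <- character(0)
  out <- lapply(smiles, function(s) {
    tk <- smilesTokens(s)
    ids <- unname(map[tk])
    if (anyNA(ids)) {
      unknown <<- union(unknown, tk[is.na(ids)])
      ids[is.na(ids)] <- .UNK_ID
    }
    c(.BOS_ID, as.integer(ids), .EOS_ID)
  })
  if (length(unknown))
    warning("tokens outside the vocabulary mapped to <unk>: ",
            paste(unknown, collapse = " "))
  out
}

#' Reassemble a SMILES string from token ids
#'
#' Inverse of [tokenizeSmiles()] for in-vocabulary strings: reserved ids
#' (pad/bos/eos) are dropped, everything after the first end-of-sequence id
#' is ignored, and the remaining tokens are concatenated.
#'
#' @param ids integer vector of token ids.
#' @param vocab a \code{SmilesVocabulary}.
#' @return a SMILES string.
#' @export
detokenizeSmiles <- function(ids, vocab) {
  stopifnot(is(vocab, "SmilesVocabulary"))
  ids <- as.integer(ids)
  eos <- which(ids == .EOS_ID)
  if (length(eos)) ids <- ids[seq_len(eos[1] - 1L)]
  ids <- ids[!(ids %in% c(.PAD_ID, .BOS_ID, .UNK_ID))]
  paste(vocab@tokens[ids], collapse = "")
}

# Pad a list of id vectors into a batch matrix (B x T), pad id on the right.
padTokenMatrix <- function(seqs, maxLen = NULL) {
  L <- vapply(seqs, length, 0L)
  Tmax <- if (is.null(maxLen)) max(L) else maxLen
  if (any(L > Tmax)) stop("sequence longer than maxLen (", Tmax, ")")
  out <- matrix(.PAD_ID, nrow = length(seqs), ncol = Tmax)
  for (i in seq_along(seqs)) if (L[i]) out[i, seq_len(L[i])] <- seqs[[i]]
  out
}

# Structural check for a token sequence: begin id first, an end id present,
# nothing but pad after the first end id.
isWellFormedTokenSequence <- function(ids) {
  ids <- as.integer(ids)
  if (!length(ids) || ids[1] != .BOS_ID) return(FALSE)
  eos <- which(ids == .EOS_ID)
  if (length(eos) < 1L) return(FALSE)
  after <- if (eos[1] < length(ids)) ids[(eos[1] + 1L):length(ids)] else integer(0)
  all(after == .PAD_ID)
}

#' Write / read a vocabulary as JSON
#'
#' @param vocab a \code{SmilesVocabulary}.
#' @param path file path.
#' @return \code{readVocabulary} returns a \code{SmilesVocabulary}.
#' @export
writeVocabulary <- function(vocab, path) {
  stopifnot(is(vocab, "SmilesVocabulary"))
  jsonlite::write_json(list(tokens = vocab@tokens), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SmilesVocabulary", tokens = as.character(x$tokens))
}
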