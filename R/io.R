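# Corpus I/O: plain text (one SMILES per line) and the benchmark CSV
# dialect (a SMILES column, optional SPLIT column with train / test /
# test_scaffolds values).

#' Read a SMILES corpus
#'
#' \code{.csv} paths are read as CSV with a \code{SMILES} column (an
#' optional \code{SPLIT} column selects a subset); anything else is plain
#' text, one SMILES per line (anything after whitespace is treated as a
#' name and dropped).
#'
#' @param path file path.
#' @param split optional value of the \code{SPLIT} column to keep
#'   (e.g. "train", "test", "test_scaffolds"); CSV only.
#' @param keepEmpty keep empty lines as empty strings? Default FALSE;
#'   generated sets use TRUE so that empty generations still count
#'   against validity.
#' @return character vector of SMILES.
#' @export
readSmilesCorpus <- function(path, split = NULL, keepEmpty = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"SMILES" %in% names(df))
      stop("CSV corpus must have a SMILES column: ", path)
    if (!is.null(split)) {
      if (!"SPLIT" %in% names(df))
        stop("split requested but no SPLIT column in ", path)
      df <- df[df$SPLIT == split, , drop = FALSE]
    }
    smiles <- df$SMILES
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    if (!keepEmpty) lines <- lines[nzchar(lines)]
    smiles <- vapply(strsplit(lines, "[ \t]+"), function(f)
      if (length(f)) f[1L] else "", "")
  }
  as.character(smiles)
}

#' Write a SMILES corpus
#'
#' \code{.csv} paths get a \code{SMILES} column (plus \code{SPLIT} when
#' given); anything else is one SMILES per line.
#'
#' @param smiles character vector of SMILES.
#' @param path output path.
#' @param split optional SPLIT value (recycled) for the CSV dialect.
#' @return the path, invisibly.
#' @export
writeSmilesCorpus <- function(smiles, path, split = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(SMILES = smiles, stringsAsFactors = FALSE)
    if (!is.null(split)) df$SPLIT <- split
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(smiles, path)
  }
  invisible(path)
}

#' Write a metrics report as JSON (plus optional descriptor CSV)
#'
#' @param metrics a \code{GenerationMetrics}.
#' @param path JSON output path.
#' @param descriptorTable optional data.frame (e.g. [propertyProfile()]
#'   output) written next to the report as \code{<path>.descriptors.csv}.
#' @return the path, invisibly.
#' @export
writeMetricsReport <- function(metrics, path, descriptorTable = NULL) {
  stopifnot(is(metrics, "GenerationMetrics"))
  obj <- list(
    validity = metrics@validity,
    unique_at_k = metrics@uniqueAtK,
    K = metrics@K,
    novelty = metrics@novelty,
    intdiv1 = metrics@intDiv1,
    intdiv2 = metrics@intDiv2,
    scaffold_similarity = as.list(metrics@scaffoldSimilarity),
    property_wasserstein = as.list(metrics@propertyDistances),
    n_generated = metrics@nGenerated,
    n_valid = metrics@nValid,
    toolkit = paste0("OpenBabel/ChemmineOB ",
                     as.character(utils::packageVersion("ChemmineOB")))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(descriptorTable))
    utils::write.csv(descriptorTable,
                     paste0(tools::file_path_sans_ext(path), ".descriptors.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Write a resolved flat key/value config file
#'
#' Every training / generation run records the configuration it actually
#' used next to its outputs, one \code{key = value} pair per line.
#'
#' @param values named list of scalars.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeResolvedConfig <- function(values, path) {
  lines <- vapply(names(values), function(k)
    paste0(k, " = ", format(values[[k]], scientific = FALSE)), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key/value config file
#'
#' @param path file path with \code{key = value} lines (\code{#} comments
#'   allowed). Values that parse as numbers become numeric.
#' @return named list.
#' @export
readResolvedConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
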