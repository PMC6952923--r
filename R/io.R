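#' Read mature-miRNA sequences from a FASTA file
#'
#' Reads a FASTA file (miRBase-style mature sequences), uppercases, maps T
#' to U (one warning per file), and validates the alphabet, reporting the
#' record id and position of any invalid symbol. Duplicate ids trigger a
#' warning but both records are kept.
#'
#' @param path FASTA file path.
#' @return A \code{Biostrings::RNAStringSet} with the record ids (first
#'   whitespace-delimited token of each header) as names.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- duplicated(ids)
  if (any(dup))
    warning("duplicate FASTA id(s): ",
            paste(unique(ids[dup]), collapse = ", "), " (all records kept)")
  seqs <- toupper(as.character(set))
  if (any(grepl("T", seqs, fixed = TRUE))) {
    warning("T normalized to U in ", path)
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
  }
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c("A", "C", "G", "U"))
    if (length(bad))
      stop(sprintf("record '%s': invalid symbol '%s' at position %d",
                   ids[i], chars[bad[1]], bad[1]))
  }
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector or \code{RNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(sequences, path) {
  if (is.character(sequences))
    sequences <- Biostrings::RNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read a disease expression table
#'
#' CSV with columns \code{mirna_id}, \code{disease}, \code{fc},
#' \code{log2fc}; either of fc/log2fc may be blank but not both (such rows
#' are an error, reported by row). Missing values are completed via
#' fc = 2^log2fc / log2fc = log2(fc).
#'
#' @param path CSV file path.
#' @return The completed data.frame (see \code{\link{completeExpression}}).
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "disease")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("expression CSV lacks column(s): ", paste(miss, collapse = ", "))
  completeExpression(df)
}

# TSV writer shared by the table outputs: fixed column order, 6 significant
# digits on floats, so outputs diff cleanly across runs.
.writeTSV <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a score / regression / decision table as TSV
#'
#' Fixed column order and 6-significant-digit floats make repeated runs
#' byte-identical and diff-able.
#'
#' @param df the table (from \code{\link{scoreTable}},
#'   \code{\link{regressionTable}}, \code{\link{duplicateSummary}} or
#'   \code{\link{diseaseDiscrimination}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(df, path) .writeTSV(df, path)

#' Raw-score regression table for a mature FASTA file
#'
#' Convenience pipeline for the whole-corpus analysis: read a mature-miRNA
#' FASTA (e.g. the human subset of a miRBase mature release), score every
#' sequence, and run the with-intercept axis-pair regressions per scoring
#' method. With the miRBase Release 22.1 human mature file this reproduces
#' the published VS slopes (1.04 / 0.86 / 1.10).
#'
#' @param path FASTA path.
#' @param methods,structures passed to \code{\link{scoreTable}}.
#' @param uniqueOnly regress unique score triples only.
#' @return list with \code{scores} (score table), \code{regressions}
#'   (regression table) and \code{duplicates} (duplicate summary).
#' @export
matureFastaRegressionTable <- function(path,
                                       methods = c("VS", "Sum", "EV_C",
                                                   "EV_S"),
                                       structures = c("A", "B", "C"),
                                       uniqueOnly = FALSE) {
  seqs <- readFasta(path)
  sc <- scoreTable(seqs, methods = methods, structures = structures)
  list(scores = sc,
       regressions = regressionTable(sc, throughOrigin = FALSE,
                                     uniqueOnly = uniqueOnly),
       duplicates = duplicateSummary(sc))
}
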