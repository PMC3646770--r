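# Readers and writers for the plain-text formats the pipeline exchanges:
# 12-column tabular similarity-search output, annotation TSVs, allele-count
# pileups, and generic TSV/FASTA helpers.

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular similarity-search hit table
#'
#' The standard tabular layout (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore), tab-separated, no header,
#' 1-based inclusive coordinates.
#'
#' @param path File path.
#' @return data.frame with the standard column names.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), HIT_COLUMNS))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad))
    stop("malformed hit table row (expected 12 fields) at line ", bad[1],
         " of ", path)
  m <- do.call(rbind, parts)
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  num_cols <- c(pident = 3, length = 4, mismatch = 5, gapopen = 6,
                qstart = 7, qend = 8, sstart = 9, send = 10,
                evalue = 11, bitscore = 12)
  for (nm in names(num_cols)) {
    v <- suppressWarnings(as.numeric(m[, num_cols[[nm]]]))
    if (anyNA(v))
      stop("non-numeric '", nm, "' in hit table at line ",
           which(is.na(v))[1], " of ", path)
    df[[nm]] <- v
  }
  validate_hits(df)
  df
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  missing <- setdiff(HIT_COLUMNS, names(hits))
  if (length(missing))
    stop("hit table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(hits)) {
    if (any(hits$evalue < 0)) stop("negative evalue in hit table")
    if (any(hits$bitscore <= 0)) stop("non-positive bitscore in hit table")
  }
  invisible(hits)
}

#' Write a hit table in the 12-column tabular layout
#' @param hits data.frame as returned by \code{\link{read_hit_table}}.
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  validate_hits(hits)
  utils::write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an annotation table
#'
#' Tab-separated with header: transcript_id, protein_accession, gene_name,
#' go_terms (semicolon-joined GO ids, possibly empty).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("transcript_id", "protein_accession", "gene_name", "go_terms")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    stop("duplicate transcript_id in annotation table ", path)
  df$go_terms[is.na(df$go_terms)] <- ""
  df
}

#' Read an allele-count pileup table
#'
#' Tab-separated with header: contig, pos (0-based), countA, countC, countG,
#' countT, countDel, countIns.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "countA", "countC", "countG", "countT",
            "countDel", "countIns")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("pileup lacks columns: ", paste(missing, collapse = ", "))
  df
}

#' Write a data.frame as a TSV with header
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequences as 80-column-wrapped FASTA
#' @param x DNAStringSet or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet"))
    x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a FASTA file as a DNAStringSet
#' @param path File path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  names(x) <- sub("\\s.*$", "", names(x))
  x
}
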