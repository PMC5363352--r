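# Standard-format I/O: FASTA via Biostrings, BED via rtracklayer (0-based
# half-open on disk, 1-based inclusive in memory), TSV matrices at full
# precision, JSON reports via jsonlite.

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write 1-based inclusive intervals to a BED file
#'
#' Conversion to BED's 0-based half-open convention is delegated to
#' rtracklayer's exporter from a `GRanges`; this function is the single
#' audited coordinate bridge in the package.
#'
#' @param intervals Data.frame with `start`, `end` (1-based inclusive) and
#'   optionally `name`, `score`.
#' @param path Output file.
#' @param chrom Chromosome/sequence label for all rows (default "unit").
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, chrom = "unit") {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end))
  if (!is.null(intervals$name)) names(gr) <- intervals$name
  if (!is.null(intervals$score)) gr$score <- intervals$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path BED file.
#' @return Data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a numeric matrix as TSV at full precision
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces doubles exactly.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(vapply(seq_len(ncol(m)), function(j)
    sprintf("%.17g", m[, j]), character(nrow(m))), stringsAsFactors = FALSE)
  if (nrow(m) == 1L) df <- as.data.frame(t(df), stringsAsFactors = FALSE)
  names(df) <- colnames(m)
  df <- cbind(sample_id = rownames(m), df, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- load_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Load a TSV table with per-line validation
#'
#' Rejects ragged files, naming the first offending line.
#'
#' @param path TSV file with a header line.
#' @return Data.frame.
#' @export
load_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("malformed row in %s at line %d: expected %d fields, found %d",
                 path, bad[1], nf[1], nf[bad[1]]), call. = FALSE)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a calls data.frame as TSV
#'
#' @param calls Data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
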