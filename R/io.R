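#' Plain-text readers and writers
#'
#' Counts, sample sheets, TSS tables, peak tag tables and truth records
#' travel as TSV; promoters and region sequences as FASTA (via
#' Biostrings); peaks as BED6 with 0-based half-open coordinates.
#'
#' @name io
NULL

#' @rdname io
#' @param counts Gene x sample integer matrix.
#' @param path File path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname io
#' @param df Data frame to write (sample sheet, TSS table, truth, ...).
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname io
#' @param peaks Peak data frame (`id`, `chrom`, `start`, `end`, optional
#'   `score`, `strand`).
#' @export
write_bed <- function(peaks, path) {
  peaks <- .check_peaks(peaks)
  bed <- data.frame(chrom = peaks$chrom,
                    start = peaks$start,
                    end = peaks$end,
                    name = peaks$id,
                    score = if (is.null(peaks$score)) 0 else peaks$score,
                    strand = if (is.null(peaks$strand)) "."
                             else peaks$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param one_based Set TRUE for interval tables exported 1-based
#'   inclusive; starts are shifted back to the BED 0-based half-open
#'   convention on read.
#' @export
read_bed <- function(path, one_based = FALSE) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "id"
  else bed$id <- paste0("peak", seq_len(nrow(bed)))
  if (ncol(bed) >= 5) names(bed)[5] <- "score"
  if (ncol(bed) >= 6) names(bed)[6] <- "strand"
  if (one_based) bed$start <- bed$start - 1L
  bed[, c("id", "chrom", "start", "end",
          intersect(c("score", "strand"), names(bed)))]
}

#' @rdname io
#' @param genes Character vector of gene ids, one per line.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname io
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}
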