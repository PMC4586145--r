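# Readers and writers for the plain-text interchange formats used across
# the pipeline: wrapped FASTA, Phred+33 FASTQ with constant quality, TSV
# matrices and tables.

#' Read and write transcript FASTA
#'
#' Thin wrappers over Biostrings tolerant of wrapped lines and mixed case;
#' FASTA is written wrapped at 80 columns.
#'
#' @param path file path.
#' @param seqs named `DNAStringSet`.
#' @return `readFasta()` a named `DNAStringSet`; writers return the path
#'   invisibly.
#' @export
readFasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname readFasta
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read and write FASTQ (Phred+33)
#'
#' Simulated reads are written with constant quality `"I"` (Q40). Reading
#' discards qualities, which no downstream step uses.
#'
#' @param path file path.
#' @param reads named `DNAStringSet`.
#' @export
readFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(
    vapply(Biostrings::width(reads),
           function(w) paste(rep("I", w), collapse = ""), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Write a synthetic read-pair set as two FASTQ files
#'
#' @param pairs list with `mate1`, `mate2` from [generateReadPairs()].
#' @param prefix output prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return character vector of the two paths, invisibly.
#' @export
writeReadPairs <- function(pairs, prefix) {
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  writeFastq(pairs$mate1, p1)
  writeFastq(pairs$mate2, p2)
  invisible(c(p1, p2))
}

#' Read and write expression matrices as TSV
#'
#' The TSV carries sample ids in the header and transcript ids in the
#' first column (`transcript_id`). Values are written with six significant
#' digits.
#'
#' @param path file path.
#' @param state transform state to tag the matrix with on read.
#' @param m an [ExpressionMatrix].
#' @export
readExpressionMatrix <- function(path, state = "counts") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "transcript_id")
    .stopf("first column must be 'transcript_id'")
  v <- as.matrix(df[-1L])
  rownames(v) <- df$transcript_id
  ExpressionMatrix(v, state = state)
}

#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(m, path) {
  v <- exprValues(m)
  df <- data.frame(transcript_id = rownames(v),
                   signif(v, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-transcript tau scores as TSV
#'
#' @param tau named numeric vector from [tauScores()].
#' @param path file path.
#' @export
writeTauScores <- function(tau, path) {
  utils::write.table(
    data.frame(transcript_id = names(tau), tau = signif(tau, 6)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster membership table as TSV
#'
#' Long format: one row per member, columns `cluster_id`, `member_id`,
#' `representative` (logical).
#'
#' @param clusters a [HomologClusterSet].
#' @param path file path.
#' @export
writeClusters <- function(clusters, path) {
  mem <- clusterMembers(clusters)
  rep_ <- clusterRepresentatives(clusters)
  df <- data.frame(
    cluster_id = rep(names(mem), lengths(mem)),
    member_id = unlist(mem, use.names = FALSE),
    stringsAsFactors = FALSE)
  df$representative <- df$member_id == rep_[df$cluster_id]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample transcript FASTA files from a directory
#'
#' Every `*.fa` / `*.fasta` file is read as one sample; the sample id is
#' the file name without extension.
#'
#' @param dir directory path.
#' @return named list of `DNAStringSet`s.
#' @export
readSampleFastas <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  if (!length(files)) .stopf("no FASTA files found in %s", dir)
  out <- lapply(files, readFasta)
  names(out) <- sub("\\.(fa|fasta)$", "", basename(files))
  out
}
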