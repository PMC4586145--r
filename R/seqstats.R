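#' Percent GC content of nucleotide sequences
#'
#' GC percent is the number of G and C occurrences divided by the full
#' sequence length, times 100, rounded to two decimal places (round half to
#' even). Matching is case-insensitive; `N` and other ambiguity codes count
#' toward the length but never toward the GC numerator, so results on
#' gap-containing assemblies are reproducible.
#'
#' @param sequence character vector of nucleotide strings, or a
#'   [Biostrings::DNAStringSet].
#' @return numeric vector of GC percentages, two decimals.
#' @examples
#' gcPercent(c("GGCC", "AATT", "ACGTACGTAC"))  # 100, 0, 50
#' @export
gcPercent <- function(sequence) {
  if (is(sequence, "XStringSet")) sequence <- as.character(sequence)
  if (!is.character(sequence) || length(sequence) == 0L)
    .stopf("sequence must be a non-empty character vector or DNAStringSet")
  if (any(!nzchar(sequence)))
    .stopf("empty sequence has no defined GC content")
  s <- Biostrings::BStringSet(toupper(sequence))
  gc <- Biostrings::letterFrequency(s, letters = c("G", "C"))
  round(100 * rowSums(gc) / Biostrings::width(s), 2)
}

#' Joint GC content of a read pair
#'
#' The GC percent of the two mates taken together, i.e. of their
#' concatenation, which weights each mate by its length. Used by the
#' GC-based read enrichment filter.
#'
#' @param mate1,mate2 character vectors (or `DNAStringSet`s) of equal
#'   length; element i of each is one pair.
#' @return numeric vector of pair GC percentages, two decimals.
#' @examples
#' readPairGC("ACGT", "ATAT")  # 25
#' @seealso [filterReadsByGC()]
#' @export
readPairGC <- function(mate1, mate2) {
  if (is(mate1, "XStringSet")) mate1 <- as.character(mate1)
  if (is(mate2, "XStringSet")) mate2 <- as.character(mate2)
  if (length(mate1) != length(mate2))
    .stopf("mate vectors differ in length (%d vs %d)",
           length(mate1), length(mate2))
  if (any(!nzchar(mate1)) || any(!nzchar(mate2)))
    .stopf("empty mate sequence")
  gcPercent(paste0(mate1, mate2))
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L together contain
#' at least half of the total bases: sort descending, accumulate until the
#' running sum reaches half the total, return the length reached.
#'
#' @param lengths positive numeric vector of sequence lengths.
#' @return a single length (always an element of `lengths`).
#' @examples
#' n50(c(40, 30, 20, 10))  # 30
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) .stopf("n50 of an empty length set is undefined")
  if (any(lengths <= 0)) .stopf("lengths must be positive")
  s <- sort(unname(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Per-transcript summary statistics
#'
#' @param seqs a named [Biostrings::DNAStringSet] of transcripts.
#' @param sample sample id(s) of origin, recycled along `seqs`.
#' @return data.frame with columns id, sample, length, gc.
#' @export
transcriptStats <- function(seqs, sample = NA_character_) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    .stopf("transcripts must carry unique names")
  data.frame(
    id = names(seqs),
    sample = rep_len(sample, length(seqs)),
    length = Biostrings::width(seqs),
    gc = gcPercent(seqs),
    row.names = NULL
  )
}
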