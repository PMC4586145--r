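# Internal helpers: seed-stream derivation and small sequence utilities.

# Every generator op draws from its own stream derived from the root seed by
# a fixed affine map modulo the Mersenne prime 2^31 - 1, so ops are
# individually reproducible and adding transcripts to one stage never
# perturbs another.
.STREAMS <- c(transcripts = 1L, expression = 2L, reads = 3L,
              families = 4L, spike = 5L)

.streamSeed <- function(seed, stream) {
  offset <- .STREAMS[[stream]]
  as.integer((abs(seed) * 48271 + offset * 16807) %% 2147483647)
}

.setStream <- function(seed, stream) {
  set.seed(.streamSeed(seed, stream))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Draw one random sequence of length len with i.i.d. bases,
# P(G) = P(C) = gc/200. gc is a percent in [0, 100].
.randSeq <- function(len, gc) {
  p <- gc / 200
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(p, p, (1 - 2 * p) / 2, (1 - 2 * p) / 2)),
        collapse = "")
}

.sampleIds <- function(n) sprintf("S%02d", seq_len(n))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
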