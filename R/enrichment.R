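#' Keep read pairs at or above a joint GC threshold
#'
#' A pair is retained when the GC percent of the two mates taken together
#' (see [readPairGC()]) is greater than or equal to `threshold` — the
#' inclusive bound means a pair at exactly the threshold is kept. Mates
#' must be synchronized: same ids in the same order.
#'
#' @param mate1,mate2 named `DNAStringSet`s (or paths to FASTQ files) of
#'   the two mate streams.
#' @param threshold GC percent bound (default 46).
#' @return list with `mate1`, `mate2` (filtered, pairing preserved) and
#'   `report` (a [FilterReport]).
#' @export
filterReadsByGC <- function(mate1, mate2, threshold = 46) {
  if (is.character(mate1)) mate1 <- readFastq(mate1)
  if (is.character(mate2)) mate2 <- readFastq(mate2)
  if (length(mate1) != length(mate2))
    .stopf("mate files differ in read count (%d vs %d)",
           length(mate1), length(mate2))
  if (length(mate1)) {
    mism <- names(mate1) != names(mate2)
    if (any(mism))
      .stopf("desynchronized mates at pair %d: '%s' vs '%s'",
             which(mism)[1L], names(mate1)[which(mism)[1L]],
             names(mate2)[which(mism)[1L]])
  }
  gc <- if (length(mate1)) readPairGC(mate1, mate2) else numeric(0)
  keep <- gc >= threshold
  report <- FilterReport(length(mate1), sum(keep),
                         params = list(threshold = threshold))
  list(mate1 = mate1[keep], mate2 = mate2[keep], report = report)
}

#' Remove transcripts sharing exact stretches across many samples
#'
#' A transcript is removed when transcripts carrying an identical stretch
#' of at least `k` nucleotides (on either strand) occur in at least
#' `minSamples` distinct samples — the transcript's own sample counts
#' toward that tally by default. Broadly shared exact sequence across
#' per-sample assemblies is the signature of the ubiquitously expressed
#' host background, whereas symbiont transcripts are confined to few
#' samples.
#'
#' Implementation: two sequences share an exact stretch of length >= k if
#' and only if they share a k-mer, so a canonical (strand-symmetric) k-mer
#' index is lossless for this rule. K-mers containing `N` never match.
#' Transcripts shorter than `k` cannot match and are always retained.
#'
#' @param seqs named `DNAStringSet` of transcripts pooled over samples.
#' @param samples character vector of sample ids, parallel to `seqs`.
#' @param k exact-match length (default 100).
#' @param minSamples minimum number of distinct samples (default 5).
#' @param includeSelf count the transcript's own sample (default TRUE).
#' @return list with `retained`, `removed` (character id vectors) and
#'   `report` (a [FilterReport] with per-sample breakdown).
#' @export
crossSampleIdentityFilter <- function(seqs, samples, k = 100,
                                      minSamples = 5, includeSelf = TRUE) {
  if (k < 1) .stopf("k must be at least 1")
  if (length(samples) != length(seqs))
    .stopf("samples must parallel seqs")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    .stopf("transcripts must carry unique names")
  w <- Biostrings::width(seqs)
  tooShort <- w < k
  if (any(tooShort))
    message(sprintf("%d transcript(s) shorter than k = %d: trivially retained",
                    sum(tooShort), k))
  nshare <- stats::setNames(rep.int(0L, length(seqs)), ids)
  idx <- which(!tooShort)
  if (length(idx)) {
    chr <- toupper(as.character(seqs[idx]))
    nk <- nchar(chr) - k + 1L
    kmers <- unlist(lapply(seq_along(chr), function(i)
      substring(chr[i], seq_len(nk[i]), seq_len(nk[i]) + k - 1L)),
      use.names = FALSE)
    tid <- rep(ids[idx], nk)
    smp <- rep(samples[idx], nk)
    valid <- !grepl("[^ACGT]", kmers)
    kmers <- kmers[valid]; tid <- tid[valid]; smp <- smp[valid]
    if (length(kmers)) {
      rc <- .revcomp(kmers)
      canon <- ifelse(kmers <= rc, kmers, rc)
      DT <- data.table::data.table(kmer = canon, tid = tid, smp = smp)
      DT <- unique(DT)
      occ <- unique(DT[, c("kmer", "smp")])
      hits <- merge(DT[, c("kmer", "tid")], occ, by = "kmer",
                    allow.cartesian = TRUE)
      if (!includeSelf) {
        own <- stats::setNames(samples, ids)
        hits <- hits[hits$smp != own[hits$tid], ]
      }
      cnt <- hits[, list(n = length(unique(smp))), by = "tid"]
      nshare[cnt$tid] <- cnt$n
    }
  }
  removed <- ids[nshare >= minSamples]
  retained <- setdiff(ids, removed)
  perSample <- data.frame(sample = samples, removed = ids %in% removed)
  perSample <- stats::aggregate(removed ~ sample, perSample, sum)
  report <- FilterReport(length(seqs), length(retained),
                         params = list(k = k, minSamples = minSamples,
                                       includeSelf = includeSelf),
                         perSample = perSample)
  list(retained = retained, removed = removed, report = report)
}
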