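#' Generate a synthetic dual-population transcript set
#'
#' Draws host-like and symbiont-like transcripts whose GC and length
#' distributions follow the configured per-population parameters: each
#' transcript gets a target GC percent from a truncated normal, a length
#' from a log-normal, and a sequence with i.i.d. bases at
#' `P(G) = P(C) = gc/200`. Every transcript is assigned a sample of origin
#' uniformly at random. Deterministic for a fixed config seed.
#'
#' @param config a [GeneratorConfig].
#' @return list with `seqs` (named `DNAStringSet`) and `truth` (data.frame
#'   `transcript_id`, `population`, `family_id` (NA here), `sample`).
#' @examples
#' out <- generateTranscripts(GeneratorConfig(nHost = 5, nSymbiont = 5,
#'                                            seed = 3))
#' out$truth$population
#' @export
generateTranscripts <- function(config) {
  validObject(config)
  .setStream(config@seed, "transcripts")
  samples <- .sampleIds(config@nSamples)
  pops <- list(
    host = list(n = config@nHost, gc = config@hostGCMean,
                gcsd = config@hostGCSd, lm = config@hostLenLogMean,
                ls = config@hostLenLogSd),
    symbiont = list(n = config@nSymbiont, gc = config@symbiontGCMean,
                    gcsd = config@symbiontGCSd,
                    lm = config@symbiontLenLogMean,
                    ls = config@symbiontLenLogSd)
  )
  seqs <- character(0)
  truth <- NULL
  for (pop in names(pops)) {
    p <- pops[[pop]]
    gc <- pmin(100, pmax(0, stats::rnorm(p$n, p$gc, p$gcsd)))
    len <- pmax(100L, as.integer(round(stats::rlnorm(p$n, p$lm, p$ls))))
    s <- vapply(seq_len(p$n), function(i) .randSeq(len[i], gc[i]), "")
    ids <- sprintf("%s_%05d", pop, seq_len(p$n))
    names(s) <- ids
    seqs <- c(seqs, s)
    truth <- rbind(truth, data.frame(
      transcript_id = ids, population = pop, family_id = NA_character_,
      sample = sample(samples, p$n, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  list(seqs = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Simulate a count matrix with population-specific expression breadth
#'
#' Host transcripts express in approximately `hostBreadth` of the samples
#' (each sample an independent Bernoulli draw; at least one guaranteed).
#' Symbiont transcripts express only in a small drawn set of samples: the
#' set size is the stochastic rounding of `symbiontBreadth * nSamples`
#' (minimum one), so at the default breadth a symbiont transcript occupies
#' one or two samples and never more — the near-complete sample
#' specificity that separates symbiont from host tau scores. Counts in expressing cells are negative binomial around a
#' per-transcript log-normal base mean (zero draws are bumped to one so an
#' expressing cell is never silent); all other cells are zero.
#'
#' @param truth truth table from [generateTranscripts()].
#' @param config a [GeneratorConfig].
#' @param baseMeans optional named vector overriding the per-transcript
#'   expected count in expressing samples (e.g. all zeros for a silent
#'   matrix).
#' @return list with `matrix` (an [ExpressionMatrix], state `"counts"`) and
#'   `truth` (the input table plus an `expressed_samples` column,
#'   comma-separated sample ids).
#' @export
generateExpression <- function(truth, config, baseMeans = NULL) {
  validObject(config)
  if (nrow(truth) == 0L) .stopf("empty truth table")
  .setStream(config@seed, "expression")
  n <- nrow(truth)
  ns <- config@nSamples
  samples <- .sampleIds(ns)
  if (is.null(baseMeans)) {
    baseMeans <- stats::rlnorm(n, log(100), 1)
    names(baseMeans) <- truth$transcript_id
  } else {
    baseMeans <- baseMeans[truth$transcript_id]
  }
  counts <- matrix(0, n, ns, dimnames = list(truth$transcript_id, samples))
  expressed <- character(n)
  size <- if (config@dispersion > 0) 1 / config@dispersion else Inf
  for (i in seq_len(n)) {
    if (truth$population[i] == "host") {
      on <- which(stats::runif(ns) < config@hostBreadth)
      if (!length(on)) on <- sample.int(ns, 1L)
    } else {
      m <- ns * config@symbiontBreadth
      k <- max(1L, floor(m) + stats::rbinom(1L, 1L, m - floor(m)))
      on <- sort(sample.int(ns, k))
    }
    mu <- baseMeans[i]
    if (mu > 0) {
      x <- if (is.finite(size)) stats::rnbinom(length(on), mu = mu, size = size)
           else stats::rpois(length(on), mu)
      x[x == 0] <- 1
      counts[i, on] <- x
    }
    expressed[i] <- paste(samples[on], collapse = ",")
  }
  truth$expressed_samples <- expressed
  list(matrix = ExpressionMatrix(counts, state = "counts"), truth = truth)
}

#' Simulate paired-end reads from transcripts
#'
#' Fragments are sampled from transcripts with probability proportional to
#' transcript length; the fragment length is normal around `insertMean`
#' (truncated to \[readLen, transcript length\]). Mate 1 is the fragment's
#' first `readLen` bases; mate 2 is the reverse complement of its last
#' `readLen` bases, so the pair's joint GC equals the fragment's GC in
#' expectation. Transcripts shorter than `readLen` are skipped with a
#' warning.
#'
#' @param seqs named `DNAStringSet` of source transcripts.
#' @param nPairs number of read pairs to draw.
#' @param readLen read length in nucleotides.
#' @param insertMean,insertSd fragment-length distribution.
#' @param seed integer seed.
#' @return list with `mate1`, `mate2` (named `DNAStringSet`s, ids
#'   `p<No>`) — write with [writeReadPairs()].
#' @export
generateReadPairs <- function(seqs, nPairs, readLen = 100,
                              insertMean = 300, insertSd = 30, seed = 1) {
  .setStream(seed, "reads")
  w <- Biostrings::width(seqs)
  short <- w < readLen
  if (any(short)) {
    warning(sprintf("%d transcript(s) shorter than readLen skipped",
                    sum(short)))
    seqs <- seqs[!short]
    w <- w[!short]
  }
  if (nPairs == 0L || length(seqs) == 0L) {
    empty <- Biostrings::DNAStringSet(character(0))
    return(list(mate1 = empty, mate2 = empty))
  }
  src <- sample.int(length(seqs), nPairs, replace = TRUE, prob = w)
  frag <- pmin(w[src],
               pmax(readLen, round(stats::rnorm(nPairs, insertMean, insertSd))))
  start <- vapply(seq_len(nPairs), function(i)
    sample.int(w[src[i]] - frag[i] + 1L, 1L), 1L)
  chr <- as.character(seqs)[src]
  f <- substring(chr, start, start + frag - 1L)
  m1 <- substring(f, 1L, readLen)
  m2 <- .revcomp(substring(f, frag - readLen + 1L, frag))
  ids <- sprintf("p%06d", seq_len(nPairs))
  list(mate1 = stats::setNames(Biostrings::DNAStringSet(m1), ids),
       mate2 = stats::setNames(Biostrings::DNAStringSet(m2), ids))
}

#' Generate homologous gene families across pseudo-samples
#'
#' Each family descends from one random ancestor (symbiont-like GC):
#' members are produced by independent per-site substitution at rate
#' `1 - familyIdentity` (substituted sites always change base), a star
#' phylogeny with no indels. Expected pairwise identity between members is
#' therefore about `familyIdentity^2` plus a small coincidence term.
#' Members are dealt round-robin to pseudo-samples.
#'
#' @param config a [GeneratorConfig].
#' @return list with `seqs` (named `DNAStringSet`, ids
#'   `fam<F>_m<M>`) and `truth` (data.frame `transcript_id`, `population`
#'   (`symbiont`), `family_id`, `sample`).
#' @export
generateFamilies <- function(config) {
  validObject(config)
  .setStream(config@seed, "families")
  samples <- .sampleIds(config@nSamples)
  rate <- 1 - config@familyIdentity
  seqs <- character(0)
  truth <- NULL
  bases <- c("A", "C", "G", "T")
  for (f in seq_len(config@nFamilies)) {
    anc <- strsplit(.randSeq(config@familyLen, config@symbiontGCMean), "")[[1]]
    for (m in seq_len(config@familySize)) {
      child <- anc
      hit <- which(stats::runif(length(anc)) < rate)
      if (length(hit)) {
        # substitute to a uniformly chosen different base
        child[hit] <- vapply(child[hit],
                             function(b) sample(setdiff(bases, b), 1L), "")
      }
      id <- sprintf("fam%03d_m%02d", f, m)
      seqs[id] <- paste(child, collapse = "")
      truth <- rbind(truth, data.frame(
        transcript_id = id, population = "symbiont",
        family_id = sprintf("fam%03d", f),
        sample = samples[((m - 1L) %% config@nSamples) + 1L],
        stringsAsFactors = FALSE))
    }
  }
  list(seqs = Biostrings::DNAStringSet(seqs), truth = truth)
}

#' Spike an identical segment into transcripts of several samples
#'
#' Copies one random segment into exactly one transcript in each of
#' `nSamplesShared` samples (overwriting a random window), creating a
#' ground-truth positive set for the cross-sample exact-identity filter.
#'
#' @param seqsBySample named list of `DNAStringSet`s, one per sample.
#' @param segmentLen segment length in nucleotides.
#' @param nSamplesShared number of samples to receive a copy.
#' @param seed integer seed.
#' @return list with `seqsBySample` (modified) and `spiked` (data.frame
#'   `transcript_id`, `sample`).
#' @export
spikeSharedSegments <- function(seqsBySample, segmentLen = 100,
                                nSamplesShared = 5, seed = 1) {
  .setStream(seed, "spike")
  if (nSamplesShared > length(seqsBySample))
    .stopf("nSamplesShared exceeds the number of samples")
  eligible <- vapply(seqsBySample,
                     function(s) any(Biostrings::width(s) >= segmentLen),
                     TRUE)
  if (sum(eligible) < nSamplesShared)
    .stopf("segmentLen %d exceeds every transcript in some required samples",
           segmentLen)
  segment <- .randSeq(segmentLen, 50)
  chosen <- sample(names(seqsBySample)[eligible], nSamplesShared)
  spiked <- NULL
  for (s in chosen) {
    set <- seqsBySample[[s]]
    ok <- which(Biostrings::width(set) >= segmentLen)
    tgt <- ok[sample.int(length(ok), 1L)]
    chr <- as.character(set[[tgt]])
    pos <- sample.int(nchar(chr) - segmentLen + 1L, 1L)
    substr(chr, pos, pos + segmentLen - 1L) <- segment
    set[[tgt]] <- Biostrings::DNAString(chr)
    seqsBySample[[s]] <- set
    spiked <- rbind(spiked, data.frame(transcript_id = names(set)[tgt],
                                       sample = s, stringsAsFactors = FALSE))
  }
  list(seqsBySample = seqsBySample, spiked = spiked)
}
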