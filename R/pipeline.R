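#' Joint-characterisation branch of the partitioning workflow
#'
#' Runs sequence statistics, the expression chain (FPKM, floored log2,
#' all-zero removal, tau), taxonomic assignment with the genome-alignment
#' rescue rule, and the per-class comparison (N50, mean GC, mean tau,
#' Welch test of tau between host and fungi) on one jointly assembled
#' transcript set. Every intermediate artifact is written to `outDir` so
#' stages can be re-run independently; a machine-readable `report.json`
#' summarises the funnel.
#'
#' @param transcripts named `DNAStringSet` or path to a FASTA file.
#' @param counts an [ExpressionMatrix] in state `"counts"` or path to a
#'   counts TSV (see [readExpressionMatrix()]).
#' @param hits protein hits data.frame ([readProteinHits()]) or path;
#'   `NULL` for none (all transcripts start unassigned).
#' @param genomeAlignments alignment summary data.frame
#'   ([readGenomeAlignments()]) or path; `NULL` to skip the rescue rule.
#' @param outDir output directory (created if needed).
#' @param eCutoff e-value cutoff for [topHitTaxon()].
#' @param taxonMap taxon-label lookup for [topHitTaxon()].
#' @param seed integer, echoed into the report (the branch itself is
#'   deterministic).
#' @return the report, invisibly (a named list mirroring `report.json`).
#' @export
runJoint <- function(transcripts, counts, hits = NULL,
                     genomeAlignments = NULL, outDir,
                     eCutoff = 1e-3, taxonMap = defaultTaxonMap(),
                     seed = 1) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(transcripts)) transcripts <- readFasta(transcripts)
  if (is.character(counts)) counts <- readExpressionMatrix(counts, "counts")
  if (is.character(hits)) hits <- readProteinHits(hits)
  if (is.character(genomeAlignments))
    genomeAlignments <- readGenomeAlignments(genomeAlignments)

  stage <- function(name, n) message(sprintf("[joint] %-18s %d", name, n))
  stats_ <- transcriptStats(transcripts)
  stage("transcripts", nrow(stats_))
  utils::write.table(stats_, file.path(outDir, "transcript_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  lengths <- stats::setNames(stats_$length, stats_$id)
  fp <- fpkm(counts, lengths)
  lg <- floorLog2(fp)
  expressed <- dropAllZero(lg)
  stage("expressed", nrow(expressed))
  writeExpressionMatrix(fp, file.path(outDir, "fpkm.tsv"))
  writeExpressionMatrix(expressed, file.path(outDir, "log2fpkm.tsv"))
  tau <- tauScores(expressed)
  writeTauScores(tau, file.path(outDir, "tau.tsv"))

  if (is.null(hits))
    hits <- data.frame(transcript_id = character(), subject_id = character(),
                       evalue = numeric(), bitscore = numeric(),
                       taxon_label = character(), stringsAsFactors = FALSE)
  asg <- topHitTaxon(hits, transcripts = names(transcripts),
                     eCutoff = eCutoff, taxonMap = taxonMap)
  if (!is.null(genomeAlignments))
    asg <- reclassifyUnassigned(asg, genomeAlignments)
  stage("classified", sum(asg$label != "none"))
  utils::write.table(asg, file.path(outDir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- kingdomSummary(asg)
  utils::write.table(comp, file.path(outDir, "kingdom_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  lab <- stats::setNames(asg$label, asg$transcript_id)
  perClass <- lapply(split(stats_$id, lab[stats_$id]), function(ids) {
    tt <- tau[intersect(ids, names(tau))]
    list(n = length(ids),
         n50 = n50(lengths[ids]),
         meanGC = round(mean(stats_$gc[stats_$id %in% ids]), 2),
         meanTau = if (length(tt)) round(mean(tt), 4) else NA)
  })

  welch <- NULL
  hostTau <- tau[intersect(names(tau), asg$transcript_id[asg$label == "host"])]
  fungTau <- tau[intersect(names(tau), asg$transcript_id[asg$label == "fungi"])]
  if (length(hostTau) >= 2L && length(fungTau) >= 2L) {
    w <- welchT(fungTau, hostTau)
    welch <- list(t = signif(w$t, 10), df = signif(w$df, 10),
                  p = signif(w$p, 10))
  }

  if (nrow(expressed)[1L] >= 2L && ncol(expressed)[1L] >= 2L) {
    pca <- pcaExpression(expressed, k = 2L)
    utils::write.table(
      data.frame(sample = rownames(pca$scores), signif(pca$scores, 6)),
      file.path(outDir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    branch = "joint",
    version = as.character(utils::packageVersion("metapart")),
    seed = seed,
    parameters = list(eCutoff = eCutoff),
    counts = list(input = length(transcripts),
                  expressed = nrow(expressed),
                  classified = sum(asg$label != "none"),
                  unassigned = sum(asg$label == "none")),
    composition = comp,
    perClass = perClass,
    welch = welch
  )
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(report)
}

#' Fungal-enrichment branch of the partitioning workflow
#'
#' Optionally filters read pairs by joint GC, removes transcripts shared
#' identically across many per-sample assemblies, aligns the survivors
#' all-vs-all, groups them into single-linkage homolog clusters, drops
#' undersized and plant-labelled clusters, and pools member expression per
#' cluster. Artifacts and a `report.json` land in `outDir`.
#'
#' @param seqsBySample named list of `DNAStringSet`s (one per sample) or a
#'   directory of per-sample FASTA files ([readSampleFastas()]).
#' @param reads optional list with `mate1`/`mate2` `DNAStringSet`s or a
#'   length-2 character vector of FASTQ paths; when given, the GC read
#'   filter runs first and the kept pairs are written out.
#' @param expression optional [ExpressionMatrix] (or TSV path, state
#'   `"fpkm"`) used for pooled cluster expression.
#' @param assignments optional assignment data.frame used to drop
#'   plant-representative clusters.
#' @param outDir output directory.
#' @param gcThreshold GC percent bound for the read filter.
#' @param k,minSamples parameters of [crossSampleIdentityFilter()].
#' @param minOverlap,minIdentity parameters of [allVsAll()].
#' @param minClusterSize minimum cluster size kept.
#' @param seed integer, echoed into the report.
#' @return the report, invisibly.
#' @export
runEnrichment <- function(seqsBySample, reads = NULL, expression = NULL,
                          assignments = NULL, outDir,
                          gcThreshold = 46, k = 100, minSamples = 5,
                          minOverlap = 200, minIdentity = 0.52,
                          minClusterSize = 4, seed = 1) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(seqsBySample)) seqsBySample <- readSampleFastas(seqsBySample)
  if (is.character(expression))
    expression <- readExpressionMatrix(expression, "fpkm")

  readReport <- NULL
  if (!is.null(reads)) {
    if (is.character(reads)) reads <- list(mate1 = reads[1L], mate2 = reads[2L])
    fr <- filterReadsByGC(reads$mate1, reads$mate2, threshold = gcThreshold)
    writeReadPairs(fr, file.path(outDir, "reads_gc_filtered"))
    readReport <- list(input = fr$report@input, retained = fr$report@retained,
                       removed = fr$report@removed)
    message(sprintf("[enrich] read filter      %d -> %d",
                    fr$report@input, fr$report@retained))
  } else {
    message("[enrich] read filter      skipped (no reads supplied)")
  }

  seqs <- do.call(c, unname(seqsBySample))
  samples <- rep(names(seqsBySample), lengths(seqsBySample))
  if (anyDuplicated(names(seqs)))
    .stopf("transcript ids must be unique across samples")
  filt <- crossSampleIdentityFilter(seqs, samples, k = k,
                                    minSamples = minSamples)
  message(sprintf("[enrich] identity filter  %d -> %d",
                  filt$report@input, filt$report@retained))
  writeLines(filt$retained, file.path(outDir, "retained_ids.txt"))
  writeLines(filt$removed, file.path(outDir, "removed_ids.txt"))

  kept <- seqs[filt$retained]
  matches <- if (length(kept) >= 2L)
    allVsAll(kept, minOverlap = minOverlap, minIdentity = minIdentity)
  else data.frame(id_a = character(), id_b = character(),
                  overlap = numeric(), identity = numeric())
  utils::write.table(
    cbind(matches[c("id_a", "id_b", "overlap")],
          identity = signif(matches$identity, 6)),
    file.path(outDir, "matches.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  lengths <- stats::setNames(Biostrings::width(kept), names(kept))
  clusters <- clusterHomologs(matches, names(kept), lengths,
                              cut = 1 - minIdentity)
  sized <- filterMinSize(clusters, minSize = minClusterSize)
  dropped <- if (!is.null(assignments))
    dropPlantClusters(sized, assignments) else sized
  message(sprintf("[enrich] clusters         %d total, %d >= %d, %d kept",
                  length(clusters), length(sized), minClusterSize,
                  length(dropped)))
  writeClusters(dropped, file.path(outDir, "clusters.tsv"))
  if (length(dropped))
    writeFasta(kept[clusterRepresentatives(dropped)],
               file.path(outDir, "representatives.fasta"))

  pooled <- NULL
  if (!is.null(expression) && length(dropped)) {
    pooled <- pooledExpression(dropped, expression)
    utils::write.table(
      data.frame(cluster_id = rownames(pooled), signif(pooled, 6),
                 check.names = FALSE),
      file.path(outDir, "pooled_expression.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  sizes <- lengths(clusterMembers(dropped))
  report <- list(
    branch = "enrichment",
    version = as.character(utils::packageVersion("metapart")),
    seed = seed,
    parameters = list(gcThreshold = gcThreshold, k = k,
                      minSamples = minSamples, minOverlap = minOverlap,
                      minIdentity = minIdentity,
                      minClusterSize = minClusterSize),
    readFilter = readReport,
    identityFilter = list(input = filt$report@input,
                          retained = filt$report@retained,
                          removed = filt$report@removed),
    clusters = list(total = length(clusters),
                    minSize = length(sized),
                    kept = length(dropped),
                    sizeDistribution = if (length(sizes))
                      as.list(table(sizes)) else list())
  )
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(report)
}
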