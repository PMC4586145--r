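#' Read a protein-homology hits table
#'
#' Expects a tab-separated file (BLAST outfmt-6-compatible superset) with
#' columns `transcript_id`, `subject_id`, `evalue`, `bitscore`,
#' `taxon_label`. Malformed rows (non-numeric or negative e-value, missing
#' fields) are rejected with a warning that names their line numbers.
#'
#' @param path path to the TSV file (header row required).
#' @return data.frame of well-formed hits; rejected line numbers in
#'   attribute `"rejected"`.
#' @export
readProteinHits <- function(path) {
  req <- c("transcript_id", "subject_id", "evalue", "bitscore", "taxon_label")
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(req %in% names(df)))
    .stopf("hits table lacks column(s): %s",
           paste(setdiff(req, names(df)), collapse = ", "))
  df <- df[req]
  ev <- suppressWarnings(as.numeric(df$evalue))
  bs <- suppressWarnings(as.numeric(df$bitscore))
  bad <- is.na(ev) | ev < 0 | is.na(bs) |
    !nzchar(df$transcript_id) | !nzchar(df$subject_id)
  if (any(bad))
    warning(sprintf("rejected %d malformed hit row(s) at line(s) %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
  out <- df[!bad, , drop = FALSE]
  out$evalue <- ev[!bad]
  out$bitscore <- bs[!bad]
  rownames(out) <- NULL
  attr(out, "rejected") <- which(bad) + 1L
  out
}

#' Read a transcript-to-genome alignment summary table
#'
#' Tab-separated columns `transcript_id`, `support` (fraction of the
#' alignment considered reliable), `coverage` (fraction of the transcript
#' aligned) and `identity` (fraction), all in \[0, 1\].
#'
#' @param path path to the TSV file.
#' @return data.frame of alignment summaries.
#' @export
readGenomeAlignments <- function(path) {
  req <- c("transcript_id", "support", "coverage", "identity")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(req %in% names(df)))
    .stopf("alignment table lacks column(s): %s",
           paste(setdiff(req, names(df)), collapse = ", "))
  df <- df[req]
  num <- df[c("support", "coverage", "identity")]
  if (any(is.na(as.matrix(num))) || any(num < 0) || any(num > 1))
    .stopf("support/coverage/identity must be fractions in [0, 1]")
  df
}

#' Default taxon-label to kingdom-class lookup
#'
#' Two-column mapping from taxon labels (as they appear in a hits table) to
#' the classification labels used throughout: `host`, `fungi`,
#' `viridiplantae_other`, `bacteria`, `metazoa`, `other`. Plant labels for
#' the host lineage (land plants) map to `host`; green algae, which share
#' the GC profile of fungi, are kept apart as `viridiplantae_other`.
#' Supply your own table for other taxonomies; labels absent from the map
#' classify as `other`.
#'
#' @return data.frame with columns `taxon_label`, `label`.
#' @export
defaultTaxonMap <- function() {
  data.frame(
    taxon_label = c("Embryophyta", "Streptophyta", "Spermatophyta",
                    "Picea abies", "Viridiplantae",
                    "Chlorophyta",
                    "Fungi", "Ascomycota", "Basidiomycota",
                    "Dothideomycetes", "Leotiomycetes", "Eurotiomycetes",
                    "Bacteria", "Metazoa"),
    label = c(rep("host", 5),
              "viridiplantae_other",
              rep("fungi", 6),
              "bacteria", "metazoa"),
    stringsAsFactors = FALSE
  )
}

#' Taxonomic assignment from the top-ranking protein hit
#'
#' Per transcript, hits with e-value strictly below the cutoff are ranked
#' by ascending e-value, ties broken by descending bitscore and then
#' lexicographic subject id (a total order, so assignment is
#' deterministic); the winning hit's taxon label is mapped to a
#' classification label. Transcripts with no passing hit are labelled
#' `none`.
#'
#' @param hits data.frame as returned by [readProteinHits()].
#' @param transcripts optional character vector of all transcript ids, so
#'   hit-less transcripts appear with label `none`.
#' @param eCutoff e-value cutoff (hits must be strictly below it).
#' @param taxonMap lookup data.frame (`taxon_label`, `label`); defaults to
#'   [defaultTaxonMap()].
#' @return data.frame with columns `transcript_id`, `label`, `provenance`
#'   (`protein_hit` or `unassigned`).
#' @export
topHitTaxon <- function(hits, transcripts = NULL, eCutoff = 1e-3,
                        taxonMap = defaultTaxonMap()) {
  if (eCutoff <= 0) .stopf("eCutoff must be positive")
  pass <- hits[hits$evalue < eCutoff, , drop = FALSE]
  if (nrow(pass)) {
    ord <- order(pass$transcript_id, pass$evalue, -pass$bitscore,
                 pass$subject_id, method = "radix")
    pass <- pass[ord, , drop = FALSE]
    top <- pass[!duplicated(pass$transcript_id), , drop = FALSE]
    lab <- taxonMap$label[match(top$taxon_label, taxonMap$taxon_label)]
    lab[is.na(lab)] <- "other"
    asg <- data.frame(transcript_id = top$transcript_id, label = lab,
                      provenance = "protein_hit", stringsAsFactors = FALSE)
  } else {
    asg <- data.frame(transcript_id = character(), label = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(transcripts)) {
    missing <- setdiff(transcripts, asg$transcript_id)
    if (length(missing))
      asg <- rbind(asg, data.frame(transcript_id = missing, label = "none",
                                   provenance = "unassigned",
                                   stringsAsFactors = FALSE))
    asg <- asg[match(transcripts, asg$transcript_id), , drop = FALSE]
  }
  rownames(asg) <- NULL
  asg
}

#' Validity rule for transcript-to-genome alignments
#'
#' An alignment is valid when at least `minSupport` of it is reliable, it
#' covers strictly more than `minCov` of the transcript, and its identity
#' strictly exceeds `minIdent`. The support clause is a separate fraction
#' because the reliable-portion requirement and the coverage requirement
#' are independent readings of alignment quality; all three thresholds are
#' parameters so either emphasis can be configured.
#'
#' @param support,coverage,identity fractions in \[0, 1\] (vectorised).
#' @param minCov,minIdent strict lower bounds on coverage and identity.
#' @param minSupport inclusive lower bound on the reliable fraction.
#' @return logical vector.
#' @examples
#' validGenomeAlignment(1.0, 0.85, 0.95)  # TRUE
#' validGenomeAlignment(1.0, 0.80, 0.95)  # FALSE: coverage bound is strict
#' @export
validGenomeAlignment <- function(support, coverage, identity,
                                 minCov = 0.80, minIdent = 0.90,
                                 minSupport = 0.99) {
  stopifnot(all(support >= 0 & support <= 1),
            all(coverage >= 0 & coverage <= 1),
            all(identity >= 0 & identity <= 1))
  support >= minSupport & coverage > minCov & identity > minIdent
}

#' Rescue unassigned transcripts with a valid genome alignment
#'
#' Transcripts with no protein-based taxonomic assignment (`label ==
#' "none"`) but a valid alignment to the host genome are re-classified as
#' `host` with provenance `genome_alignment`. Protein-hit-derived labels
#' are never changed.
#'
#' @param assignments data.frame from [topHitTaxon()].
#' @param alignments data.frame from [readGenomeAlignments()].
#' @param ... threshold arguments passed to [validGenomeAlignment()].
#' @return updated assignments data.frame.
#' @export
reclassifyUnassigned <- function(assignments, alignments, ...) {
  valid <- alignments$transcript_id[
    validGenomeAlignment(alignments$support, alignments$coverage,
                         alignments$identity, ...)]
  idx <- assignments$label == "none" & assignments$transcript_id %in% valid
  assignments$label[idx] <- "host"
  assignments$provenance[idx] <- "genome_alignment"
  assignments
}

#' Per-label composition of an assignment table
#'
#' @param assignments data.frame with a `label` column.
#' @return data.frame with columns `label`, `n`, `percent` (percentages of
#'   all transcripts, summing to 100 up to rounding).
#' @export
kingdomSummary <- function(assignments) {
  if (nrow(assignments) == 0L) .stopf("empty assignment table")
  tab <- table(assignments$label)
  data.frame(label = names(tab), n = as.integer(tab),
             percent = round(100 * as.integer(tab) / nrow(assignments), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}
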