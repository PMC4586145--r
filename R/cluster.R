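.nucMat <- function() {
  # match +1 / mismatch -1; ambiguity-aware (fuzzy) so Ns align neutrally
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# columns of a local alignment, gap columns included
.alnCols <- function(aln) nchar(as.character(Biostrings::pattern(aln)))

.alnStats <- function(aln) {
  cols <- .alnCols(aln)
  list(overlap = cols,
       identity = ifelse(cols > 0, Biostrings::nmatch(aln) / cols, 0),
       score = Biostrings::score(aln))
}

#' Overlap and identity of the best local alignment of two transcripts
#'
#' Smith–Waterman local alignment with match +1, mismatch -1 and affine
#' gaps (opening 2, extension 1; a gap of length L costs 2 + L), computed
#' on both relative strands; the better-scoring strand wins. Identity is
#' the fraction of matching columns over all aligned columns, gap columns
#' included — i.e. identity local to the overlap, not to the full
#' sequences. A match is reported only when the aligned span reaches
#' `minOverlap` and identity strictly exceeds `minIdentity`.
#'
#' @param a,b nucleotide strings or `DNAString`s.
#' @param minOverlap minimum aligned span in columns (default 200).
#' @param minIdentity strict lower bound on identity (default 0.52).
#' Arguments are ordered canonically (lexicographically) before aligning,
#' so the result is exactly symmetric even when co-optimal alignments with
#' different spans exist.
#'
#' @return `NULL` when no qualifying overlap exists, else a list with
#'   `overlap`, `identity`, `strand` (`"+"` or `"-"`).
#' @export
pairwiseOverlapIdentity <- function(a, b, minOverlap = 200,
                                    minIdentity = 0.52) {
  a <- as.character(a)
  b <- as.character(b)
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  a <- Biostrings::DNAString(a)
  b <- Biostrings::DNAString(b)
  mat <- .nucMat()
  fw <- .alnStats(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 1))
  rv <- .alnStats(Biostrings::pairwiseAlignment(
    a, Biostrings::reverseComplement(b), type = "local",
    substitutionMatrix = mat, gapOpening = 2, gapExtension = 1))
  best <- if (fw$score >= rv$score) c(fw, strand = "+") else c(rv, strand = "-")
  if (best$overlap >= minOverlap && best$identity > minIdentity)
    list(overlap = best$overlap, identity = best$identity,
         strand = best$strand)
  else NULL
}

#' All-vs-all overlap-identity matches
#'
#' Evaluates every unordered pair of sequences once with
#' [pairwiseOverlapIdentity()] (vectorised over one subject at a time) and
#' returns the qualifying matches sorted by id pair, so output order never
#' depends on input order.
#'
#' @param seqs named `DNAStringSet` (>= 2 sequences).
#' @param minOverlap,minIdentity emission thresholds, see
#'   [pairwiseOverlapIdentity()].
#' @return data.frame with columns `id_a`, `id_b` (`id_a < id_b`),
#'   `overlap`, `identity`.
#' @export
allVsAll <- function(seqs, minOverlap = 200, minIdentity = 0.52) {
  n <- length(seqs)
  if (n < 2L) .stopf("need at least two sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) .stopf("unique names required")
  mat <- .nucMat()
  out <- vector("list", n)
  for (j in 2:n) {
    pat <- seqs[seq_len(j - 1L)]
    fw <- Biostrings::pairwiseAlignment(
      pat, seqs[[j]], type = "local", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    rv <- Biostrings::pairwiseAlignment(
      pat, Biostrings::reverseComplement(seqs[[j]]), type = "local",
      substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
    useFw <- Biostrings::score(fw) >= Biostrings::score(rv)
    cols <- ifelse(useFw, .alnCols(fw), .alnCols(rv))
    nmat <- ifelse(useFw, Biostrings::nmatch(fw), Biostrings::nmatch(rv))
    idy <- ifelse(cols > 0, nmat / cols, 0)
    hit <- cols >= minOverlap & idy > minIdentity
    if (any(hit)) {
      ia <- pmin(ids[which(hit)], ids[j])
      ib <- pmax(ids[which(hit)], ids[j])
      out[[j]] <- data.frame(id_a = ia, id_b = ib,
                             overlap = cols[hit], identity = idy[hit],
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(id_a = character(), id_b = character(),
                      overlap = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$id_a, res$id_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Single-linkage homolog clustering at an identity distance cut
#'
#' Agglomerative single-linkage clustering with pairwise distance
#' 1 - identity between matched pairs and distance 1 (never merged) for
#' unmatched pairs, cut at distance < `cut`. At the emission threshold
#' this is exactly the set of connected components of the match graph, so
#' the clustering needs no separate cut height: ids with no qualifying
#' match become singletons. Cluster ids (`C000001`, ...) are assigned by
#' the lexicographically smallest member id, and the representative of
#' each cluster is its longest member (ties: smallest id), making the
#' result independent of input order.
#'
#' @param matches data.frame from [allVsAll()].
#' @param ids character vector of all transcript ids (matched or not).
#' @param lengths named numeric vector of sequence lengths covering `ids`
#'   (used to pick representatives).
#' @param cut distance cut; edges with `1 - identity >= cut` are ignored
#'   (default 0.48, the complement of the 0.52 identity threshold).
#' @return a [HomologClusterSet].
#' @export
clusterHomologs <- function(matches, ids, lengths, cut = 0.48) {
  if (anyDuplicated(ids)) .stopf("duplicate transcript ids")
  unknown <- setdiff(unique(c(matches$id_a, matches$id_b)), ids)
  if (length(unknown))
    .stopf("matches reference unknown id(s): %s",
           paste(utils::head(unknown, 3), collapse = ", "))
  if (!all(ids %in% names(lengths)))
    .stopf("lengths must cover every id")
  edges <- matches[1 - matches$identity < cut, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  members <- lapply(members, function(m) sort(m))
  members <- members[order(vapply(members, `[`, "", 1L))]
  names(members) <- sprintf("C%06d", seq_along(members))
  rep_ <- vapply(members, function(m) {
    len <- lengths[m]
    cand <- m[len == max(len)]
    sort(cand)[1L]
  }, "")
  new("HomologClusterSet", members = members, representative = rep_)
}

#' Keep clusters with at least a minimum number of members
#'
#' @param clusters a [HomologClusterSet].
#' @param minSize minimum member count (default 4, the size at which a
#'   cluster is considered a supported gene family).
#' @return filtered `HomologClusterSet`.
#' @export
filterMinSize <- function(clusters, minSize = 4) {
  keep <- lengths(clusters@members) >= minSize
  new("HomologClusterSet", members = clusters@members[keep],
      representative = clusters@representative[keep])
}

#' Drop clusters whose representative is classified as plant
#'
#' Clusters whose longest sequence has a top protein hit in the plant set
#' are removed as residual host material; clusters whose representative is
#' unlabelled (`none`) are retained, absence of a hit being no evidence of
#' plant origin.
#'
#' @param clusters a [HomologClusterSet].
#' @param assignments data.frame from [topHitTaxon()] /
#'   [reclassifyUnassigned()].
#' @param plantLabels labels counted as plant (default `host` and
#'   `viridiplantae_other`).
#' @return filtered `HomologClusterSet`.
#' @export
dropPlantClusters <- function(clusters, assignments,
                              plantLabels = c("host", "viridiplantae_other")) {
  lab <- assignments$label[match(clusters@representative,
                                 assignments$transcript_id)]
  lab[is.na(lab)] <- "none"
  keep <- !lab %in% plantLabels
  new("HomologClusterSet", members = clusters@members[keep],
      representative = clusters@representative[keep])
}

#' Pooled per-cluster expression
#'
#' Sums the expression rows of each cluster's members per sample — the
#' cluster-level matrix used for joint expression analysis of gene
#' families. Members missing from the matrix contribute zero and are
#' reported in a message.
#'
#' @param clusters a [HomologClusterSet].
#' @param m an [ExpressionMatrix] (any state; typically fpkm).
#' @return numeric matrix, clusters x samples.
#' @export
pooledExpression <- function(clusters, m) {
  v <- exprValues(m)
  miss <- setdiff(unlist(clusters@members, use.names = FALSE), rownames(v))
  if (length(miss))
    message(sprintf("%d cluster member(s) absent from matrix contribute 0",
                    length(miss)))
  pooled <- t(vapply(clusters@members, function(mem) {
    mem <- intersect(mem, rownames(v))
    if (!length(mem)) rep(0, ncol(v))
    else colSums(v[mem, , drop = FALSE])
  }, numeric(ncol(v))))
  colnames(pooled) <- colnames(v)
  pooled
}
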