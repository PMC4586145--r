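test_that("pairwiseOverlapIdentity finds self-identity and rejects noise", {
  s <- rand_dna(300)
  self <- pairwiseOverlapIdentity(s, s)
  expect_equal(self$overlap, 300)
  expect_equal(self$identity, 1.0)

  set.seed(41)
  for (i in 1:5) {
    a <- rand_dna(300)
    b <- rand_dna(300)
    expect_null(pairwiseOverlapIdentity(a, b))
  }

  # reverse-complement homology is found on the minus strand
  rc <- revcomp_chr(s)
  hit <- pairwiseOverlapIdentity(s, rc)
  expect_equal(hit$strand, "-")
  expect_equal(hit$identity, 1.0)
})

test_that("alignment is symmetric and scores match an affine SW oracle", {
  set.seed(42)
  for (i in 1:8) {
    a <- rand_dna(sample(40:80, 1))
    b <- rand_dna(sample(40:80, 1))
    # plant some shared sequence so alignments are non-trivial
    if (i %% 2 == 0) substr(b, 5, 24) <- substr(a, 11, 30)
    pa <- pairwiseOverlapIdentity(a, b, minOverlap = 1, minIdentity = 0)
    pb <- pairwiseOverlapIdentity(b, a, minOverlap = 1, minIdentity = 0)
    expect_equal(pa$overlap, pb$overlap)
    expect_equal(pa$identity, pb$identity)
    want <- max(oracle_sw_score(a, b),
                oracle_sw_score(a, revcomp_chr(b)))
    got <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 2, gapExtension = 1)
    gotrc <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a),
      Biostrings::reverseComplement(Biostrings::DNAString(b)),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 2, gapExtension = 1)
    expect_equal(max(Biostrings::score(got), Biostrings::score(gotrc)),
                 want)
  }
})

test_that("family members align near their construction identity", {
  cfg <- GeneratorConfig(nHost = 2, nSymbiont = 2, nFamilies = 2,
                         familySize = 3, familyLen = 1000,
                         familyIdentity = 0.9, seed = 13)
  fam <- generateFamilies(cfg)
  fams <- split(names(fam$seqs), fam$truth$family_id)
  for (f in fams) {
    chr <- as.character(fam$seqs[f])
    for (i in seq_along(f)) for (j in seq_len(i - 1)) {
      site_identity <- mean(strsplit(chr[i], "")[[1]] ==
                              strsplit(chr[j], "")[[1]])
      hit <- pairwiseOverlapIdentity(chr[i], chr[j])
      expect_false(is.null(hit))
      expect_lt(abs(hit$identity - site_identity), 0.05)
    }
  }
})

test_that("allVsAll evaluates each pair once, output order canonical", {
  s <- rand_dna(250)
  seqs <- Biostrings::DNAStringSet(c(c1 = s, b2 = s, a3 = s))
  m <- allVsAll(seqs)
  expect_equal(nrow(m), 3L)  # all three unordered pairs
  expect_true(all(m$id_a < m$id_b))
  expect_equal(m, allVsAll(rev(seqs)))

  set.seed(44)
  r <- Biostrings::DNAStringSet(
    stats::setNames(vapply(1:4, function(.) rand_dna(250), ""),
                    paste0("r", 1:4)))
  expect_equal(nrow(allVsAll(r)), 0L)
  expect_lte(nrow(allVsAll(c(seqs, r))), choose(7, 2))
})

test_that("clustering equals connected components with deterministic ids", {
  matches <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"),
                        overlap = c(300, 300), identity = c(0.9, 0.9))
  lens <- c(A = 100, B = 300, C = 200, D = 50, E = 50)
  cl <- clusterHomologs(matches, c("A", "B", "C", "D", "E"), lens)
  expect_equal(length(cl), 3L)
  expect_equal(clusterMembers(cl)[[1]], c("A", "B", "C"))  # transitivity
  expect_equal(unname(clusterRepresentatives(cl)[1]), "B")  # longest wins
  # representative ties break to the smallest id
  expect_equal(unname(clusterRepresentatives(cl)[2:3]), c("D", "E"))

  none <- clusterHomologs(matches[0, ], c("A", "B"), lens)
  expect_equal(length(none), 2L)
  expect_error(clusterHomologs(matches, c("A", "B"), lens), "unknown id")
})

test_that("clusters match a union-find oracle and ignore weak edges", {
  set.seed(45)
  for (i in 1:15) {
    n <- sample(5:60, 1)
    ids <- sprintf("n%03d", sample(999, n))
    ne <- sample(0:(2 * n), 1)
    edges <- data.frame(
      id_a = sample(ids, ne, replace = TRUE),
      id_b = sample(ids, ne, replace = TRUE),
      overlap = 300,
      identity = runif(ne, 0.4, 1.0), stringsAsFactors = FALSE)
    edges <- edges[edges$id_a != edges$id_b, , drop = FALSE]
    lens <- stats::setNames(sample(100:1000, n, replace = TRUE), ids)
    cl <- clusterHomologs(edges, ids, lens, cut = 0.48)
    strong <- edges[1 - edges$identity < 0.48, , drop = FALSE]
    want <- canonical_partition(oracle_components(ids, strong))
    expect_identical(canonical_partition(clusterMembers(cl)), want)
    # permuting the id universe changes nothing
    cl2 <- clusterHomologs(edges, sample(ids), lens, cut = 0.48)
    expect_identical(clusterMembers(cl2), clusterMembers(cl))
  }
})

test_that("size filtering and plant-cluster removal behave at boundaries", {
  mk <- function(sizes) {
    members <- lapply(seq_along(sizes), function(i)
      sprintf("c%d_m%02d", i, seq_len(sizes[i])))
    names(members) <- sprintf("C%06d", seq_along(sizes))
    new("HomologClusterSet", members = members,
        representative = vapply(members, `[`, "", 1L))
  }
  cl <- mk(c(4, 3, 1))
  expect_equal(length(filterMinSize(cl, 4)), 1L)
  expect_equal(length(filterMinSize(cl, 1)), 3L)

  asg <- data.frame(
    transcript_id = c("c1_m01", "c2_m01", "c3_m01"),
    label = c("viridiplantae_other", "fungi", "none"),
    provenance = "protein_hit", stringsAsFactors = FALSE)
  kept <- dropPlantClusters(cl, asg)
  expect_equal(length(kept), 2L)  # the plant cluster is gone, none kept
  asg$label[1] <- "host"
  expect_equal(length(dropPlantClusters(cl, asg)), 2L)
})

test_that("pooled expression sums member rows and conserves totals", {
  v <- matrix(c(1, 2, 3, 4, 10, 20), 3, 2, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), c("s1", "s2")))
  m <- ExpressionMatrix(v, state = "fpkm")
  cl <- new("HomologClusterSet",
            members = list(C000001 = c("x", "y"), C000002 = "z"),
            representative = c(C000001 = "x", C000002 = "z"))
  pooled <- pooledExpression(cl, m)
  expect_equal(unname(pooled["C000001", ]), c(4, 6))
  expect_equal(unname(pooled["C000002", ]), c(10, 20))
  expect_equal(sum(pooled), sum(v))  # conservation

  cl2 <- new("HomologClusterSet",
             members = list(C000001 = c("x", "ghost")),
             representative = c(C000001 = "x"))
  expect_message(p2 <- pooledExpression(cl2, m), "absent")
  expect_equal(unname(p2[1, ]), c(1, 2))
})

test_that("synthetic families are recovered exactly as clusters", {
  cfg <- GeneratorConfig(nHost = 2, nSymbiont = 2, nFamilies = 5,
                         familySize = 4, familyLen = 400,
                         familyIdentity = 0.9, seed = 17)
  fam <- generateFamilies(cfg)
  m <- allVsAll(fam$seqs)
  lens <- stats::setNames(Biostrings::width(fam$seqs), names(fam$seqs))
  cl <- clusterHomologs(m, names(fam$seqs), lens)
  got <- canonical_partition(clusterMembers(cl))
  want <- canonical_partition(split(fam$truth$transcript_id,
                                    fam$truth$family_id))
  expect_identical(got, want)
})
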