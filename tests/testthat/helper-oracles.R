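# Independent oracles used to cross-check the package's implementations.
# Each is a deliberately naive route to the same quantity.

rand_dna <- function(len, gc = 50) {
  p <- gc / 200
  paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
               prob = c(p, p, (1 - 2 * p) / 2, (1 - 2 * p) / 2)),
        collapse = "")
}

revcomp_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

# tau by direct transliteration of the defining sum
oracle_tau <- function(x) {
  n <- length(x)
  m <- max(x)
  acc <- 0
  for (j in seq_len(n)) acc <- acc + (1 - x[j] / m)
  acc / (n - 1)
}

# Welch t, Welch-Satterthwaite df, two-sided p, from the textbook formulas
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# TRUE iff a and b share an exact stretch of >= k nucleotides on either
# strand: brute-force substring search, no k-mer index. Stretches
# containing N never count.
oracle_shares_stretch <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  subs <- substring(a, 1:(nchar(a) - k + 1), k:nchar(a))
  subs <- subs[!grepl("[^ACGT]", subs)]
  brc <- revcomp_chr(b)
  for (s in subs)
    if (grepl(s, b, fixed = TRUE) || grepl(s, brc, fixed = TRUE))
      return(TRUE)
  FALSE
}

# removed-id set of the cross-sample filter by all-pairs comparison
oracle_identity_filter <- function(seqs, samples, k, minSamples) {
  n <- length(seqs)
  removed <- character(0)
  for (i in seq_len(n)) {
    sharers <- vapply(seq_len(n), function(j)
      i == j || oracle_shares_stretch(seqs[i], seqs[j], k), TRUE)
    if (length(unique(samples[sharers])) >= minSamples)
      removed <- c(removed, names(seqs)[i])
  }
  removed
}

# connected components by union-find (path halving)
oracle_components <- function(ids, edges) {
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(which(ids == edges$id_a[r]))
    b <- find(which(ids == edges$id_b[r]))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(ids), find, 1L)
  split(ids, roots)
}

# affine-gap Smith-Waterman score: match +1, mismatch -1, a gap of
# length L costs open + L * ext (so the first gap column costs open+ext)
oracle_sw_score <- function(a, b, match = 1, mismatch = -1,
                            open = 2, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  H <- matrix(0, na + 1, nb + 1)
  E <- matrix(-Inf, na + 1, nb + 1)
  F_ <- matrix(-Inf, na + 1, nb + 1)
  best <- 0
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F_[i, j] <- max(H[i - 1, j] - open - ext, F_[i - 1, j] - ext)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# canonical member sets, order-free, for comparing clusterings
canonical_partition <- function(memberList) {
  unname(lapply(memberList, sort))[order(vapply(memberList,
                                                function(m) sort(m)[1], ""))]
}
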