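#' FPKM normalisation of a count matrix
#'
#' Fragments Per Kilobase of transcript per Million mapped fragments:
#' `count / (length/1000) / (column_total/1e6)` per sample column. The
#' per-sample library size is the column total of the matrix itself, so the
#' operation is scale-invariant in each column; columns with zero total
#' yield all-zero columns. Users holding externally computed FPKM (e.g.
#' from RSEM) can construct an `ExpressionMatrix` with `state = "fpkm"` and
#' skip this step.
#'
#' @param object an [ExpressionMatrix] in state `"counts"`.
#' @param lengths named numeric vector of transcript lengths (nucleotides)
#'   covering every row of the matrix.
#' @return an `ExpressionMatrix` in state `"fpkm"`.
#' @examples
#' m <- ExpressionMatrix(matrix(c(10, 999990), 2,
#'        dimnames = list(c("a", "b"), "s1")))
#' exprValues(fpkm(m, c(a = 1000, b = 500)))["a", ]  # 10
#' @rdname fpkm
#' @export
setMethod("fpkm", "ExpressionMatrix", function(object, lengths) {
  if (object@state != "counts")
    .stopf("fpkm() requires state 'counts', got '%s'", object@state)
  ids <- rownames(object@values)
  if (!all(ids %in% names(lengths)))
    .stopf("missing length for transcript(s): %s",
           paste(utils::head(setdiff(ids, names(lengths)), 3), collapse = ", "))
  len <- lengths[ids]
  tot <- colSums(object@values)
  denom <- ifelse(tot > 0, tot / 1e6, Inf)  # zero-depth column -> all zeros
  v <- sweep(object@values / (len / 1000), 2, denom, "/")
  ExpressionMatrix(v, state = "fpkm")
})

#' Floored log2 transform of FPKM values
#'
#' Values below 1 are set to 0; values at or above 1 become `log2(value)`.
#' This is the transform applied before specificity scoring, so that
#' expression below one fragment per kilobase per million counts as absent.
#'
#' @param object an [ExpressionMatrix] in state `"fpkm"`.
#' @return an `ExpressionMatrix` in state `"log2fpkm"`.
#' @rdname floorLog2
#' @export
setMethod("floorLog2", "ExpressionMatrix", function(object) {
  if (object@state != "fpkm")
    .stopf("floorLog2() requires state 'fpkm', got '%s'", object@state)
  v <- object@values
  v <- ifelse(v < 1, 0, log2(v))
  ExpressionMatrix(v, state = "log2fpkm")
})

#' Remove transcripts with no expression signal in any sample
#'
#' Drops rows that are zero in every column of the floored log2 matrix.
#' Required before [tauScores()], whose score is undefined on all-zero rows.
#'
#' @param object an [ExpressionMatrix] in state `"log2fpkm"`.
#' @return the matrix without all-zero rows.
#' @rdname dropAllZero
#' @export
setMethod("dropAllZero", "ExpressionMatrix", function(object) {
  if (object@state != "log2fpkm")
    .stopf("dropAllZero() requires state 'log2fpkm', got '%s'", object@state)
  keep <- rowSums(object@values > 0) > 0
  ExpressionMatrix(object@values[keep, , drop = FALSE], state = "log2fpkm")
})

#' Tau expression-specificity score
#'
#' For an expression profile a over n samples,
#' \deqn{\tau = \frac{1}{n-1}\sum_{j=1}^{n}\left(1 -
#'   \frac{a_j}{\max_j a_j}\right)}
#' so specificity is measured relative to the sample with the highest
#' expression: tau = 1 for expression in exactly one sample, 0 for equal
#' expression in all samples, and e.g. 0.8 when every other sample sits at
#' 20% of the maximum. Scores are invariant under positive scaling of the
#' profile.
#'
#' @param x non-negative numeric vector over at least two samples with at
#'   least one positive entry.
#' @return tau in \[0, 1\].
#' @examples
#' tauScore(c(100, rep(20, 21)))  # 0.8
#' tauScore(c(5, 0, 0, 0))        # 1
#' tauScore(rep(3, 22))           # 0
#' @export
tauScore <- function(x) {
  if (length(x) < 2L) .stopf("tau needs at least two samples")
  if (any(x < 0)) .stopf("negative expression values")
  m <- max(x)
  if (m == 0) .stopf("tau is undefined for an all-zero profile; apply dropAllZero() first")
  sum(1 - x / m) / (length(x) - 1L)
}

#' @param object an [ExpressionMatrix] (state `"log2fpkm"` in the standard
#'   chain; any non-negative matrix is accepted).
#' @return `tauScores()`: named numeric vector, one tau per row.
#' @rdname tauScore
#' @aliases tauScores
#' @export
setMethod("tauScores", "ExpressionMatrix", function(object) {
  v <- object@values
  if (ncol(v) < 2L) .stopf("tau needs at least two samples")
  mx <- apply(v, 1L, max)
  if (any(mx == 0))
    .stopf("all-zero rows present; apply dropAllZero() first")
  tau <- rowSums(1 - v / mx) / (ncol(v) - 1L)
  names(tau) <- rownames(v)
  tau
})

#' Welch two-sample comparison of score distributions
#'
#' Unequal-variance t test with Welch–Satterthwaite degrees of freedom,
#' used to compare tau distributions between transcript classes.
#'
#' @param x,y numeric vectors of at least two values each, with nonzero
#'   variance in at least one of them.
#' @return list with elements `t`, `df`, `p` (two-sided).
#' @export
welchT <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    .stopf("welchT needs at least two values per group")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    .stopf("degenerate samples: both groups have zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Principal component analysis of an expression matrix
#'
#' Samples are the observations and transcripts the variables; the matrix
#' is transposed and passed to [stats::prcomp()]. Centering is always on;
#' scaling to unit variance is off by default (matching prcomp defaults).
#'
#' @param object an [ExpressionMatrix] in state `"fpkm"` or `"log2fpkm"`.
#' @param k number of components to return; truncated to the matrix rank
#'   with a warning when it exceeds it.
#' @param scale. scale transcripts to unit variance before rotation.
#' @return list with `scores` (samples x k), `loadings` (transcripts x k)
#'   and `varianceFraction` (length k).
#' @rdname pcaExpression
#' @export
setMethod("pcaExpression", "ExpressionMatrix",
          function(object, k = 2L, scale. = FALSE) {
  if (!object@state %in% c("fpkm", "log2fpkm"))
    .stopf("pcaExpression() requires fpkm or log2fpkm state")
  v <- object@values
  if (nrow(v) < 2L || ncol(v) < 2L)
    .stopf("need at least two transcripts and two samples")
  p <- stats::prcomp(t(v), center = TRUE, scale. = scale.)
  rank <- sum(p$sdev > max(p$sdev) * 1e-10)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; truncating", k, rank))
    k <- rank
  }
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(k), drop = FALSE],
       loadings = p$rotation[, seq_len(k), drop = FALSE],
       varianceFraction = vf[seq_len(k)])
})
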