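#' Configuration for the synthetic dual-population generator
#'
#' Holds every tunable of the synthetic-data module: sizes, per-population
#' GC targets, length log-normals, expression breadth, count overdispersion,
#' homolog-family structure and the root seed from which every random stream
#' is derived.
#'
#' Defaults mirror the mixed plant/fungus structure the package is designed
#' for: a host population at 44.5% mean GC expressed across most of 22
#' samples, and a symbiont population at 53.1% mean GC confined to one or
#' two samples, with host transcripts markedly longer than symbiont ones.
#'
#' @slot nHost,nSymbiont number of transcripts per population.
#' @slot nSamples number of samples (columns of the expression matrix).
#' @slot hostGCMean,hostGCSd,symbiontGCMean,symbiontGCSd per-transcript
#'   target GC percent is drawn Normal(mean, sd), truncated to \[0, 100\].
#' @slot hostLenLogMean,hostLenLogSd,symbiontLenLogMean,symbiontLenLogSd
#'   log-normal length parameters (natural log of nucleotides).
#' @slot hostBreadth,symbiontBreadth expected fraction of samples in which a
#'   transcript is expressed (at least one sample is always expressed).
#' @slot dispersion negative-binomial dispersion of simulated counts
#'   (\code{size = 1/dispersion}).
#' @slot nFamilies,familySize,familyLen,familyIdentity homolog-family
#'   structure: number of families, members per family, ancestor length and
#'   per-branch expected site identity to the ancestor.
#' @slot seed root integer seed; all streams are derived from it.
#' @seealso [generateTranscripts()], [generateExpression()],
#'   [generateFamilies()]
#' @export
setClass("GeneratorConfig",
  representation(
    nHost = "numeric", nSymbiont = "numeric", nSamples = "numeric",
    hostGCMean = "numeric", hostGCSd = "numeric",
    symbiontGCMean = "numeric", symbiontGCSd = "numeric",
    hostLenLogMean = "numeric", hostLenLogSd = "numeric",
    symbiontLenLogMean = "numeric", symbiontLenLogSd = "numeric",
    hostBreadth = "numeric", symbiontBreadth = "numeric",
    dispersion = "numeric",
    nFamilies = "numeric", familySize = "numeric",
    familyLen = "numeric", familyIdentity = "numeric",
    seed = "numeric"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  cnt <- c(
    nHost = object@nHost, nSymbiont = object@nSymbiont,
    nSamples = object@nSamples, nFamilies = object@nFamilies,
    familySize = object@familySize, familyLen = object@familyLen
  )
  if (any(cnt <= 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be positive integers")
  gc <- c(object@hostGCMean, object@symbiontGCMean)
  if (any(gc <= 0) || any(gc > 100))
    msg <- c(msg, "GC means must lie in (0, 100]")
  if (object@hostGCSd < 0 || object@symbiontGCSd < 0)
    msg <- c(msg, "GC standard deviations must be non-negative")
  br <- c(object@hostBreadth, object@symbiontBreadth)
  if (any(br <= 0) || any(br > 1))
    msg <- c(msg, "breadth must lie in (0, 1]")
  if (object@familyIdentity <= 0 || object@familyIdentity > 1)
    msg <- c(msg, "familyIdentity must lie in (0, 1]")
  if (object@dispersion < 0)
    msg <- c(msg, "dispersion must be non-negative")
  if (length(object@seed) != 1L || object@seed != round(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' @param nHost,nSymbiont,nSamples,hostGCMean,hostGCSd,symbiontGCMean,symbiontGCSd,hostLenLogMean,hostLenLogSd,symbiontLenLogMean,symbiontLenLogSd,hostBreadth,symbiontBreadth,dispersion,nFamilies,familySize,familyLen,familyIdentity,seed see slots.
#' @return A validated `GeneratorConfig`.
#' @examples
#' cfg <- GeneratorConfig(nHost = 50, nSymbiont = 50, seed = 7)
#' @rdname GeneratorConfig-class
#' @export
GeneratorConfig <- function(nHost = 2000, nSymbiont = 2000, nSamples = 22,
                            hostGCMean = 44.5, hostGCSd = 3.0,
                            symbiontGCMean = 53.1, symbiontGCSd = 3.0,
                            hostLenLogMean = log(1300), hostLenLogSd = 0.6,
                            symbiontLenLogMean = log(420),
                            symbiontLenLogSd = 0.5,
                            hostBreadth = 0.9, symbiontBreadth = 0.05,
                            dispersion = 0.3,
                            nFamilies = 10, familySize = 6,
                            familyLen = 1000, familyIdentity = 0.9,
                            seed = 1) {
  new("GeneratorConfig",
    nHost = nHost, nSymbiont = nSymbiont, nSamples = nSamples,
    hostGCMean = hostGCMean, hostGCSd = hostGCSd,
    symbiontGCMean = symbiontGCMean, symbiontGCSd = symbiontGCSd,
    hostLenLogMean = hostLenLogMean, hostLenLogSd = hostLenLogSd,
    symbiontLenLogMean = symbiontLenLogMean,
    symbiontLenLogSd = symbiontLenLogSd,
    hostBreadth = hostBreadth, symbiontBreadth = symbiontBreadth,
    dispersion = dispersion,
    nFamilies = nFamilies, familySize = familySize,
    familyLen = familyLen, familyIdentity = familyIdentity,
    seed = seed
  )
}

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig\n")
  cat(sprintf("  transcripts : %d host + %d symbiont over %d samples\n",
              object@nHost, object@nSymbiont, object@nSamples))
  cat(sprintf("  GC%%        : host %.1f (sd %.1f) / symbiont %.1f (sd %.1f)\n",
              object@hostGCMean, object@hostGCSd,
              object@symbiontGCMean, object@symbiontGCSd))
  cat(sprintf("  breadth     : host %.2f / symbiont %.2f\n",
              object@hostBreadth, object@symbiontBreadth))
  cat(sprintf("  families    : %d x %d members, identity %.2f, length %d\n",
              object@nFamilies, object@familySize, object@familyIdentity,
              object@familyLen))
  cat(sprintf("  seed        : %d\n", object@seed))
})

#' Expression matrix with an explicit transform state
#'
#' A transcripts-by-samples numeric matrix tagged with its place in the
#' quantification chain: raw fragment `counts`, length/depth-normalised
#' `fpkm`, or the floored `log2fpkm` scale used for specificity scoring.
#' State transitions are enforced by [fpkm()], [floorLog2()] and
#' [dropAllZero()]: counts -> fpkm -> log2fpkm, never backwards.
#'
#' @slot values numeric matrix, transcripts in rows, samples in columns; no
#'   negative entries; dimnames required and unique.
#' @slot state one of `"counts"`, `"fpkm"`, `"log2fpkm"`.
#' @param values,state see slots.
#' @param object an `ExpressionMatrix`.
#' @examples
#' m <- ExpressionMatrix(matrix(1:4, 2, dimnames = list(c("t1", "t2"),
#'                                                      c("s1", "s2"))))
#' exprState(m)
#' @aliases exprValues exprState
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", state = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.numeric(v) && any(v < 0)) msg <- c(msg, "negative entries forbidden")
  if ((nrow(v) > 0L && is.null(rownames(v))) ||
      (ncol(v) > 0L && is.null(colnames(v))))
    msg <- c(msg, "row and column names are required")
  if (anyDuplicated(rownames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "dimnames must be unique")
  if (length(object@state) != 1L ||
      !object@state %in% c("counts", "fpkm", "log2fpkm"))
    msg <- c(msg, "state must be one of counts, fpkm, log2fpkm")
  if (length(msg)) msg else TRUE
})

#' @rdname ExpressionMatrix-class
#' @export
ExpressionMatrix <- function(values, state = "counts") {
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, state = state)
}

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @rdname ExpressionMatrix-class
#' @export
setMethod("exprState", "ExpressionMatrix", function(object) object@state)

#' @rdname ExpressionMatrix-class
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' @rdname ExpressionMatrix-class
#' @export
setMethod("dimnames", "ExpressionMatrix", function(x) dimnames(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("ExpressionMatrix: %d transcripts x %d samples [%s]\n",
              d[1L], d[2L], object@state))
})

#' Homolog clusters from identity-based single-linkage grouping
#'
#' The result of [clusterHomologs()]: named member lists (cluster ids are
#' the names) and, per cluster, a representative chosen as the longest
#' member (ties broken by lexicographically smallest id).
#'
#' @slot members named list of character vectors of member transcript ids.
#' @slot representative character vector, one id per cluster, each an
#'   element of the corresponding member set.
#' @param object a `HomologClusterSet`.
#' @aliases clusterMembers clusterRepresentatives
#' @export
setClass("HomologClusterSet",
  representation(members = "list", representative = "character")
)

setValidity("HomologClusterSet", function(object) {
  msg <- character()
  if (length(object@members) != length(object@representative))
    msg <- c(msg, "one representative per cluster required")
  if (length(object@members) &&
      (is.null(names(object@members)) || anyDuplicated(names(object@members))))
    msg <- c(msg, "members must carry unique cluster ids as names")
  ok <- mapply(function(m, r) r %in% m, object@members, object@representative)
  if (length(ok) && !all(ok))
    msg <- c(msg, "each representative must belong to its cluster")
  if (length(msg)) msg else TRUE
})

#' @rdname HomologClusterSet-class
#' @export
setMethod("clusterMembers", "HomologClusterSet",
          function(object) object@members)

#' @rdname HomologClusterSet-class
#' @export
setMethod("clusterRepresentatives", "HomologClusterSet",
          function(object) object@representative)

#' @rdname HomologClusterSet-class
#' @export
setMethod("length", "HomologClusterSet", function(x) length(x@members))

setMethod("show", "HomologClusterSet", function(object) {
  sz <- lengths(object@members)
  cat(sprintf("HomologClusterSet: %d clusters", length(sz)))
  if (length(sz))
    cat(sprintf(" (sizes %d..%d, %d of size >= 4)",
                min(sz), max(sz), sum(sz >= 4)))
  cat("\n")
})

#' Accounting record of a filtering step
#'
#' Emitted by [filterReadsByGC()] and [crossSampleIdentityFilter()];
#' retained + removed always equals input.
#'
#' @slot input,retained,removed item counts.
#' @slot params the parameters the filter ran with.
#' @slot perSample per-sample breakdown (possibly empty).
#' @param object a `FilterReport`.
#' @export
setClass("FilterReport",
  representation(input = "integer", retained = "integer", removed = "integer",
                 params = "list", perSample = "data.frame")
)

setValidity("FilterReport", function(object) {
  if (object@retained + object@removed != object@input)
    "retained + removed must equal input" else TRUE
})

FilterReport <- function(input, retained, params = list(),
                         perSample = data.frame()) {
  new("FilterReport", input = as.integer(input), retained = as.integer(retained),
      removed = as.integer(input - retained), params = params,
      perSample = perSample)
}

setMethod("show", "FilterReport", function(object) {
  cat(sprintf("FilterReport: %d in, %d kept, %d removed\n",
              object@input, object@retained, object@removed))
})
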