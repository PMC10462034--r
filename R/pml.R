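#' Pseudo-matching lengths and document labels for a query
#'
#' Streams the query through the run-length BWT in a single pass,
#' maintaining the backward-search interval of the pattern matched so far.
#' While the interval stays non-empty the match extends and its length
#' grows; when the next symbol admits no extension the match resets and a
#' new one starts at length 1 (0 if the symbol is absent from the whole
#' index, in which case the document label is `NA` and the interval resets
#' to the full range). Each maximal match segment is reported as the
#' decreasing ramp `[L, L-1, ..., 1]`, so `P[i]` is the number of matched
#' symbols extending right from position i: the truncated matching
#' statistic. Each segment carries the document label established when the
#' segment closed, i.e. with its longest (most specific) pattern; labels
#' are exact whenever the tracked occurrence touches a run boundary and
#' propagate through LF steps in between.
#'
#' @param index a [PMLIndex-class].
#' @param query a [BinSequence-class] or integer vector of bin symbols.
#' @param readId identifier stored in the profile.
#' @return A [MatchProfile-class].
#' @export
computePML <- function(index, query, readId = "read") {
  st <- pmlState(index, readId)
  res <- resumePML(index, query, st)
  fin <- finalizePML(index, res$state)
  new("MatchProfile",
      P = c(res$fragment@P, fin@P),
      D = c(res$fragment@D, fin@D), readId = readId)
}

#' Streaming PML state
#'
#' A fresh state for chunk-wise PML computation on one read. The state
#' carries the backward-search interval, the tracked row, and the current
#' match length and document; the open segment is emitted when it closes
#' or at [finalizePML()].
#'
#' @param index a [PMLIndex-class].
#' @param readId read identifier; resuming with a different id errors.
#' @return a state list.
#' @export
pmlState <- function(index, readId = "read") {
  list(lo = 0L, hi = index@n, len = 0L, row = 0L, curDoc = NA_integer_,
       readId = readId)
}

#' @rdname pmlState
#' @param chunk a [BinSequence-class] or integer vector: the next query
#'   symbols.
#' @param state a state from [pmlState()] or a previous [resumePML()].
#' @return `resumePML`: list with `fragment` (a [MatchProfile-class]
#'   holding the positions finalized by this chunk) and `state`.
#'   Concatenating all fragments plus the [finalizePML()] tail equals the
#'   batch [computePML()] profile bit-for-bit.
#' @export
resumePML <- function(index, chunk, state, readId = state$readId) {
  if (!identical(readId, state$readId))
    stop(sprintf("streaming state belongs to read '%s', not '%s'",
                 state$readId, readId))
  if (is(chunk, "BinSequence")) chunk <- chunk@symbols
  enc <- as.integer(chunk) + index@nDocs + 1L
  maxSym <- index@nDocs + 1L + index@config$nBins
  res <- pml_query_cpp(enc, index@Ctab, index@symStarts, index@symLens,
                       index@symCum, index@symDocF, index@symDocL,
                       index@thresholds, index@n, maxSym,
                       state$lo, state$hi, state$len, state$row,
                       state$curDoc, FALSE)
  list(fragment = new("MatchProfile", P = res$P, D = res$D,
                      readId = state$readId),
       state = list(lo = res$lo, hi = res$hi, len = res$len,
                    row = res$row, curDoc = res$curDoc,
                    readId = state$readId))
}

#' @rdname pmlState
#' @return `finalizePML`: a [MatchProfile-class] fragment closing the open
#'   segment.
#' @export
finalizePML <- function(index, state) {
  maxSym <- index@nDocs + 1L + index@config$nBins
  res <- pml_query_cpp(integer(0), index@Ctab, index@symStarts,
                       index@symLens, index@symCum, index@symDocF,
                       index@symDocL, index@thresholds, index@n, maxSym,
                       state$lo, state$hi, state$len, state$row,
                       state$curDoc, TRUE)
  new("MatchProfile", P = res$P, D = res$D, readId = state$readId)
}

#' @describeIn MatchProfile-class PML vector.
#' @param object a `MatchProfile`.
#' @export
setGeneric("pml", function(object) standardGeneric("pml"))

#' @rdname MatchProfile-class
#' @export
setMethod("pml", "MatchProfile", function(object) object@P)

#' @rdname MatchProfile-class
#' @export
setGeneric("docLabels", function(object) standardGeneric("docLabels"))

#' @rdname MatchProfile-class
#' @export
setMethod("docLabels", "MatchProfile", function(object) object@D)

setMethod("show", "MatchProfile", function(object) {
  cat(sprintf("MatchProfile '%s': %d positions, max PML %d, %d peaks\n",
              object@readId, length(object@P),
              if (length(object@P)) max(object@P) else 0L,
              sum(peakIndicator(object@P))))
})
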