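#' Peak positions of a PML vector
#'
#' A "peak" is any position i with `P[i] >= P[i-1]`; since PMLs decrement
#' along a single match, a peak marks the start of a new match. Position 1
#' is a peak by convention (it starts a match). Summing only peak PMLs
#' keeps long matches from being counted once per contained position.
#'
#' @param P integer PML vector (or a [MatchProfile-class]).
#' @return logical vector.
#' @export
peakIndicator <- function(P) {
  if (is(P, "MatchProfile")) P <- P@P
  n <- length(P)
  if (n == 0L) return(logical(0))
  c(TRUE, P[-1L] >= P[-n])
}

#' Normalized shred sequence complexity
#'
#' Order-0 empirical entropy of each shred's bin symbols divided by
#' `log2(nBins)`, giving `C_d` in `[0, 1]` (0 for a single repeated symbol,
#' 1 for a uniform symbol distribution). Matches into low-complexity shreds
#' are down-weighted by this factor, since long matches to tandem-repeat-like
#' regions arise by coincidence. Computed once at build time from shred
#' content; sentinel symbols are excluded.
#'
#' @param ref a [ReferenceText-class].
#' @return named numeric vector, one `C_d` per doc_id.
#' @export
shredComplexity <- function(ref) {
  nb <- ref@nBins
  st <- ref@shredTable
  docs <- sort(unique(st$doc_id))
  counts <- matrix(0, nrow = length(docs), ncol = nb,
                   dimnames = list(as.character(docs), NULL))
  segInfo <- ref@seqInfo
  for (j in seq_len(nrow(st))) {
    si <- which(segInfo$segStart <= st$start[j] &
                segInfo$segStart + segInfo$length >= st$end[j] &
                segInfo$name == st$ref_name[j] &
                segInfo$strand == st$strand[j])[1L]
    loc <- ref@segments[[si]][(st$start[j] - segInfo$segStart[si] + 1L):
                              (st$end[j] - segInfo$segStart[si])]
    loc <- loc[loc < nb]  # drop sentinel
    if (length(loc))
      counts[as.character(st$doc_id[j]), ] <-
        counts[as.character(st$doc_id[j]), ] + tabulate(loc + 1L, nb)
  }
  cx <- apply(counts, 1L, function(cn) {
    tot <- sum(cn)
    if (tot == 0) return(0)
    p <- cn[cn > 0] / tot
    -sum(p * log2(p)) / log2(nb)
  })
  names(cx) <- as.character(docs)
  cx
}

#' Complexity-weighted document vote
#'
#' For each document d, the score is
#' \eqn{C_d \sum_i P[i] \cdot [D[i]=d] \cdot [peak at i]}: the sum of peak
#' PMLs attributed to d, scaled by the shred's sequence complexity.
#' Positions with no document (absent query symbols) contribute nothing.
#'
#' @param profile a [MatchProfile-class].
#' @param complexity named numeric `C_d` per doc_id, or `NULL` to disable
#'   the complexity correction (all weights 1).
#' @param shredTable the shred table; every document seen in the profile
#'   must appear in it.
#' @return named numeric vector of non-negative scores per doc_id (only
#'   documents with non-zero attributed peaks appear).
#' @export
documentScores <- function(profile, complexity, shredTable) {
  P <- profile@P
  D <- profile@D
  pk <- peakIndicator(P)
  use <- pk & !is.na(D) & P > 0L
  if (!any(use)) return(stats::setNames(numeric(0), character(0)))
  docs <- D[use]
  unknown <- setdiff(unique(docs), shredTable$doc_id)
  if (length(unknown))
    stop(sprintf("document %d in profile is absent from the shred table",
                 unknown[1L]))
  s <- tapply(as.numeric(P[use]), docs, sum)
  out <- as.numeric(s)
  names(out) <- names(s)
  if (!is.null(complexity)) {
    cx <- complexity[names(out)]
    cx[is.na(cx)] <- 1
    out <- out * cx
  }
  out
}

# deterministic doc ordering for argmax ties: ref_name, then doc_id
.docOrderKey <- function(docs, shredTable) {
  first <- shredTable[match(as.integer(docs), shredTable$doc_id), ]
  order(first$ref_name, as.integer(docs))
}

.emptyCall <- function(readId, mode) {
  data.frame(read_id = readId, mode = mode, predicted_class = "unclassified",
             top_doc = NA_integer_, score = 0, ratio = NA_real_,
             tau = NA_real_, n_chunks = NA_integer_,
             n_symbols = NA_integer_, stringsAsFactors = FALSE)
}

#' Multi-class read call from document scores
#'
#' The read is assigned to the class of the argmax-scoring document. Ties
#' break toward the lexicographically smallest reference name, then the
#' smallest doc_id. All-zero scores yield `"unclassified"`.
#'
#' @param scores named numeric from [documentScores()].
#' @param shredTable the shred table (doc -> class lookup).
#' @param readId read identifier.
#' @return one-row data.frame (read_id, mode, predicted_class, top_doc,
#'   score, ratio, tau, n_chunks, n_symbols).
#' @export
classifyMulticlass <- function(scores, shredTable, readId = "read") {
  scores <- scores[scores > 0]
  if (!length(scores)) return(.emptyCall(readId, "multi"))
  ord <- .docOrderKey(names(scores), shredTable)
  scores <- scores[ord]
  top <- names(scores)[which.max(scores)]
  cls <- shredTable$class[match(as.integer(top), shredTable$doc_id)]
  out <- .emptyCall(readId, "multi")
  out$predicted_class <- cls
  out$top_doc <- as.integer(top)
  out$score <- max(scores)
  out
}

#' Binary (spike-ratio) read call
#'
#' Compares the top-scoring document of the positive class against the top
#' of the null class: the read is positive iff their ratio exceeds the
#' spike-ratio threshold `tau` (strictly). A zero null score with a
#' positive score yields ratio `Inf` (positive); all-zero scores yield
#' `"unclassified"`.
#'
#' @param scores named numeric from [documentScores()].
#' @param classMap named roles per class; must contain a `"positive"` and a
#'   `"null"` role.
#' @param shredTable the shred table.
#' @param tau spike-ratio threshold; the default 1.0 suits classes in
#'   roughly equal proportion (see [calibrateThreshold()] otherwise).
#' @param readId read identifier.
#' @return one-row data.frame as in [classifyMulticlass()].
#' @export
classifyBinary <- function(scores, classMap, shredTable, tau = 1.0,
                           readId = "read") {
  if (!any(classMap == "positive") || !any(classMap == "null"))
    stop("binary mode needs both a positive- and a null-role class")
  if (tau <= 0) stop("tau must be positive")
  cls <- shredTable$class[match(as.integer(names(scores)),
                                shredTable$doc_id)]
  roles <- classMap[cls]
  topOf <- function(role) {
    s <- scores[which(roles == role)]
    s <- s[s > 0]
    if (!length(s)) return(NULL)
    s <- s[.docOrderKey(names(s), shredTable)]
    s[which.max(s)]
  }
  tp <- topOf("positive")
  tn <- topOf("null")
  out <- .emptyCall(readId, "binary")
  out$tau <- tau
  if (is.null(tp) && is.null(tn)) return(out)
  ratio <- if (is.null(tp)) 0 else if (is.null(tn)) Inf else
    unname(tp) / unname(tn)
  out$ratio <- ratio
  if (!is.null(tp) && ratio > tau) {
    top <- tp
  } else if (!is.null(tn)) {
    top <- tn
  } else {
    return(out)  # only a positive doc, but ratio not above tau: keep null-free unclassified
  }
  doc <- as.integer(names(top))
  out$predicted_class <- shredTable$class[match(doc, shredTable$doc_id)]
  out$top_doc <- doc
  out$score <- unname(top)
  out
}

#' Calibrate the spike-ratio threshold from burn-in ratios
#'
#' During a burn-in period the observed spike ratios are collected and
#' `tau` is set to the `(1 - expectedPositiveFraction)` quantile (linear
#' interpolation between order statistics), so the expected positive-call
#' rate matches the expected class abundance.
#'
#' @param burninRatios numeric spike ratios observed during burn-in
#'   (`Inf` allowed; at least one finite value required).
#' @param expectedPositiveFraction expected fraction of positive-class
#'   reads, in (0, 1).
#' @return the calibrated threshold.
#' @export
calibrateThreshold <- function(burninRatios, expectedPositiveFraction) {
  if (!length(burninRatios)) stop("empty burn-in ratio set")
  if (!any(is.finite(burninRatios))) stop("no finite burn-in ratios")
  f <- expectedPositiveFraction
  if (!(f > 0 && f < 1)) stop("expectedPositiveFraction must be in (0,1)")
  stats::quantile(burninRatios, probs = 1 - f, names = FALSE, type = 7)
}

#' Classify one read's raw signal (batch)
#'
#' Full pipeline: segmentation, normalization, quantization, run
#' compression, PML computation, complexity-weighted document vote.
#'
#' @param samples numeric pA samples of one read.
#' @param index a [PMLIndex-class].
#' @param model,cfg,params pipeline components.
#' @param mode `"multi"` or `"binary"`.
#' @param tau spike-ratio threshold (binary mode).
#' @param normalize normalize event means to model moments.
#' @param complexityCorrection apply the `C_d` weights.
#' @param readId read identifier.
#' @return one-row call data.frame.
#' @export
classifyRead <- function(samples, index, model, cfg,
                         params = eventParams(), mode = c("multi", "binary"),
                         tau = 1.0, normalize = TRUE,
                         complexityCorrection = TRUE, readId = "read") {
  mode <- match.arg(mode)
  bs <- signalToBinSeq(samples, model, cfg, params, normalize)
  prof <- computePML(index, bs, readId)
  cx <- if (complexityCorrection) index@complexity else NULL
  sc <- documentScores(prof, cx, index@shredTable)
  out <- if (mode == "multi")
    classifyMulticlass(sc, index@shredTable, readId)
  else
    classifyBinary(sc, index@classMap, index@shredTable, tau, readId)
  out$n_chunks <- 1L
  out$n_symbols <- length(bs@symbols)
  out
}

#' @rdname classifyRead
#' @param signals named list of sample vectors (e.g. from
#'   [readSignalFixture()] or [simulateDataset()]).
#' @return `classifyReads`: a call data.frame with one row per read.
#' @export
classifyReads <- function(signals, index, model, cfg,
                          params = eventParams(),
                          mode = c("multi", "binary"), tau = 1.0,
                          normalize = TRUE, complexityCorrection = TRUE) {
  mode <- match.arg(mode)
  do.call(rbind, lapply(seq_along(signals), function(i)
    classifyRead(signals[[i]], index, model, cfg, params, mode, tau,
                 normalize, complexityCorrection,
                 readId = names(signals)[i])))
}

#' Chunked (adaptive-sampling style) classification of one read
#'
#' Processes the read's signal chunk by chunk (a typical chunk is ~4,000
#' samples, about one second of sequencing): after each chunk the event
#' stream and normalization are extended over all signal seen so far, the
#' query bin sequence is re-derived, the PML pass is resumed (restarted
#' only if re-normalization changed the already-emitted prefix), and a
#' call is emitted. The decision after the final chunk equals the batch
#' decision on the full signal.
#'
#' @param chunks list of numeric vectors, the read's signal in arrival
#'   order.
#' @inheritParams classifyRead
#' @return data.frame of per-chunk calls.
#' @export
classifyStream <- function(chunks, index, model, cfg,
                           params = eventParams(),
                           mode = c("multi", "binary"), tau = 1.0,
                           normalize = TRUE, complexityCorrection = TRUE,
                           readId = "read") {
  mode <- match.arg(mode)
  es <- eventStream(params)
  pst <- pmlState(index, readId)
  accP <- accD <- integer(0)
  prevSyms <- integer(0)
  cx <- if (complexityCorrection) index@complexity else NULL
  calls <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    es <- feedSignal(es, chunks[[ci]])
    bs <- signalToBinSeq(es$raw, model, cfg, params, normalize)
    syms <- bs@symbols
    np <- length(prevSyms)
    extends <- length(syms) >= np &&
      (np == 0L || identical(syms[seq_len(np)], prevSyms))
    if (!extends) {  # re-normalization rewrote the prefix: restart the pass
      pst <- pmlState(index, readId)
      accP <- accD <- integer(0)
      np <- 0L
    }
    newSyms <- if (length(syms) > np) syms[(np + 1L):length(syms)] else
      integer(0)
    res <- resumePML(index, newSyms, pst)
    pst <- res$state
    accP <- c(accP, res$fragment@P)
    accD <- c(accD, res$fragment@D)
    tail <- finalizePML(index, pst)  # pure: previews the open segment
    prof <- new("MatchProfile", P = c(accP, tail@P), D = c(accD, tail@D),
                readId = readId)
    sc <- documentScores(prof, cx, index@shredTable)
    call <- if (mode == "multi")
      classifyMulticlass(sc, index@shredTable, readId)
    else
      classifyBinary(sc, index@classMap, index@shredTable, tau, readId)
    call$n_chunks <- ci
    call$n_symbols <- length(syms)
    calls[[ci]] <- call
    prevSyms <- syms
  }
  do.call(rbind, calls)
}
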