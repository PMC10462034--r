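#' Event detector parameter sets
#'
#' Defaults follow the two-window t-test segmentation used across the
#' squiggle-mapping tool family for R9.4 DNA signal (windows of 3 and 6
#' samples, thresholds 4.30265 and 2.57058, peak height 1.0), chosen to
#' balance stay and skip errors. All five constants are configuration, not
#' hard-coded truth, and are recorded in classification reports.
#'
#' @param shortWindow,longWindow window sizes in samples.
#' @param shortThreshold,longThreshold t-statistic cutoffs.
#' @param peakHeight minimum peak prominence.
#' @return An [EventParams-class].
#' @export
eventParams <- function(shortWindow = 3L, longWindow = 6L,
                        shortThreshold = 4.30265, longThreshold = 2.57058,
                        peakHeight = 1.0) {
  new("EventParams", shortWindow = as.integer(shortWindow),
      longWindow = as.integer(longWindow),
      shortThreshold = shortThreshold, longThreshold = longThreshold,
      peakHeight = peakHeight)
}

setMethod("show", "EventParams", function(object) {
  cat(sprintf(
    "EventParams: windows %d/%d, thresholds %.3f/%.3f, peak height %.2f\n",
    object@shortWindow, object@longWindow, object@shortThreshold,
    object@longThreshold, object@peakHeight))
})

#' Segment raw signal into events
#'
#' Runs a rolling two-window Welch t-test over the samples and places event
#' boundaries at t-statistic peaks exceeding either threshold. Each event is
#' summarized by its mean current `ec`, dwell time `et` (samples) and
#' 0-based `start` index; events tile the input.
#'
#' @param raw numeric vector of picoamp samples.
#' @param params an [EventParams-class].
#' @return data.frame with columns `start`, `et`, `ec`.
#' @export
detectEvents <- function(raw, params = eventParams()) {
  n <- length(raw)
  if (n < params@longWindow) {
    warning("signal shorter than the long window; no events detected")
    return(data.frame(start = integer(0), et = integer(0), ec = numeric(0)))
  }
  b <- event_boundaries_cpp(raw, params@shortWindow, params@longWindow,
                            params@shortThreshold, params@longThreshold,
                            params@peakHeight)
  starts <- c(0L, b)
  ends <- c(b, n)
  cs <- c(0, cumsum(raw))
  data.frame(start = starts, et = ends - starts,
             ec = (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts))
}

#' Streaming event detection state
#'
#' `eventStream()` creates a fresh state; [feedSignal()] appends a chunk and
#' returns the updated state. The state buffers the read's raw samples, so
#' [streamEvents()] on the final state is exactly [detectEvents()] on the
#' concatenated signal: chunked and batch segmentations agree by
#' construction, with no chunk-edge artifacts.
#'
#' @param params an [EventParams-class].
#' @return a state list.
#' @export
eventStream <- function(params = eventParams()) {
  list(raw = numeric(0), params = params, nChunks = 0L)
}

#' @rdname eventStream
#' @param state a state from [eventStream()] / [feedSignal()].
#' @param chunk numeric vector of new samples.
#' @export
feedSignal <- function(state, chunk) {
  state$raw <- c(state$raw, chunk)
  state$nChunks <- state$nChunks + 1L
  state
}

#' @rdname eventStream
#' @export
streamEvents <- function(state) {
  if (length(state$raw) < state$params@longWindow)
    return(data.frame(start = integer(0), et = integer(0), ec = numeric(0)))
  detectEvents(state$raw, state$params)
}

#' Single-pass running moments (Welford update)
#'
#' @param x numeric vector.
#' @return list with `mean` and population `sd`, accumulated in one pass.
#' @export
welfordMoments <- function(x) {
  n <- 0L
  mu <- 0
  m2 <- 0
  for (v in x) {
    n <- n + 1L
    d <- v - mu
    mu <- mu + d / n
    m2 <- m2 + d * (v - mu)
  }
  list(mean = mu, sd = if (n > 0L) sqrt(m2 / n) else NaN)
}

#' Normalize event currents to the pore model's scale
#'
#' Method-of-moments normalization: event means are shifted and scaled so
#' that their running mean and standard deviation (maintained with the
#' Welford streaming update) match the mean and standard deviation of the
#' pore model's level means. Dwell times are unchanged.
#'
#' @param events data.frame from [detectEvents()].
#' @param model a [PoreModel-class].
#' @return the events data.frame with normalized `ec`.
#' @export
normalizeEvents <- function(events, model) {
  if (nrow(events) < 2L) stop("need at least 2 events to normalize")
  w <- welfordMoments(events$ec)
  if (w$sd <= 0) stop("degenerate signal: zero variance across events")
  mm <- .modelMoments(model)
  events$ec <- (events$ec - w$mean) / w$sd * mm["sd"] + mm["mean"]
  events
}

#' Collapse runs of identical symbols
#'
#' Homopolymer-style compression of the bin alphabet: consecutive equal
#' symbols collapse to one. This absorbs "stay" over-segmentation errors,
#' where one k-mer spans several events that all land in the same bin. The
#' reference is compressed the same way so true repeats remain queryable.
#'
#' @param bins a [BinSequence-class] (or plain integer vector).
#' @return a run-compressed [BinSequence-class] (or integer vector).
#' @export
compressRuns <- function(bins) {
  plain <- !is(bins, "BinSequence")
  s <- if (plain) as.integer(bins) else bins@symbols
  n <- length(s)
  if (n > 1L) s <- s[c(TRUE, s[-1L] != s[-n])]
  if (plain) return(s)
  new("BinSequence", symbols = s, nBins = bins@nBins, hpc = TRUE)
}

#' Raw signal to run-compressed query bin sequence
#'
#' The full query-side pipeline: event detection, (optional) moment
#' normalization against the pore model, quantization into the bin
#' alphabet, and run compression, in that order.
#'
#' @param raw numeric pA samples.
#' @param model a [PoreModel-class].
#' @param cfg a [BinningConfig-class].
#' @param params an [EventParams-class].
#' @param normalize normalize event means to the model moments (default
#'   `TRUE`; disable for signal already on the model's pA scale, e.g.
#'   noise-free simulation).
#' @return a compressed [BinSequence-class]; attribute `nEvents` carries the
#'   event count.
#' @export
signalToBinSeq <- function(raw, model, cfg, params = eventParams(),
                           normalize = TRUE) {
  ev <- detectEvents(raw, params)
  if (nrow(ev) == 0L)
    return(new("BinSequence", symbols = integer(0), nBins = cfg@nBins,
               hpc = TRUE))
  if (normalize && nrow(ev) >= 2L) ev <- normalizeEvents(ev, model)
  out <- compressRuns(quantizeSignal(ev$ec, cfg))
  attr(out, "nEvents") <- nrow(ev)
  out
}

#' Read/write the plain-text signal fixture format
#'
#' One read per line: `read_id<TAB>space-separated float samples`. This is
#' the test-suite carrier for raw signal; production FAST5/SLOW5/POD5
#' readers fulfil the same contract (read id + sample vector).
#'
#' @param path file path.
#' @return named list of numeric sample vectors.
#' @export
readSignalFixture <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  sig <- lapply(parts, function(p)
    as.numeric(strsplit(p[[2L]], " ", fixed = TRUE)[[1L]]))
  names(sig) <- ids
  sig
}

#' @rdname readSignalFixture
#' @param signals named list of numeric vectors.
#' @export
writeSignalFixture <- function(signals, path) {
  lines <- vapply(seq_along(signals), function(i)
    paste0(names(signals)[i], "\t",
           paste(sprintf("%.4f", signals[[i]]), collapse = " ")), "")
  writeLines(lines, path)
  invisible(path)
}
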