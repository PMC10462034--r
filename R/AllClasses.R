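#' @import methods
NULL

#' Pore model: expected current per k-mer
#'
#' Maps each of the 4^k nucleotide k-mers to the expected picoamp level
#' (mean and spread) it produces while resident in the pore. The global
#' range of level means defines the quantization alphabet.
#'
#' @slot k k-mer length.
#' @slot levelMean named numeric, expected mean current (pA) per k-mer.
#' @slot levelSd named numeric, level spread (pA) per k-mer.
#' @slot minP,maxP range of the level means (pA).
#' @export
setClass("PoreModel",
  representation(k = "integer", levelMean = "numeric", levelSd = "numeric",
                 minP = "numeric", maxP = "numeric"))

setValidity("PoreModel", function(object) {
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 1L)
    return("k must be a single positive integer")
  kmers <- names(object@levelMean)
  if (length(object@levelMean) != 4L^k)
    return(sprintf("pore model must cover all %d %d-mers", 4L^k, k))
  if (anyDuplicated(kmers)) return("duplicate k-mers in pore model")
  if (any(nchar(kmers) != k)) return("inconsistent k-mer lengths")
  if (!identical(names(object@levelSd), kmers))
    return("levelSd names must match levelMean names")
  if (any(!is.finite(object@levelMean)) || any(!is.finite(object@levelSd)))
    return("non-finite level values")
  if (any(object@levelSd < 0)) return("negative level sd")
  if (!isTRUE(object@minP < object@maxP)) return("minP must be < maxP")
  if (abs(object@minP - min(object@levelMean)) > 1e-9 ||
      abs(object@maxP - max(object@levelMean)) > 1e-9)
    return("minP/maxP must equal the range of level means")
  TRUE
})

#' Picoamp bin alphabet
#'
#' Partition of the pore model's current range \eqn{[min_p, max_p]} into
#' `nBins` equal-width, left-closed/right-open bins of width
#' \eqn{s_p = (max_p - min_p)/n}. Values below the range map to bin 0,
#' above it to bin n-1.
#'
#' @slot nBins alphabet size (default 6).
#' @slot sp bin width in pA.
#' @slot minP,maxP pA range copied from the model.
#' @export
setClass("BinningConfig",
  representation(nBins = "integer", sp = "numeric",
                 minP = "numeric", maxP = "numeric"))

setValidity("BinningConfig", function(object) {
  if (object@nBins < 2L) return("nBins must be >= 2")
  if (!isTRUE(object@sp > 0)) return("bin width must be positive")
  if (abs(object@sp - (object@maxP - object@minP) / object@nBins) > 1e-9)
    return("sp must equal (maxP - minP)/nBins")
  TRUE
})

#' A read or reference rendered over the picoamp-bin alphabet
#'
#' @slot symbols integer vector with values in `[0, nBins-1]`; the value
#'   `nBins` is a reserved sentinel used for reference positions derived
#'   from ambiguous bases (it can never match a query symbol).
#' @slot nBins alphabet size.
#' @slot hpc `TRUE` if same-symbol runs have been compressed.
#' @export
setClass("BinSequence",
  representation(symbols = "integer", nBins = "integer", hpc = "logical"))

setValidity("BinSequence", function(object) {
  s <- object@symbols
  if (anyNA(s)) return("NA symbols not allowed")
  if (length(s) && (min(s) < 0L || max(s) > object@nBins))
    return("symbols out of range")
  if (isTRUE(object@hpc) && length(s) > 1L &&
      any(s[-1L] == s[-length(s)]))
    return("hpc sequence has adjacent equal symbols")
  TRUE
})

#' Event detector parameters
#'
#' Two-window rolling Welch t-test segmentation: the short window reacts to
#' abrupt current jumps, the long window to subtle ones. Both thresholds are
#' on the t-statistic scale; `peakHeight` is the drop below a running peak
#' required before a second peak may be called in the same excursion.
#'
#' @slot shortWindow,longWindow window sizes in samples.
#' @slot shortThreshold,longThreshold t-statistic cutoffs.
#' @slot peakHeight minimum peak prominence.
#' @export
setClass("EventParams",
  representation(shortWindow = "integer", longWindow = "integer",
                 shortThreshold = "numeric", longThreshold = "numeric",
                 peakHeight = "numeric"))

setValidity("EventParams", function(object) {
  if (!(object@shortWindow >= 1L && object@longWindow > object@shortWindow))
    return("need 1 <= shortWindow < longWindow")
  if (object@shortThreshold <= 0 || object@longThreshold <= 0)
    return("thresholds must be positive")
  TRUE
})

#' Binned, shredded, class-labeled reference text
#'
#' Each input sequence (and, by default, its reverse complement) is rendered
#' into the bin alphabet, run-compressed, and stored as one strand-sequence
#' followed by a terminator. Positions are partitioned into equal-length
#' "shreds", each carrying a document id and a class label; reverse-strand
#' intervals share the document ids of the mirrored forward shreds.
#'
#' @slot segments list of integer vectors (bin symbols per strand-sequence).
#' @slot seqInfo data.frame: name, class, strand, segStart (0-based offset of
#'   the segment in the concatenated text), length.
#' @slot shredTable data.frame: doc_id, ref_name, class, start, end (0-based
#'   half-open, concatenated-text coordinates), strand.
#' @slot classMap named character: class label -> role
#'   (`"positive"`, `"null"` or `"plain"`).
#' @slot nBins,hpc,k,shredSize build parameters.
#' @slot modelHash digest of the pore model used.
#' @export
setClass("ReferenceText",
  representation(segments = "list", seqInfo = "data.frame",
                 shredTable = "data.frame", classMap = "character",
                 nBins = "integer", hpc = "logical", k = "integer",
                 shredSize = "numeric", modelHash = "character"))

setValidity("ReferenceText", function(object) {
  if (!length(object@segments)) return("empty reference")
  if (nrow(object@seqInfo) != length(object@segments))
    return("seqInfo rows must match segments")
  st <- object@shredTable
  need <- c("doc_id", "ref_name", "class", "start", "end", "strand")
  if (!all(need %in% names(st))) return("incomplete shred table")
  if (any(st$end <= st$start)) return("empty shred interval")
  TRUE
})

#' Run-length BWT index with thresholds and sampled document labels
#'
#' Stores the maximal equal-symbol runs of the BWT built over the (per
#' strand-sequence reversed) reference text, per-symbol rank tables, the
#' thresholds structure (LCP argmin per same-symbol run gap), document
#' labels sampled at the first and last offset of every run, per-shred
#' sequence complexity, and the shred table. Queries are answered run-wise
#' in a single streaming pass.
#'
#' @slot runStarts,runSyms,runLens the BWT runs (0-based starts).
#' @slot n text length in symbols (terminators included).
#' @slot r number of BWT runs.
#' @slot nDocs number of strand-sequences (= terminators).
#' @slot Ctab F-column offsets per encoded symbol.
#' @slot symStarts,symLens,symCum,symDocF,symDocL per-symbol run rank
#'   tables and run-boundary document samples.
#' @slot thresholds list per symbol of switch offsets between consecutive
#'   runs of that symbol.
#' @slot docFirst,docLast document labels at run boundaries.
#' @slot shredTable,classMap,complexity classification metadata.
#' @slot config build configuration (nBins, shredSize, strand flag, pore
#'   model hash, ...).
#' @export
setClass("PMLIndex",
  representation(runStarts = "integer", runSyms = "integer",
                 runLens = "integer", n = "integer", r = "integer",
                 nDocs = "integer", Ctab = "integer",
                 symStarts = "list", symLens = "list", symCum = "list",
                 symDocF = "list", symDocL = "list", thresholds = "list",
                 docFirst = "integer", docLast = "integer",
                 shredTable = "data.frame", classMap = "character",
                 complexity = "numeric", config = "list"))

setValidity("PMLIndex", function(object) {
  if (object@r > object@n) return("r must be <= n")
  if (length(object@runStarts) != object@r) return("run count mismatch")
  if (sum(object@runLens) != object@n) return("runs must tile the text")
  if (object@runStarts[1L] != 0L ||
      any(diff(object@runStarts) != object@runLens[-object@r]))
    return("runs must be contiguous")
  TRUE
})

#' Per-position match profile of a query
#'
#' `P[i]` is the pseudo-matching length at query position i (the length of
#' the greedy exact match extending right from i within its match segment);
#' `D[i]` the document (shred) label attributed to that position, `NA` where
#' the symbol is absent from the index.
#'
#' @slot P integer PML vector.
#' @slot D integer document labels (NA = no document).
#' @slot readId read identifier.
#' @export
setClass("MatchProfile",
  representation(P = "integer", D = "integer", readId = "character"))

setValidity("MatchProfile", function(object) {
  if (length(object@P) != length(object@D)) return("P and D lengths differ")
  if (length(object@P) && min(object@P) < 0L) return("negative PML")
  n <- length(object@P)
  if (n > 1L && any(object@P[-1L] < object@P[-n] - 1L))
    return("PML decays by more than 1")
  TRUE
})
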