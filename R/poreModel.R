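#' Construct a pore model from level tables
#'
#' @param levelMean named numeric vector of expected mean currents (pA), one
#'   per k-mer; names are the k-mers.
#' @param levelSd named numeric vector of level spreads (pA), same names.
#' @return A [PoreModel-class] object.
#' @export
PoreModel <- function(levelMean, levelSd) {
  kmers <- names(levelMean)
  k <- as.integer(nchar(kmers[1L]))
  ord <- order(kmers)
  new("PoreModel", k = k,
      levelMean = levelMean[ord], levelSd = levelSd[ord],
      minP = min(levelMean), maxP = max(levelMean))
}

#' Read a pore model from a tab-separated table
#'
#' The table must have a header with columns `kmer`, `level_mean` and
#' `level_stdv` (the usual ONT model dump layout); extra columns are
#' ignored. All 4^k k-mers must be present exactly once.
#'
#' @param path path to the TSV file.
#' @return A [PoreModel-class].
#' @export
loadPoreModel <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("kmer", "level_mean", "level_stdv")
  if (!all(need %in% names(tab)))
    stop("pore model table must have columns kmer, level_mean, level_stdv")
  if (anyDuplicated(tab$kmer)) {
    dup <- tab$kmer[duplicated(tab$kmer)][1L]
    stop(sprintf("duplicate k-mer row '%s' in pore model", dup))
  }
  if (length(unique(nchar(tab$kmer))) != 1L)
    stop("inconsistent k-mer lengths in pore model")
  lm <- suppressWarnings(as.numeric(tab$level_mean))
  ls <- suppressWarnings(as.numeric(tab$level_stdv))
  bad <- which(!is.finite(lm) | !is.finite(ls))
  if (length(bad))
    stop(sprintf("non-numeric level in pore model row for k-mer '%s'",
                 tab$kmer[bad[1L]]))
  k <- nchar(tab$kmer[1L])
  if (nrow(tab) != 4^k)
    stop(sprintf("pore model has %d rows; expected %d for k=%d",
                 nrow(tab), 4^k, k))
  names(lm) <- names(ls) <- tab$kmer
  PoreModel(lm, ls)
}

#' Write a pore model to the TSV dialect read by [loadPoreModel()]
#' @param model a [PoreModel-class].
#' @param path output path.
#' @export
writePoreModel <- function(model, path) {
  tab <- data.frame(kmer = names(model@levelMean),
                    level_mean = model@levelMean,
                    level_stdv = model@levelSd)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic pore model
#'
#' Real pore chemistries come with vendor-published k-mer level tables; this
#' generator produces a synthetic stand-in with the same shape so the whole
#' pipeline can run self-contained. Level means are drawn uniformly over a
#' documented R9.4-like current range and level spreads uniformly over a
#' typical spread range; the draw is deterministic in `seed`.
#'
#' @param k k-mer length (default 6).
#' @param meanRange pA range of level means, default `c(60, 130)`.
#' @param sdRange pA range of level spreads, default `c(1, 3)`.
#' @param seed RNG seed.
#' @return A [PoreModel-class].
#' @export
syntheticPoreModel <- function(k = 6L, meanRange = c(60, 130),
                               sdRange = c(1, 3), seed = 101L) {
  nk <- 4L^as.integer(k)
  kmers <- sort(do.call(paste0, expand.grid(
    rep(list(c("A", "C", "G", "T")), k), stringsAsFactors = FALSE)))
  old <- .saveSeed()
  on.exit(.restoreSeed(old))
  set.seed(seed)
  lm <- stats::runif(nk, meanRange[1L], meanRange[2L])
  # pin the extremes so the quantization range equals meanRange exactly
  lm[which.min(lm)] <- meanRange[1L]
  lm[which.max(lm)] <- meanRange[2L]
  ls <- stats::runif(nk, sdRange[1L], sdRange[2L])
  names(lm) <- names(ls) <- kmers
  PoreModel(lm, ls)
}

.saveSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @describeIn PoreModel-class k-mer length.
#' @param object,model a `PoreModel`.
#' @export
setGeneric("kmerSize", function(object) standardGeneric("kmerSize"))

#' @rdname PoreModel-class
#' @export
setMethod("kmerSize", "PoreModel", function(object) object@k)

#' @rdname PoreModel-class
#' @export
setGeneric("levelMeans", function(object) standardGeneric("levelMeans"))

#' @rdname PoreModel-class
#' @export
setMethod("levelMeans", "PoreModel", function(object) object@levelMean)

#' @rdname PoreModel-class
#' @export
setGeneric("levelSds", function(object) standardGeneric("levelSds"))

#' @rdname PoreModel-class
#' @export
setMethod("levelSds", "PoreModel", function(object) object@levelSd)

#' @rdname PoreModel-class
#' @export
setGeneric("modelRange", function(object) standardGeneric("modelRange"))

#' @rdname PoreModel-class
#' @export
setMethod("modelRange", "PoreModel",
          function(object) c(minP = object@minP, maxP = object@maxP))

setMethod("show", "PoreModel", function(object) {
  cat(sprintf("PoreModel: k=%d, %d k-mers, level means %.1f-%.1f pA\n",
              object@k, length(object@levelMean), object@minP, object@maxP))
})

# population moments of the level means; the normalization target
.modelMoments <- function(model) {
  mu <- mean(model@levelMean)
  sigma <- sqrt(mean((model@levelMean - mu)^2))
  c(mean = mu, sd = sigma)
}

# deterministic content hash, for provenance in build configs
.modelHash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(sprintf("%s\t%.6f\t%.6f", names(model@levelMean),
                     model@levelMean, model@levelSd), f)
  unname(tools::md5sum(f))
}

# encode A,C,G,T -> 0..3 (anything else NA)
.baseCodes <- function(seq) {
  v <- utf8ToInt(toupper(seq))
  code <- rep(NA_integer_, 128L)
  code[utf8ToInt("A") + 1L] <- 0L
  code[utf8ToInt("C") + 1L] <- 1L
  code[utf8ToInt("G") + 1L] <- 2L
  code[utf8ToInt("T") + 1L] <- 3L
  code[v + 1L]
}

#' Expected current trace of a nucleotide sequence
#'
#' Slides a k-wide window over `seq` and looks up the pore model's expected
#' mean current for each k-mer. Windows containing ambiguous bases (N etc.)
#' yield `NA`; downstream reference construction maps those to a sentinel
#' symbol that can never match a query.
#'
#' @param seq nucleotide string (A/C/G/T, case-insensitive).
#' @param model a [PoreModel-class].
#' @return numeric vector of length `nchar(seq) - k + 1` (pA).
#' @export
expectedSignal <- function(seq, model) {
  k <- model@k
  b <- .baseCodes(seq)
  n <- length(b)
  if (n < k) stop(sprintf("sequence length %d is shorter than k=%d", n, k))
  nw <- n - k + 1L
  idx <- rep(0, nw)
  ok <- rep(TRUE, nw)
  for (j in seq_len(k)) {
    bj <- b[j:(j + nw - 1L)]
    ok <- ok & !is.na(bj)
    bj[is.na(bj)] <- 0L
    idx <- idx * 4 + bj
  }
  # levelMean is sorted lexicographically == base-4 order of the encoding
  out <- rep(NA_real_, nw)
  out[ok] <- model@levelMean[idx[ok] + 1L]
  out
}

#' Define the picoamp bin alphabet over a pore model's range
#'
#' The current range \eqn{[min_p, max_p]} of the model's level means is cut
#' into `nBins` equal bins of width \eqn{s_p = (max_p - min_p)/n}.
#'
#' @param model a [PoreModel-class].
#' @param nBins alphabet size, default 6.
#' @return A [BinningConfig-class].
#' @export
makeBins <- function(model, nBins = 6L) {
  nBins <- as.integer(nBins)
  if (is.na(nBins) || nBins < 2L) stop("nBins must be an integer >= 2")
  new("BinningConfig", nBins = nBins,
      sp = (model@maxP - model@minP) / nBins,
      minP = model@minP, maxP = model@maxP)
}

#' @describeIn BinningConfig-class bin width in pA.
#' @param object a `BinningConfig`.
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname BinningConfig-class
#' @export
setMethod("binWidth", "BinningConfig", function(object) object@sp)

setMethod("show", "BinningConfig", function(object) {
  cat(sprintf("BinningConfig: %d bins of %.3f pA over [%.1f, %.1f]\n",
              object@nBins, object@sp, object@minP, object@maxP))
})

#' Quantize picoamp values into the bin alphabet
#'
#' Each value v maps to bin 0 if below the model range, bin n-1 if above it,
#' and otherwise to `floor((v - minP)/sp)`, with v = maxP assigned to bin
#' n-1 (bins are left-closed/right-open).
#'
#' @param values numeric pA values (event means or expected currents).
#' @param cfg a [BinningConfig-class].
#' @param naAsSentinel if `TRUE`, `NA` values (ambiguous-base reference
#'   windows) become the sentinel symbol `nBins` instead of an error.
#' @return A [BinSequence-class] (uncompressed).
#' @export
quantizeSignal <- function(values, cfg, naAsSentinel = FALSE) {
  nb <- cfg@nBins
  nav <- is.na(values)
  if (any(nav) && !naAsSentinel) stop("NA/NaN values cannot be quantized")
  if (any(!is.finite(values[!nav]))) stop("non-finite values cannot be quantized")
  b <- floor((values - cfg@minP) / cfg@sp)
  b[values < cfg@minP] <- 0
  b[values > cfg@maxP] <- nb - 1
  b <- pmin(b, nb - 1)          # v == maxP lands in the top bin
  b[nav] <- nb                  # sentinel
  new("BinSequence", symbols = as.integer(b), nBins = nb, hpc = FALSE)
}

#' @describeIn BinSequence-class symbol vector.
#' @param object a `BinSequence`.
#' @export
setGeneric("binSymbols", function(object) standardGeneric("binSymbols"))

#' @rdname BinSequence-class
#' @export
setMethod("binSymbols", "BinSequence", function(object) object@symbols)

#' @rdname BinSequence-class
#' @export
setGeneric("alphabetSize", function(object) standardGeneric("alphabetSize"))

#' @rdname BinSequence-class
#' @export
setMethod("alphabetSize", "BinSequence", function(object) object@nBins)

#' @rdname BinSequence-class
#' @export
setGeneric("isCompressed", function(object) standardGeneric("isCompressed"))

#' @rdname BinSequence-class
#' @export
setMethod("isCompressed", "BinSequence", function(object) object@hpc)

setMethod("show", "BinSequence", function(object) {
  n <- length(object@symbols)
  head <- paste(utils::head(object@symbols, 15L), collapse = " ")
  cat(sprintf("BinSequence: %d symbols over %d bins%s%s\n", n, object@nBins,
              if (object@hpc) " (run-compressed)" else "",
              if (n) paste0(": ", head, if (n > 15L) " ...") else ""))
})
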