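#' Signal simulation parameters
#'
#' The generator emulates a nanopore current trace: each reference k-mer
#' dwells in the pore for a truncated-Gaussian number of samples (floored
#' at 1) and emits Gaussian samples around its pore-model level, with the
#' per-k-mer spread scaled by `amplitudeNoiseFactor`. Optional stay/skip
#' probabilities re-emit or drop k-mers to mimic segmentation-scale motor
#' artifacts. Defaults are the study conditions used throughout the test
#' suite: 10,000 bp mean read length, amplitude noise factor 2.0, dwell
#' time sd 8.0 samples around a 9-sample mean.
#'
#' @slot meanReadLength mean read length in bp.
#' @slot amplitudeNoiseFactor multiplier on per-k-mer level sd.
#' @slot dwellMean,dwellSd dwell time distribution in samples per k-mer.
#' @slot stayProb,skipProb per-k-mer probabilities of re-emission/dropping.
#' @export
setClass("SimParams",
  representation(meanReadLength = "numeric", amplitudeNoiseFactor = "numeric",
                 dwellMean = "numeric", dwellSd = "numeric",
                 stayProb = "numeric", skipProb = "numeric"))

setValidity("SimParams", function(object) {
  if (object@stayProb < 0 || object@stayProb >= 1 ||
      object@skipProb < 0 || object@skipProb >= 1)
    return("stay/skip probabilities must be in [0,1)")
  if (object@dwellMean < 1) return("dwellMean must be >= 1 sample")
  if (object@amplitudeNoiseFactor < 0) return("noise factor must be >= 0")
  TRUE
})

#' @rdname SimParams-class
#' @param meanReadLength,amplitudeNoiseFactor,dwellMean,dwellSd,stayProb,skipProb
#'   see the class slots.
#' @export
simParams <- function(meanReadLength = 10000, amplitudeNoiseFactor = 2.0,
                      dwellMean = 9, dwellSd = 8.0, stayProb = 0,
                      skipProb = 0) {
  new("SimParams", meanReadLength = meanReadLength,
      amplitudeNoiseFactor = amplitudeNoiseFactor, dwellMean = dwellMean,
      dwellSd = dwellSd, stayProb = stayProb, skipProb = skipProb)
}

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: mean read %d bp, noise x%.1f, dwell %.1f+-%.1f, stay %.2f, skip %.2f\n",
    round(object@meanReadLength), object@amplitudeNoiseFactor,
    object@dwellMean, object@dwellSd, object@stayProb, object@skipProb))
})

# level means and sds for each k-mer window of a sequence
.windowLevels <- function(seq, model) {
  mu <- expectedSignal(seq, model)
  k <- model@k
  b <- .baseCodes(seq)
  nw <- length(b) - k + 1L
  idx <- rep(0, nw)
  ok <- rep(TRUE, nw)
  for (j in seq_len(k)) {
    bj <- b[j:(j + nw - 1L)]
    ok <- ok & !is.na(bj)
    bj[is.na(bj)] <- 0L
    idx <- idx * 4 + bj
  }
  sd <- rep(NA_real_, nw)
  sd[ok] <- model@levelSd[idx[ok] + 1L]
  list(mean = mu, sd = sd)
}

#' Simulate raw signal for a reference window
#'
#' Draws the current trace a pore would produce while a read from
#' `[start, start+length)` of `refSeq` translocates. Uses the caller's RNG
#' stream (seed upstream for reproducibility).
#'
#' @param refSeq nucleotide string (or `DNAString`).
#' @param start 0-based window start (bp).
#' @param length window length (bp).
#' @param model a [PoreModel-class].
#' @param params a [SimParams-class].
#' @param strand `"+"` or `"-"` (reverse complement).
#' @return list with `samples` (numeric) and `truth`
#'   (ref/strand/start/end record).
#' @export
simulateRead <- function(refSeq, start, length, model, params = simParams(),
                         strand = "+") {
  seq <- as.character(refSeq)
  if (start < 0 || start + length > nchar(seq))
    stop("read window falls outside the reference sequence")
  win <- substr(seq, start + 1L, start + length)
  if (strand == "-")
    win <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(win)))
  lv <- .windowLevels(win, model)
  n <- length(lv$mean)
  keep <- if (params@skipProb > 0)
    stats::runif(n) >= params@skipProb else rep(TRUE, n)
  reps <- rep(1L, n)
  if (params@stayProb > 0)
    reps <- reps + (stats::runif(n) < params@stayProb)
  reps[!keep] <- 0L
  mu <- rep(lv$mean, reps)
  sd <- rep(lv$sd, reps) * params@amplitudeNoiseFactor
  nk <- length(mu)
  dw <- if (params@dwellSd > 0)
    pmax(1L, as.integer(round(stats::rnorm(nk, params@dwellMean,
                                           params@dwellSd))))
  else rep(as.integer(round(params@dwellMean)), nk)
  tot <- sum(dw)
  samples <- rep(mu, dw)
  if (params@amplitudeNoiseFactor > 0)
    samples <- samples + stats::rnorm(tot) * rep(sd, dw)
  list(samples = samples,
       truth = list(strand = strand, start = start, end = start + length))
}

#' Simulate a labeled dataset of reads
#'
#' Classes are drawn uniformly; within a class, records are drawn with
#' probability proportional to length, start positions and strands
#' uniformly. Read lengths follow Normal(mean, mean/4) truncated at 500 bp
#' and at the record length. Deterministic in `seed`.
#'
#' @param refs named character vector of FASTA paths or named list of
#'   `DNAStringSet`s; names are class labels.
#' @param nReads number of reads.
#' @param model a [PoreModel-class].
#' @param params a [SimParams-class].
#' @param seed RNG seed.
#' @return list with `signals` (named list of sample vectors) and `truth`
#'   (data.frame: read_id, class, ref, start, end, strand).
#' @export
simulateDataset <- function(refs, nReads, model, params = simParams(),
                            seed = 1L) {
  if (nReads <= 0) stop("nReads must be positive")
  if (is.character(refs)) {
    seqsets <- lapply(refs, Biostrings::readDNAStringSet)
    names(seqsets) <- names(refs)
  } else seqsets <- refs
  classes <- names(seqsets)
  old <- .saveSeed()
  on.exit(.restoreSeed(old))
  set.seed(seed)
  signals <- vector("list", nReads)
  truth <- vector("list", nReads)
  for (i in seq_len(nReads)) {
    cls <- classes[1L + (i - 1L) %% length(classes)]  # balanced class mix
    set <- seqsets[[cls]]
    w <- Biostrings::width(set)
    ri <- sample.int(length(set), 1L, prob = w)
    L <- w[ri]
    len <- round(stats::rnorm(1L, params@meanReadLength,
                              params@meanReadLength / 4))
    len <- max(500L, min(as.integer(len), L - model@k))
    st <- sample.int(L - len + 1L, 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    rd <- simulateRead(as.character(set[[ri]]), st, len, model, params,
                       strand)
    id <- sprintf("read_%04d", i)
    signals[[i]] <- rd$samples
    nm <- if (!is.null(names(set))) sub("\\s.*$", "", names(set)[ri]) else
      sprintf("%s_%d", cls, ri)
    truth[[i]] <- data.frame(read_id = id, class = cls, ref = nm,
                             start = st, end = st + len, strand = strand)
  }
  names(signals) <- sprintf("read_%04d", seq_len(nReads))
  list(signals = signals, truth = do.call(rbind, truth))
}

#' Random nucleotide references for simulation studies
#'
#' @param lengths named integer vector: class label -> sequence length (bp).
#' @param seed RNG seed.
#' @return named list of single-record `DNAStringSet`s keyed by class.
#' @export
syntheticReferences <- function(lengths, seed = 7L) {
  old <- .saveSeed()
  on.exit(.restoreSeed(old))
  set.seed(seed)
  out <- lapply(seq_along(lengths), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE),
               collapse = "")
    set <- Biostrings::DNAStringSet(s)
    names(set) <- names(lengths)[i]
    set
  })
  names(out) <- names(lengths)
  out
}
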