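#' Assemble a ReferenceText directly from bin-symbol segments
#'
#' Used to reconstruct a reference from a binned FASTA written with
#' [writeBinnedFasta()], and to build small test references without going
#' through nucleotide space. Each segment becomes one strand-sequence with
#' its own forward shreds.
#'
#' @param segments list of integer vectors over `[0, nBins]`.
#' @param nBins alphabet size.
#' @param classes character vector of class labels, one per segment.
#' @param names optional segment names.
#' @param shredSize shred length in symbols.
#' @param classRoles optional named roles per class.
#' @return A [ReferenceText-class].
#' @export
referenceFromSegments <- function(segments, nBins, classes,
                                  names = NULL, shredSize = 1e5,
                                  classRoles = NULL) {
  if (is.null(names))
    names <- sprintf("seq%d", seq_along(segments))
  segments <- lapply(segments, function(s) compressRuns(as.integer(s)))
  info <- list()
  rows <- list()
  off <- 0L
  docCounter <- 0L
  for (i in seq_along(segments)) {
    L <- length(segments[[i]])
    starts <- seq.int(0L, max(L - 1L, 0L), by = shredSize)
    ends <- pmin(starts + shredSize, L)
    docIds <- docCounter + seq_along(starts)
    info[[i]] <- data.frame(name = names[i], class = classes[i],
                            strand = "+", segStart = off, length = L)
    rows[[i]] <- data.frame(doc_id = docIds, ref_name = names[i],
                            class = classes[i], start = off + starts,
                            end = off + ends, strand = "+")
    off <- off + L + 1L
    docCounter <- docCounter + length(starts)
  }
  cls <- unique(classes)
  cm <- rep("plain", length(cls))
  names(cm) <- cls
  if (!is.null(classRoles)) cm[names(classRoles)] <- classRoles
  new("ReferenceText", segments = segments, seqInfo = do.call(rbind, info),
      shredTable = do.call(rbind, rows), classMap = cm,
      nBins = as.integer(nBins), hpc = TRUE, k = 1L,
      shredSize = as.numeric(shredSize), modelHash = "")
}

# per-segment local document labels, forward orientation
.docLocal <- function(ref) {
  lapply(seq_len(nrow(ref@seqInfo)), function(i) {
    si <- ref@seqInfo[i, ]
    d <- integer(si$length)
    rows <- ref@shredTable[ref@shredTable$start >= si$segStart &
                           ref@shredTable$end <= si$segStart + si$length &
                           ref@shredTable$strand == si$strand &
                           ref@shredTable$ref_name == si$name, , drop = FALSE]
    for (j in seq_len(nrow(rows)))
      d[(rows$start[j] - si$segStart + 1L):(rows$end[j] - si$segStart)] <-
        rows$doc_id[j]
    d
  })
}

#' Build the run-length BWT index over a reference
#'
#' Constructs the suffix array (prefix doubling), BWT, maximal run
#' decomposition, per-symbol rank tables, LCP-derived thresholds, and
#' sampled document labels at the first and last offset of every run.
#' Per-shred sequence complexity (normalized order-0 empirical entropy of
#' the shred's bin symbols) is computed here once.
#'
#' Terminators are encoded as distinct smallest symbols in document order,
#' which makes the suffix order total; externally they present as a single
#' terminator that never matches a query. By default each strand-sequence is
#' reversed before indexing, so queries stream left-to-right in arrival
#' order (see the package vignette for why this direction choice makes
#' chunked classification exact).
#'
#' @param ref a [ReferenceText-class].
#' @param reverseSegments reverse each strand-sequence before indexing
#'   (default `TRUE`; `FALSE` gives a plain forward-text BWT index, useful
#'   for direct BWT inspection).
#' @return A [PMLIndex-class].
#' @export
buildIndex <- function(ref, reverseSegments = TRUE) {
  m <- length(ref@segments)
  nb <- ref@nBins
  maxSym <- m + 1L + nb  # bins 0..nb-1 plus sentinel nb, offset by m+1
  docLoc <- .docLocal(ref)
  xs <- vector("list", 2L * m)
  dx <- vector("list", 2L * m)
  for (i in seq_len(m)) {
    s <- ref@segments[[i]] + m + 1L
    d <- docLoc[[i]]
    if (reverseSegments) { s <- rev(s); d <- rev(d) }
    xs[[2L * i - 1L]] <- s
    xs[[2L * i]] <- i                              # terminator
    dx[[2L * i - 1L]] <- d
    dx[[2L * i]] <- if (length(d)) d[length(d)] else NA_integer_
  }
  X <- unlist(xs, use.names = FALSE)
  docX <- unlist(dx, use.names = FALSE)
  n <- length(X)
  sa <- sa_cpp(X)
  bwt <- bwt_cpp(X, sa)
  runs <- rle_runs_cpp(bwt)
  lcp <- lcp_kasai_cpp(X, sa)
  thr <- thresholds_cpp(lcp, runs$starts, runs$syms, runs$lens, maxSym)
  tab <- tabulate(X, nbins = maxSym)
  Ct <- c(0L, 0L, cumsum(tab))  # Ct[c + 2] in R == #symbols < c + 1 ... (C++ 0-based)
  docRow <- docX[sa + 1L]
  r <- length(runs$starts)
  docFirst <- docRow[runs$starts + 1L]
  docLast <- docRow[runs$starts + runs$lens]
  symStarts <- symLens <- symCum <- symDocF <- symDocL <- vector("list", maxSym)
  for (cc in seq_len(maxSym)) {
    idx <- which(runs$syms == cc)
    symStarts[[cc]] <- runs$starts[idx]
    symLens[[cc]] <- runs$lens[idx]
    cs <- cumsum(runs$lens[idx])
    symCum[[cc]] <- as.integer(c(0L, cs[-length(cs)]))
    symDocF[[cc]] <- docFirst[idx]
    symDocL[[cc]] <- docLast[idx]
  }
  new("PMLIndex",
      runStarts = runs$starts, runSyms = runs$syms, runLens = runs$lens,
      n = as.integer(n), r = as.integer(r), nDocs = as.integer(m),
      Ctab = as.integer(Ct),
      symStarts = symStarts, symLens = symLens, symCum = symCum,
      symDocF = symDocF, symDocL = symDocL, thresholds = thr,
      docFirst = as.integer(docFirst), docLast = as.integer(docLast),
      shredTable = ref@shredTable, classMap = ref@classMap,
      complexity = shredComplexity(ref),
      config = list(nBins = nb, shredSize = ref@shredSize, k = ref@k,
                    modelHash = ref@modelHash,
                    bothStrands = any(ref@seqInfo$strand == "-"),
                    reversed = reverseSegments, hpc = ref@hpc))
}

#' @describeIn PMLIndex-class text length, run count and their ratio.
#' @param object a `PMLIndex`.
#' @export
setGeneric("indexStats", function(object) standardGeneric("indexStats"))

#' @rdname PMLIndex-class
#' @export
setMethod("indexStats", "PMLIndex", function(object)
  list(n = object@n, r = object@r, nOverR = object@n / object@r,
       nDocs = object@nDocs))

#' @rdname ReferenceText-class
#' @export
setMethod("shredTable", "PMLIndex", function(object) object@shredTable)

#' @rdname ReferenceText-class
#' @export
setMethod("classMap", "PMLIndex", function(object) object@classMap)

setMethod("show", "PMLIndex", function(object) {
  cat(sprintf(
    "PMLIndex: n=%d, r=%d (n/r=%.2f), %d strand-sequences, %d shreds\n",
    object@n, object@r, object@n / object@r, object@nDocs,
    length(unique(object@shredTable$doc_id))))
})

#' Reconstruct the indexed text by inverting the BWT
#'
#' Walks the LF mapping from each terminator row, spelling every
#' strand-sequence; the result must equal the indexed text exactly
#' (structural invariant of the index).
#'
#' @param index a [PMLIndex-class].
#' @return list of integer bin-symbol vectors, one per strand-sequence, in
#'   the reference's forward orientation.
#' @export
extractReferenceText <- function(index) {
  m <- index@nDocs
  segs <- extract_docs_cpp(index@runStarts, index@runSyms, index@runLens,
                           index@Ctab, index@symStarts, index@symLens,
                           index@symCum, m, index@n)
  segs <- lapply(segs, function(s) s - (m + 1L))
  if (isTRUE(index@config$reversed)) segs <- lapply(segs, rev)
  segs
}

#' LF mapping of every BWT offset (structural test support)
#' @param index a [PMLIndex-class].
#' @return 0-based integer vector of length n; a permutation of 0..n-1.
#' @export
lfMap <- function(index) {
  lf_all_cpp(index@runStarts, index@runSyms, index@runLens, index@Ctab,
             index@symStarts, index@symLens, index@symCum, index@n)
}

#' Persist / load an index directory
#'
#' The persisted form keeps only run-length structures plus samples: the
#' run table (start, symbol, length, boundary document labels), the
#' thresholds, the shred table, per-shred complexity, and the build config.
#' Rank tables are rebuilt on load.
#'
#' @param index a [PMLIndex-class].
#' @param dir directory path.
#' @export
writeIndex <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(start = index@runStarts, sym = index@runSyms,
               len = index@runLens, docFirst = index@docFirst,
               docLast = index@docLast),
    file.path(dir, "bwt_runs.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(index@shredTable, file.path(dir, "shreds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n = index@n, r = index@r, nDocs = index@nDocs,
         classMap = as.list(index@classMap),
         complexity = as.list(index@complexity),
         thresholds = index@thresholds,
         config = index@config),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeIndex
#' @export
readIndex <- function(dir) {
  runs <- utils::read.delim(file.path(dir, "bwt_runs.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  shreds <- utils::read.delim(file.path(dir, "shreds.tsv"))
  m <- as.integer(meta$nDocs)
  nb <- as.integer(meta$config$nBins)
  maxSym <- m + 1L + nb
  n <- as.integer(meta$n)
  tab <- integer(maxSym)
  agg <- tapply(runs$len, runs$sym, sum)
  tab[as.integer(names(agg))] <- as.integer(agg)
  Ct <- c(0L, 0L, cumsum(tab))
  symStarts <- symLens <- symCum <- symDocF <- symDocL <- vector("list", maxSym)
  for (cc in seq_len(maxSym)) {
    idx <- which(runs$sym == cc)
    symStarts[[cc]] <- as.integer(runs$start[idx])
    symLens[[cc]] <- as.integer(runs$len[idx])
    cs <- cumsum(runs$len[idx])
    symCum[[cc]] <- as.integer(c(0L, cs[-length(cs)]))
    symDocF[[cc]] <- as.integer(runs$docFirst[idx])
    symDocL[[cc]] <- as.integer(runs$docLast[idx])
  }
  thr <- lapply(meta$thresholds, as.integer)
  cm <- unlist(meta$classMap)
  cx <- unlist(meta$complexity)
  new("PMLIndex",
      runStarts = as.integer(runs$start), runSyms = as.integer(runs$sym),
      runLens = as.integer(runs$len), n = n, r = as.integer(meta$r),
      nDocs = m, Ctab = as.integer(Ct),
      symStarts = symStarts, symLens = symLens, symCum = symCum,
      symDocF = symDocF, symDocL = symDocL, thresholds = thr,
      docFirst = as.integer(runs$docFirst),
      docLast = as.integer(runs$docLast),
      shredTable = shreds, classMap = cm, complexity = cx,
      config = as.list(meta$config))
}

#' Brute-force matching statistics (half-MEM) oracle
#'
#' `MS[i]` is the length of the longest prefix of `query[i..]` occurring
#' anywhere in `text`, found by exhaustive scan. This is the independent
#' reference against which pseudo-matching lengths are checked (PMLs are
#' truncated matching statistics, so `0 <= PML[i] <= MS[i]`).
#'
#' @param text,query integer symbol vectors.
#' @return integer MS vector, same length as `query`.
#' @export
matchingStatisticsOracle <- function(text, query) {
  text <- as.integer(text)
  query <- as.integer(query)
  nq <- length(query)
  nt <- length(text)
  ms <- integer(nq)
  for (i in seq_len(nq)) {
    alive <- which(text == query[i])
    k <- 0L
    while (length(alive)) {
      k <- k + 1L
      if (i + k > nq) break
      alive <- alive[alive + k <= nt]
      alive <- alive[text[alive + k] == query[i + k]]
    }
    ms[i] <- k
  }
  ms
}
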