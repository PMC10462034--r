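#' Build the binned, shredded, class-labeled reference text
#'
#' Each FASTA record is converted to expected current with the pore model,
#' quantized into the bin alphabet, and run-compressed; by default the
#' reverse complement is rendered as well, because nanopore reads sample
#' either strand and signal space has no reverse-complement symmetry. Every
#' strand-sequence is followed by one terminator, so exact matches may span
#' shred boundaries but never sequence boundaries. Positions are partitioned
#' into equal-length shreds (default 100,000 symbols) carrying document ids
#' and class labels; reverse-strand intervals share the document ids of the
#' mirrored forward shreds so votes aggregate per locus.
#'
#' @param fastas named character vector of FASTA paths, or named list of
#'   [Biostrings::DNAStringSet] objects; names are class labels. A class may
#'   appear several times.
#' @param model a [PoreModel-class].
#' @param cfg a [BinningConfig-class].
#' @param shredSize shred length in (post-compression) symbols.
#' @param bothStrands index the reverse complement too (default `TRUE`).
#' @param classRoles optional named character assigning each class label a
#'   role: `"positive"`, `"null"` or `"plain"` (default).
#' @return A [ReferenceText-class].
#' @export
buildReference <- function(fastas, model, cfg, shredSize = 1e5,
                           bothStrands = TRUE, classRoles = NULL) {
  if (is.character(fastas)) {
    seqsets <- lapply(fastas, Biostrings::readDNAStringSet)
    names(seqsets) <- names(fastas)
  } else seqsets <- fastas
  if (is.null(names(seqsets)) || any(!nzchar(names(seqsets))))
    stop("every FASTA input needs a class label")
  k <- model@k
  segments <- list()
  info <- list()
  rows <- list()
  docCounter <- 0L
  off <- 0L
  for (ci in seq_along(seqsets)) {
    cls <- names(seqsets)[ci]
    set <- seqsets[[ci]]
    if (length(set) == 0L) stop(sprintf("empty FASTA for class '%s'", cls))
    for (ri in seq_along(set)) {
      nm <- if (!is.null(names(set))) names(set)[ri] else
        sprintf("%s_%d", cls, ri)
      nm <- sub("\\s.*$", "", nm)
      if (Biostrings::width(set)[ri] < k) {
        warning(sprintf("record '%s' shorter than k=%d; skipped", nm, k))
        next
      }
      fwd <- .binSeqOf(as.character(set[[ri]]), model, cfg)
      Lf <- length(fwd)
      if (Lf == 0L) next
      starts <- seq.int(0L, Lf - 1L, by = shredSize)
      ends <- pmin(starts + shredSize, Lf)
      docIds <- docCounter + seq_along(starts)
      segments[[length(segments) + 1L]] <- fwd
      info[[length(info) + 1L]] <- data.frame(
        name = nm, class = cls, strand = "+", segStart = off, length = Lf)
      rows[[length(rows) + 1L]] <- data.frame(
        doc_id = docIds, ref_name = nm, class = cls,
        start = off + starts, end = off + ends, strand = "+")
      off <- off + Lf + 1L  # + terminator
      if (bothStrands) {
        rcseq <- as.character(Biostrings::reverseComplement(set[[ri]]))
        rev <- .binSeqOf(rcseq, model, cfg)
        Lr <- length(rev)
        if (Lr > 0L) {
          segments[[length(segments) + 1L]] <- rev
          info[[length(info) + 1L]] <- data.frame(
            name = nm, class = cls, strand = "-", segStart = off, length = Lr)
          # proportional mirror of the forward shred boundaries
          sb <- c(starts, Lf)
          tb <- round(sb * Lr / Lf)
          tb <- cummax(tb)
          m <- length(starts)
          for (j in rev(seq_len(m))) {
            a <- Lr - tb[j + 1L]
            b <- Lr - tb[j]
            if (b > a)
              rows[[length(rows) + 1L]] <- data.frame(
                doc_id = docIds[j], ref_name = nm, class = cls,
                start = off + a, end = off + b, strand = "-")
          }
          off <- off + Lr + 1L
        }
      }
      docCounter <- docCounter + length(starts)
    }
  }
  if (!length(segments)) stop("no usable records in the reference input")
  classes <- unique(names(seqsets))
  cm <- rep("plain", length(classes))
  names(cm) <- classes
  if (!is.null(classRoles)) cm[names(classRoles)] <- classRoles
  new("ReferenceText",
      segments = segments, seqInfo = do.call(rbind, info),
      shredTable = do.call(rbind, rows), classMap = cm,
      nBins = cfg@nBins, hpc = TRUE, k = as.integer(k),
      shredSize = as.numeric(shredSize), modelHash = .modelHash(model))
}

# nucleotide string -> run-compressed bin symbols (sentinel for N windows)
.binSeqOf <- function(seq, model, cfg) {
  pa <- expectedSignal(seq, model)
  compressRuns(quantizeSignal(pa, cfg, naAsSentinel = TRUE))@symbols
}

#' @describeIn ReferenceText-class the shred table.
#' @param object a `ReferenceText` or `PMLIndex`.
#' @export
setGeneric("shredTable", function(object) standardGeneric("shredTable"))

#' @rdname ReferenceText-class
#' @export
setMethod("shredTable", "ReferenceText", function(object) object@shredTable)

#' @rdname ReferenceText-class
#' @export
setGeneric("classMap", function(object) standardGeneric("classMap"))

#' @rdname ReferenceText-class
#' @export
setMethod("classMap", "ReferenceText", function(object) object@classMap)

#' @rdname ReferenceText-class
#' @export
setGeneric("refSegments", function(object) standardGeneric("refSegments"))

#' @rdname ReferenceText-class
#' @export
setMethod("refSegments", "ReferenceText", function(object) {
  s <- object@segments
  names(s) <- paste0(object@seqInfo$name, "/", object@seqInfo$strand)
  s
})

setMethod("show", "ReferenceText", function(object) {
  cat(sprintf(
    "ReferenceText: %d strand-sequences, %d symbols (+%d terminators), %d shreds, %d classes\n",
    length(object@segments), sum(object@seqInfo$length),
    length(object@segments), length(unique(object@shredTable$doc_id)),
    length(object@classMap)))
})

#' Write / read the binned reference as printable-ASCII FASTA
#'
#' Symbol s is encoded as the printable character `chr(33 + s)` (`!` for
#' bin 0); one FASTA record per strand-sequence (record boundaries encode
#' the terminators, which are never written as sequence characters). The
#' pair round-trips losslessly.
#'
#' @param ref a [ReferenceText-class].
#' @param path output path.
#' @export
writeBinnedFasta <- function(ref, path) {
  chars <- vapply(ref@segments, function(s)
    intToUtf8(33L + s), "")
  names(chars) <- sprintf("%s|%s|%s", ref@seqInfo$name, ref@seqInfo$strand,
                          ref@seqInfo$class)
  set <- Biostrings::BStringSet(chars)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' @rdname writeBinnedFasta
#' @param nBins alphabet size used when the file was written.
#' @return `readBinnedFasta`: list with `segments` (integer vectors) and
#'   `info` (name/strand/class data.frame).
#' @export
readBinnedFasta <- function(path, nBins = 6L) {
  set <- Biostrings::readBStringSet(path)
  segs <- lapply(seq_along(set), function(i)
    utf8ToInt(as.character(set[[i]])) - 33L)
  meta <- strsplit(names(set), "|", fixed = TRUE)
  info <- data.frame(name = vapply(meta, `[[`, "", 1L),
                     strand = vapply(meta, `[[`, "", 2L),
                     class = vapply(meta, `[[`, "", 3L))
  if (any(unlist(segs) < 0L | unlist(segs) > nBins))
    stop("binned FASTA contains symbols outside the declared alphabet")
  list(segments = segs, info = info)
}

#' Shred table persistence (TSV)
#' @param ref a [ReferenceText-class] or [PMLIndex-class].
#' @param path output path.
#' @export
writeShredTable <- function(ref, path) {
  utils::write.table(shredTable(ref), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
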