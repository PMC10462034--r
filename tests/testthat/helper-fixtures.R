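# Shared fixtures, all generated in code.

# evenly spaced toy 2-mer model: AA=60, ..., TT=120, sd 2
toyModel <- function() {
  km <- sort(do.call(paste0, expand.grid(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"),
                                         stringsAsFactors = FALSE)))
  lm <- seq(60, 120, length.out = 16)
  names(lm) <- km
  ls <- rep(2, 16)
  names(ls) <- km
  PoreModel(lm, ls)
}

# deterministic random bin segments
randomSegments <- function(nseg, lenRange = c(50, 200), sigma = 6,
                           seed = 1) {
  withr::with_seed(seed, lapply(seq_len(nseg), function(i)
    sample.int(sigma, sample(lenRange[1]:lenRange[2], 1),
               replace = TRUE) - 1L))
}

# an index over given symbol segments
segIndex <- function(segments, classes = NULL, nBins = 6L,
                     shredSize = 1e5, reverse = TRUE, ...) {
  if (is.null(classes)) classes <- sprintf("c%d", seq_along(segments))
  ref <- referenceFromSegments(segments, nBins, classes,
                               shredSize = shredSize, ...)
  list(ref = ref, idx = buildIndex(ref, reverseSegments = reverse))
}

# concatenated text for the brute-force MS oracle (terminators as -1,
# which never matches a bin symbol)
oracleText <- function(ref) {
  unlist(lapply(ref@segments, function(s) c(s, -1L)), use.names = FALSE)
}

# small nucleotide references for end-to-end tests
smallRefs <- function(lens = c(A = 6000, B = 6000), seed = 11) {
  syntheticReferences(lens, seed = seed)
}
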