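# decode a forward-text BWT from the stored runs, for direct inspection
bwtString <- function(idx, alphabet) {
  syms <- rep(idx@runSyms, idx@runLens)
  m <- idx@nDocs
  paste(ifelse(syms <= m, "$", alphabet[syms - m]), collapse = "")
}

test_that("the classic text yields the known BWT and run count", {
  # "banana" over a=0, b=1, n=2 with one terminator
  built <- segIndex(list(c(1L, 0L, 2L, 0L, 2L, 0L)), nBins = 3,
                    reverse = FALSE)
  idx <- built$idx
  expect_identical(bwtString(idx, c("a", "b", "n")), "annb$aa")
  expect_identical(idx@r, 5L)
  expect_identical(idx@n, 7L)
})

test_that("BWT inversion reconstructs every indexed text exactly", {
  for (seed in 1:5) {
    segs <- randomSegments(sample(1:3, 1), c(30, 150), seed = seed)
    for (rev in c(TRUE, FALSE)) {
      built <- segIndex(segs, reverse = rev)
      expect_identical(lapply(extractReferenceText(built$idx), as.integer),
                       unname(lapply(built$ref@segments, as.integer)))
    }
  }
})

test_that("LF is a bijection and runs tile the text on every index", {
  for (seed in 6:8) {
    built <- segIndex(randomSegments(2, c(40, 120), seed = seed))
    idx <- built$idx
    lf <- lfMap(idx)
    expect_identical(sort(lf), 0:(idx@n - 1L))
    expect_lte(idx@r, idx@n)
    expect_identical(sum(idx@runLens), idx@n)
  }
})

test_that("repeated copies grow the run count sublinearly", {
  seg <- randomSegments(1, c(2000, 2000), seed = 9)[[1]]
  one <- segIndex(list(seg), classes = "c")
  eight <- segIndex(rep(list(seg), 8), classes = rep("c", 8))
  expect_lte(eight$idx@r, 1.25 * one$idx@r)
  expect_gt(eight$idx@n / eight$idx@r, one$idx@n / one$idx@r)
})

test_that("the brute-force MS oracle matches hand-computed cases", {
  expect_identical(matchingStatisticsOracle(c(0, 1, 0, 1), c(0, 1, 0, 1)),
                   c(4L, 3L, 2L, 1L))
  expect_identical(matchingStatisticsOracle(c(0, 1), c(2, 0)), c(0L, 1L))
  set.seed(10)
  for (i in 1:10) {
    ms <- matchingStatisticsOracle(sample(0:3, 60, TRUE), sample(0:3, 30, TRUE))
    expect_true(all(ms[-1] >= ms[-length(ms)] - 1L))  # suffix-overlap decay
  }
})

test_that("exact substrings give the full decreasing ramp with in-shred documents", {
  built <- segIndex(randomSegments(2, c(150, 200), seed = 11), shredSize = 60)
  ref <- built$ref
  set.seed(12)
  for (i in 1:10) {
    k <- sample(seq_along(ref@segments), 1)
    seg <- ref@segments[[k]]
    st <- sample(length(seg) - 25, 1)
    q <- seg[st:(st + 24)]
    prof <- computePML(built$idx, q)
    expect_identical(pml(prof), as.integer(25:1))
    # every attributed document overlaps a true occurrence of the query
    txt <- oracleText(ref)
    occ <- which(vapply(seq_len(length(txt) - 24), function(p)
      all(txt[p:(p + 24)] == q), logical(1)))
    docs <- unique(docLabels(prof))
    stab <- shredTable(ref)
    for (d in docs) {
      iv <- stab[stab$doc_id == d, ]
      expect_true(any(vapply(seq_len(nrow(iv)), function(r)
        any(occ - 1 < iv$end[r] & occ - 1 + 25 > iv$start[r]), logical(1))))
    }
  }
})

test_that("queries over absent symbols give all-zero PMLs and NA documents", {
  built <- segIndex(list(c(0L, 1L, 0L, 2L, 1L)), nBins = 6)
  prof <- computePML(built$idx, c(4L, 5L, 4L))
  expect_identical(pml(prof), c(0L, 0L, 0L))
  expect_true(all(is.na(docLabels(prof))))
})

test_that("PMLs never exceed brute-force matching statistics", {
  set.seed(13)
  for (i in 1:150) {
    sigma <- sample(2:6, 1)
    segs <- list(sample.int(sigma, sample(30:200, 1), TRUE) - 1L)
    built <- segIndex(segs, nBins = 6)
    q <- sample.int(sigma + 1, sample(5:50, 1), TRUE) - 1L  # may include absent
    P <- pml(computePML(built$idx, q))
    ms <- matchingStatisticsOracle(oracleText(built$ref), q)
    expect_true(all(P >= 0L & P <= ms))
    expect_true(all(P[-1] >= P[-length(P)] - 1L))
  }
})

test_that("streamed PML fragments concatenate to the batch profile", {
  built <- segIndex(randomSegments(2, c(100, 180), seed = 14))
  idx <- built$idx
  seg <- built$ref@segments[[1]]
  set.seed(15)
  for (i in 1:10) {
    q <- c(seg[10:60], sample(0:5, 30, TRUE))
    batch <- computePML(idx, q, "rd")
    # any 2-way split
    cut <- sample(0:length(q), 1)
    st <- pmlState(idx, "rd")
    a <- resumePML(idx, q[seq_len(cut)], st)
    b <- resumePML(idx, q[setdiff(seq_along(q), seq_len(cut))], a$state)
    tail <- finalizePML(idx, b$state)
    expect_identical(c(a$fragment@P, b$fragment@P, tail@P), pml(batch))
    expect_identical(c(a$fragment@D, b$fragment@D, tail@D), docLabels(batch))
    # 3-way split agrees too
    cuts <- sort(sample(0:length(q), 2))
    st <- pmlState(idx, "rd")
    parts <- list(q[seq_len(cuts[1])],
                  q[seq_len(cuts[2])[-seq_len(cuts[1])]],
                  q[-seq_len(cuts[2])])
    P3 <- integer(0); D3 <- integer(0)
    for (p in parts) {
      r <- resumePML(idx, p, st)
      st <- r$state
      P3 <- c(P3, r$fragment@P); D3 <- c(D3, r$fragment@D)
    }
    tail <- finalizePML(idx, st)
    expect_identical(c(P3, tail@P), pml(batch))
    expect_identical(c(D3, tail@D), docLabels(batch))
  }

  # empty chunk: empty fragment, state unchanged
  st <- pmlState(idx, "rd")
  r1 <- resumePML(idx, seg[1:10], st)
  r2 <- resumePML(idx, integer(0), r1$state)
  expect_length(r2$fragment@P, 0L)
  expect_identical(r2$state, r1$state)

  # resuming under a different read id errors
  expect_error(resumePML(idx, 1L, r1$state, readId = "other"),
               "belongs to read")
})

test_that("indexes persist to a directory and load back equivalently", {
  built <- segIndex(randomSegments(2, c(80, 140), seed = 16), shredSize = 70)
  d <- tempfile()
  writeIndex(built$idx, d)
  expect_true(all(file.exists(file.path(d, c("bwt_runs.tsv", "shreds.tsv",
                                             "config.json")))))
  back <- readIndex(d)
  expect_identical(back@r, built$idx@r)
  expect_identical(back@runSyms, built$idx@runSyms)
  expect_equal(back@complexity, built$idx@complexity)
  set.seed(17)
  q <- sample(0:5, 60, TRUE)
  expect_identical(pml(computePML(back, q)), pml(computePML(built$idx, q)))
  expect_identical(docLabels(computePML(back, q)),
                   docLabels(computePML(built$idx, q)))
})
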