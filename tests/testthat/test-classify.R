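test_that("peak indicator marks match starts", {
  expect_identical(which(peakIndicator(c(3, 2, 1, 2, 1, 0))), c(1L, 4L))
  expect_identical(which(peakIndicator(c(5, 4, 3, 2))), 1L)   # one match
  expect_true(all(peakIndicator(rep(2, 5))))                  # ties count
  expect_length(peakIndicator(integer(0)), 0L)
})

test_that("shred complexity is normalized order-0 entropy", {
  # one repeated symbol alternating with nothing else is impossible after
  # run compression, so probe entropy through multi-symbol shreds
  ref1 <- referenceFromSegments(list(rep(c(0L, 1L), 12)), 6, "c")
  expect_equal(unname(shredComplexity(ref1)), log2(2) / log2(6))
  ref2 <- referenceFromSegments(list(rep(c(0L, 1L, 2L, 3L, 4L, 5L), 6)), 6, "c")
  expect_equal(unname(shredComplexity(ref2)), 1)
  ref3 <- referenceFromSegments(list(rep(c(0L, 1L, 2L), 8)), 6, "c")
  expect_equal(unname(shredComplexity(ref3)), log2(3) / log2(6))
})

test_that("document scores implement the complexity-weighted peak vote", {
  st <- data.frame(doc_id = 1:2, ref_name = c("r1", "r2"),
                   class = c("A", "B"), start = c(0, 101), end = c(100, 201),
                   strand = "+")
  prof <- new("MatchProfile", P = c(3L, 2L, 1L, 2L, 1L, 0L),
              D = c(1L, 1L, 1L, 2L, 2L, NA), readId = "r")
  sc <- documentScores(prof, NULL, st)
  expect_equal(sc, c(`1` = 3, `2` = 2))

  # all-zero profile scores nothing
  z <- new("MatchProfile", P = rep(0L, 4), D = rep(NA_integer_, 4),
           readId = "r")
  expect_length(documentScores(z, NULL, st), 0L)

  # complexity scales linearly, per document
  sc2 <- documentScores(prof, c(`1` = 1, `2` = 0.5), st)
  expect_equal(sc2, c(`1` = 3, `2` = 1))

  # unknown documents are an error
  bad <- new("MatchProfile", P = c(2L, 1L), D = c(9L, 9L), readId = "r")
  expect_error(documentScores(bad, NULL, st), "absent from the shred table")
})

test_that("multiclass calls take the argmax class with deterministic ties", {
  st <- data.frame(doc_id = 1:4, ref_name = c("a", "a", "b", "c"),
                   class = c("A", "A", "B", "C"),
                   start = 0:3 * 10, end = 0:3 * 10 + 10, strand = "+")
  out <- classifyMulticlass(c(`1` = 3, `3` = 2), st, "r")
  expect_identical(out$predicted_class, "A")
  expect_identical(out$top_doc, 1L)
  expect_equal(out$score, 3)

  # zero scores abstain
  expect_identical(classifyMulticlass(setNames(numeric(0), character(0)),
                                      st)$predicted_class, "unclassified")

  # two docs of the same class tied: that class wins regardless of doc
  out2 <- classifyMulticlass(c(`1` = 2, `2` = 2), st)
  expect_identical(out2$predicted_class, "A")

  # cross-class tie: lexicographically smallest ref name
  out3 <- classifyMulticlass(c(`3` = 2, `2` = 2), st)
  expect_identical(out3$predicted_class, "A")
})

test_that("binary calls follow the spike-ratio rule incl. degenerate cases", {
  st <- data.frame(doc_id = 1:2, ref_name = c("p", "n"),
                   class = c("pos", "neg"), start = c(0, 10),
                   end = c(10, 20), strand = "+")
  cm <- c(pos = "positive", neg = "null")
  call <- function(s1, s2, tau) classifyBinary(c(`1` = s1, `2` = s2), cm, st, tau)

  out <- call(6, 4, 1.2)
  expect_identical(out$predicted_class, "pos")
  expect_equal(out$ratio, 1.5)

  # boundary: ratio exactly tau is not positive (strict inequality)
  out <- call(4, 4, 1.0)
  expect_identical(out$predicted_class, "neg")
  expect_equal(out$ratio, 1.0)

  # zero null score with positive evidence: ratio +Inf, positive
  out <- classifyBinary(c(`1` = 3), cm, st, 1.0)
  expect_identical(out$predicted_class, "pos")
  expect_identical(out$ratio, Inf)

  # no evidence at all: abstain (the only abstention case)
  out <- classifyBinary(setNames(numeric(0), character(0)), cm, st, 1.0)
  expect_identical(out$predicted_class, "unclassified")

  expect_error(classifyBinary(c(`1` = 1), c(pos = "positive"), st, 1.0),
               "positive- and a null-role")
  expect_error(call(1, 1, 0), "tau")
})

test_that("burn-in calibration hits the requested quantile", {
  expect_equal(calibrateThreshold(c(0.5, 1, 2, 4), 0.25), 2.5)
  expect_equal(calibrateThreshold(rep(1.3, 10), 0.5), 1.3)
  expect_equal(calibrateThreshold(c(0.5, 1, 2, 4), 0.999), 0.5,
               tolerance = 0.02)  # fraction -> 1 drives tau to the minimum
  expect_error(calibrateThreshold(numeric(0), 0.5), "empty")
  expect_error(calibrateThreshold(c(Inf, Inf), 0.5), "finite")
  expect_error(calibrateThreshold(c(1, 2), 1.5), "in \\(0,1\\)")

  # calibration on the burn-in set reproduces the expected call rate
  set.seed(41)
  ratios <- rlnorm(500, 0, 0.8)
  for (f in c(0.1, 0.3, 0.5, 0.8)) {
    tau <- calibrateThreshold(ratios, f)
    expect_lt(abs(mean(ratios > tau) - f), 0.05)
  }
})

test_that("raising tau never increases the number of positive calls", {
  st <- data.frame(doc_id = 1:2, ref_name = c("p", "n"),
                   class = c("pos", "neg"), start = c(0, 10),
                   end = c(10, 20), strand = "+")
  cm <- c(pos = "positive", neg = "null")
  set.seed(42)
  scoreSets <- lapply(1:40, function(i)
    c(`1` = rexp(1, 1 / 10), `2` = rexp(1, 1 / 10)))
  nPos <- vapply(c(0.5, 0.8, 1, 1.3, 2, 4), function(tau)
    sum(vapply(scoreSets, function(s)
      classifyBinary(s, cm, st, tau)$predicted_class == "pos", logical(1))),
    integer(1))
  expect_true(all(diff(nPos) <= 0L))
})

test_that("relabeling classes permutes calls identically", {
  segs <- randomSegments(2, c(120, 160), seed = 43)
  b1 <- segIndex(segs, classes = c("X", "Y"))
  b2 <- segIndex(segs, classes = c("Y", "X"))
  set.seed(44)
  for (i in 1:5) {
    q <- c(b1$ref@segments[[sample(1:2, 1)]][1:40], sample(0:5, 10, TRUE))
    c1 <- classifyMulticlass(documentScores(computePML(b1$idx, q), NULL,
                                            shredTable(b1$ref)),
                             shredTable(b1$ref))
    c2 <- classifyMulticlass(documentScores(computePML(b2$idx, q), NULL,
                                            shredTable(b2$ref)),
                             shredTable(b2$ref))
    swap <- c(X = "Y", Y = "X")
    expect_identical(unname(swap[c1$predicted_class]), c2$predicted_class)
  }
})

test_that("streamed classification converges to the batch decision", {
  m <- toyModel()
  cfg <- makeBins(m, 6)
  refs <- smallRefs(c(A = 4000, B = 4000), seed = 45)
  ref <- buildReference(refs, m, cfg)
  idx <- buildIndex(ref)
  set.seed(46)
  ds <- simulateDataset(refs, 4, m, simParams(meanReadLength = 1500), seed = 46)
  for (id in names(ds$signals)) {
    sig <- ds$signals[[id]]
    batch <- classifyRead(sig, idx, m, cfg, readId = id)
    # single chunk: trivially equal
    one <- classifyStream(list(sig), idx, m, cfg, readId = id)
    expect_identical(one$predicted_class[nrow(one)], batch$predicted_class)
    # random split points
    cuts <- sort(sample(seq_len(length(sig) - 1), 3))
    chunks <- split(sig, findInterval(seq_along(sig) - 1, cuts))
    st <- classifyStream(chunks, idx, m, cfg, readId = id)
    expect_identical(st$predicted_class[nrow(st)], batch$predicted_class)
    expect_equal(st$score[nrow(st)], batch$score)
    expect_identical(st$n_chunks[nrow(st)], length(chunks))
  }
})

test_that("true-class score grows along chunks of a noise-free read", {
  m <- toyModel()
  cfg <- makeBins(m, 6)
  refs <- smallRefs(c(A = 5000, B = 5000), seed = 47)
  ref <- buildReference(refs, m, cfg)
  idx <- buildIndex(ref)
  set.seed(48)
  rd <- simulateRead(as.character(refs$A[[1]]), 200, 3000, m,
                     simParams(amplitudeNoiseFactor = 0, dwellSd = 0), "+")
  chunks <- split(rd$samples, (seq_along(rd$samples) - 1) %/% 4000)
  st <- classifyStream(chunks, idx, m, cfg, normalize = FALSE)
  expect_true(all(st$predicted_class == "A"))
  expect_true(all(diff(st$score) >= 0))
})
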