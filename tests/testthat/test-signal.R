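test_that("event detection finds level changes and tiles the input", {
  # no change point: a single event with exact summary stats
  ev <- detectEvents(rep(95.5, 100))
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$ec, 95.5)
  expect_identical(ev$et, 100L)

  # clean step: boundary within +-2 samples of the true change
  ev <- detectEvents(c(rep(80, 50), rep(110, 50)))
  expect_identical(nrow(ev), 2L)
  expect_lte(abs(ev$start[2] - 50L), 2L)
  expect_equal(ev$ec, c(80, 110), tolerance = 1e-6)
  expect_identical(sum(ev$et), 100L)

  # events always tile the input
  set.seed(8)
  raw <- rep(runif(40, 60, 120), each = 9) + rnorm(360)
  ev <- detectEvents(raw)
  expect_identical(ev$start, c(0L, cumsum(ev$et)[-nrow(ev)]))
  expect_identical(sum(ev$et), length(raw))

  expect_warning(out <- detectEvents(c(1, 2, 3)), "shorter")
  expect_identical(nrow(out), 0L)
})

test_that("chunked event detection equals batch detection", {
  set.seed(9)
  raw <- rep(runif(60, 60, 120), each = 8) + rnorm(480, sd = 2)
  st <- eventStream()
  for (cut in split(raw, (seq_along(raw) - 1) %/% 100))
    st <- feedSignal(st, cut)
  expect_identical(streamEvents(st), detectEvents(raw))
})

test_that("Welford streaming moments equal the two-pass oracle", {
  set.seed(10)
  for (n in c(2, 17, 400)) {
    x <- rnorm(n, 90, 12)
    w <- welfordMoments(x)
    expect_equal(w$mean, mean(x))
    expect_equal(w$sd, sqrt(mean((x - mean(x))^2)))
  }
})

test_that("normalization matches event moments to the model moments", {
  m <- toyModel()
  lv <- unname(levelMeans(m))
  ev <- data.frame(start = seq_along(lv) - 1L, et = 1L, ec = lv)

  # already on the model scale: unchanged within float tolerance
  expect_equal(normalizeEvents(ev, m)$ec, lv, tolerance = 1e-12)

  # affine distortion is removed exactly (method of moments)
  ev2 <- ev
  ev2$ec <- lv * 2 + 30
  norm <- normalizeEvents(ev2, m)
  expect_equal(norm$ec, lv, tolerance = 1e-9)
  expect_identical(norm$et, ev2$et)  # dwell untouched

  expect_error(normalizeEvents(ev[1, , drop = FALSE], m), "at least 2")
  ev3 <- ev
  ev3$ec <- rep(80, nrow(ev3))
  expect_error(normalizeEvents(ev3, m), "zero variance")
})

test_that("run compression collapses adjacent equal symbols and is idempotent", {
  expect_identical(compressRuns(c(2L, 2L, 3L, 3L, 3L, 2L)), c(2L, 3L, 2L))
  expect_identical(compressRuns(integer(0)), integer(0))
  set.seed(11)
  for (i in 1:20) {
    x <- sample(0:5, 50, replace = TRUE)
    once <- compressRuns(x)
    expect_identical(compressRuns(once), once)
    expect_false(any(diff(once) == 0L))
  }
  bs <- compressRuns(quantizeSignal(c(61, 61, 75, 75, 75, 61), makeBins(toyModel(), 6)))
  expect_true(isCompressed(bs))
})

test_that("zero-noise simulated signal closes the loop with reference binning", {
  m <- toyModel()
  cfg <- makeBins(m, 6)
  refs <- smallRefs(c(A = 4000), seed = 21)
  A <- as.character(refs$A[[1]])
  set.seed(22)
  rd <- simulateRead(A, 500, 1500, m,
                     simParams(amplitudeNoiseFactor = 0, dwellSd = 0), "+")
  got <- signalToBinSeq(rd$samples, m, cfg, normalize = FALSE)
  want <- compressRuns(quantizeSignal(
    expectedSignal(substr(A, 501, 2000), m), cfg))
  expect_identical(binSymbols(got), binSymbols(want))

  # constant signal collapses to one symbol; symbols always in range
  one <- signalToBinSeq(rep(90, 200), m, cfg, normalize = FALSE)
  expect_identical(length(binSymbols(one)), 1L)
  expect_true(all(binSymbols(got) >= 0L & binSymbols(got) <= 5L))

  # pipeline determinism
  again <- signalToBinSeq(rd$samples, m, cfg, normalize = FALSE)
  expect_identical(binSymbols(got), binSymbols(again))
})

test_that("duplicating a same-bin event leaves the compressed query unchanged", {
  # the stated purpose of run compression: stay errors vanish
  m <- toyModel()
  cfg <- makeBins(m, 6)
  set.seed(23)
  lv <- sample(unname(levelMeans(m)), 30, replace = TRUE)
  raw <- rep(lv, each = 9)
  base <- binSymbols(signalToBinSeq(raw, m, cfg, normalize = FALSE))
  for (dup in c(5, 12, 25)) {
    lv2 <- append(lv, lv[dup], after = dup)  # stay: one level twice
    raw2 <- rep(lv2, each = 9)
    expect_identical(
      binSymbols(signalToBinSeq(raw2, m, cfg, normalize = FALSE)), base)
  }
})

test_that("signal fixture format round-trips", {
  sig <- list(r1 = c(80.25, 91.5, 100), r2 = rep(75.1, 5))
  f <- tempfile()
  writeSignalFixture(sig, f)
  back <- readSignalFixture(f)
  expect_identical(names(back), c("r1", "r2"))
  expect_equal(back$r1, sig$r1, tolerance = 1e-4)
})
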