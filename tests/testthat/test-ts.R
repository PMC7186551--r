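# A small scene with one expressing cell carrying a known transcription site,
# rendered and detected end to end.
tsScene <- function(seed, nascent = 4L, tsFactor = 1.5) {
  p <- scenarioParams(nCells = 1, fieldShape = c(41L, 96L, 96L), seed = seed,
                      phaseFractions = c(G1 = 1, S = 0, G2 = 0, M = 0),
                      expressingFractionG1 = 1, tsFraction = 1,
                      matureMean = 5)
  sc <- sampleScene(p)
  cc <- sceneCells(sc)[[1]]
  set.seed(seed + 1)
  cc$ts$nascent_n <- nascent
  cc$ts$Q <- sum(SpotQuant:::.rBrightness(nascent, 48L, 0.8, 500))
  sc@cells <- list(cc)
  sc
}

test_that("nascent counting is the rounded intensity ratio with floor one", {
  ts <- data.frame(cell_id = "c1", x = 0, y = 0, z = 0, Q_ts = 1,
                   nascent_frac = NA, nascent_n = NA, in_nucleus = TRUE,
                   spot = 1L)
  one <- nascentCount(transform(ts, Q_ts = 1000), QRef = 1000)
  expect_equal(one$nascent_n, 1L)
  expect_equal(one$nascent_frac, 1)

  r34 <- nascentCount(transform(ts, Q_ts = 3400), QRef = 1000)
  expect_equal(r34$nascent_n, 3L)
  expect_equal(r34$nascent_frac, 3.4)

  r05 <- nascentCount(transform(ts, Q_ts = 400), QRef = 1000)
  expect_equal(r05$nascent_n, 1L)  # floor of one

  expect_error(nascentCount(ts, QRef = 0), "positive")
})

test_that("transcription sites are found in the nucleus and counted", {
  sc <- tsScene(seed = 61, nascent = 4L)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  out <- sceneOutlines(sc)
  ts <- findTS(st, out, QRef = 19200, raw = stk)
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$cell_id, "cell_001")
  expect_true(ts$in_nucleus)
  expect_equal(ts$nascent_n, 4L)
  # the TS spot is excluded from the mature count
  rec <- buildCellRecords(st, ts, out)
  expect_equal(rec$n_nascent, 4L)
  truthMat <- sceneCellTruth(sc)$n_mature
  expect_lt(abs(rec$n_mature - truthMat), 3)
})

test_that("no intra-nuclear spot above threshold means no TS", {
  p <- scenarioParams(nCells = 2, fieldShape = c(41L, 128L, 128L), seed = 71,
                      phaseFractions = c(G1 = 1, S = 0, G2 = 0, M = 0),
                      expressingFractionG1 = 1, tsFraction = 0, matureMean = 5)
  sc <- sampleScene(p)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  ts <- findTS(st, sceneOutlines(sc), QRef = 19200)
  expect_equal(nrow(ts), 0L)
})

test_that("a bright cytoplasmic spot is not a transcription site", {
  sc <- oneSpotScene(seed = 5, Q = 5 * 19200, field = c(41L, 96L, 96L))
  cc <- sceneCells(sc)[[1]]
  # place the bright spot in the cytoplasm, outside the nucleus polygon
  far <- cc$polygon[which.max(cc$polygon[, 1]), ]
  ctr <- colMeans(cc$polygon)
  pos <- ctr + 0.8 * (far - ctr)
  cc$mrnas <- data.frame(x = pos[1], y = pos[2], z = 4100, Q = 5 * 19200)
  sc@cells <- list(cc)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  ts <- findTS(st, sceneOutlines(sc), QRef = 19200)
  expect_equal(nrow(ts), 0L)
})

test_that("cells without nucleus outlines are skipped with a warning", {
  sc <- tsScene(seed = 61)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  out <- sceneOutlines(sc)
  out[[1]]@nucleus <- NULL
  expect_warning(ts <- findTS(st, out, QRef = 19200), "no nucleus")
  expect_equal(nrow(ts), 0L)
})

test_that("ts_factor is monotone and kills all sites at infinity", {
  sc <- tsScene(seed = 81, nascent = 3L)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  out <- sceneOutlines(sc)
  counts <- vapply(c(1.2, 1.5, 2.9, 1e6), function(f) {
    nrow(findTS(st, out, QRef = 19200,
                settings = detectionSettings(tsFactor = f)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[4], 0)
})

test_that("nascent fraction is invariant to intensity rescaling", {
  sc <- tsScene(seed = 91, nascent = 5L)
  stk <- renderStack(sc, "FISH")
  st1 <- detectSpots(stk)
  q1 <- median(acceptedSpots(st1)$Q)
  ts1 <- findTS(st1, sceneOutlines(sc), QRef = q1, raw = stk)

  a <- 2.5
  stk2 <- imageStack(stackData(stk) * a, voxelSize(stk), "FISH",
                     positionId(stk))
  st2 <- detectSpots(stk2)
  q2 <- median(acceptedSpots(st2)$Q)
  ts2 <- findTS(st2, sceneOutlines(sc), QRef = q2, raw = stk2)
  skip_if(nrow(ts1) == 0 || nrow(ts2) == 0)
  expect_lt(abs(ts2$nascent_frac - ts1$nascent_frac) / ts1$nascent_frac,
            0.02)
  expect_equal(ts1$nascent_n, ts2$nascent_n)
})
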