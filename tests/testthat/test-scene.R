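test_that("scenes are deterministic given a seed and empty when asked", {
  p <- scenarioParams(nCells = 6, fieldShape = c(41L, 256L, 256L), seed = 7)
  s1 <- sampleScene(p)
  s2 <- sampleScene(p)
  expect_identical(sceneCells(s1), sceneCells(s2))

  p0 <- scenarioParams(nCells = 0, seed = 1)
  expect_equal(nCells(sampleScene(p0)), 0L)
})

test_that("switching expression off empties every cell", {
  p <- scenarioParams(nCells = 8, fieldShape = c(41L, 256L, 256L), seed = 3,
                      expressingFractionG1 = 0)
  sc <- sampleScene(p)
  tr <- sceneTruth(sc)
  expect_equal(nrow(tr), 0L)
  expect_true(all(!sceneCellTruth(sc)$expressing))
})

test_that("count laws match their analytic moments at Monte-Carlo scale", {
  set.seed(42)
  n <- 10000L
  mat <- SpotQuant:::.rMature(n, 10.1, 1.3)
  varNB <- 10.1 + 10.1^2 / 1.3
  expect_lt(abs(mean(mat) - 10.1), 3 * sqrt(varNB / n))

  law <- ztpFromMean(3.6)
  nas <- SpotQuant:::.rztp(n, law$lambda)
  expect_true(all(nas >= 1L))
  expect_lt(abs(mean(nas) - 3.6), 3 * law$sd / sqrt(n))

  # per-molecule brightness: binomial occupancy CV
  q <- SpotQuant:::.rBrightness(n, 48L, 0.8, 500)
  cvTheory <- sqrt((1 - 0.8) / (48 * 0.8))
  expect_lt(abs(sd(q) / mean(q) - cvTheory), 0.15 * cvTheory)
})

test_that("geometry invariants hold for sampled cells", {
  p <- scenarioParams(nCells = 10, fieldShape = c(41L, 400L, 400L), seed = 11,
                      expressingFractionG1 = 1)
  sc <- sampleScene(p)
  for (cc in sceneCells(sc)) {
    expect_true(SpotQuant:::.polyIsSimple(cc$polygon))
    expect_true(SpotQuant:::.polyInside(cc$nucleus, cc$polygon))
    if (nrow(cc$mrnas) > 0) {
      expect_true(all(pointInPolygon(cc$mrnas$x, cc$mrnas$y, cc$polygon)))
      expect_false(any(pointInPolygon(cc$mrnas$x, cc$mrnas$y, cc$nucleus)))
    }
    if (!is.null(cc$ts)) {
      expect_true(pointInPolygon(cc$ts$x, cc$ts$y, cc$nucleus))
      expect_gte(cc$ts$nascent_n, 1L)
    }
  }
})

test_that("infeasible packing errors after bounded retries", {
  p <- scenarioParams(nCells = 60, fieldShape = c(41L, 128L, 128L), seed = 1)
  expect_error(sampleScene(p), "field too small|unable to place")
})

test_that("rendering conserves photons and superposes linearly", {
  sc <- oneSpotScene(seed = 5, Q = 19200)
  stk <- renderStack(sc, "FISH", noise = FALSE)
  mass <- sum(stackData(stk) - 100)
  expect_lt(abs(mass - 19200) / 19200, 0.01)

  # empty scene -> constant offset image
  p0 <- scenarioParams(nCells = 0, fieldShape = c(11L, 32L, 32L), seed = 2)
  s0 <- renderStack(sampleScene(p0), "FISH", noise = FALSE)
  expect_equal(max(stackData(s0)), 100)
  expect_equal(min(stackData(s0)), 100)

  # a TS with n equivalents at p_bind = 1 carries n times the single mass
  p <- scenarioParams(nCells = 1, fieldShape = c(41L, 64L, 64L), seed = 9,
                      pBind = 1, phaseFractions = c(G1 = 1, S = 0, G2 = 0,
                                                    M = 0))
  sc4 <- sampleScene(p)
  cc <- sceneCells(sc4)[[1]]
  cc$mrnas <- cc$mrnas[0, ]
  cc$ts <- list(x = 2050, y = 2050, z = 4100, nascent_n = 4L,
                Q = 4 * 48 * p@qProbe)
  sc4@cells <- list(cc)
  m4 <- sum(stackData(renderStack(sc4, "FISH", noise = FALSE)) - 100)
  single <- 48 * p@qProbe
  expect_lt(abs(m4 - 4 * single) / (4 * single), 0.01)
})

test_that("whole-scene rendered mass equals the summed truth brightness", {
  p <- scenarioParams(nCells = 4, fieldShape = c(41L, 256L, 256L), seed = 21,
                      expressingFractionG1 = 1)
  sc <- sampleScene(p)
  tr <- sceneTruth(sc)
  skip_if(nrow(tr) == 0)
  stk <- renderStack(sc, "FISH", noise = FALSE)
  mass <- sum(stackData(stk) - 100)
  expect_lt(abs(mass - sum(tr$Q_true)) / sum(tr$Q_true), 0.01)
})

test_that("renders are deterministic and truth tables export", {
  p <- scenarioParams(nCells = 2, fieldShape = c(21L, 180L, 180L), seed = 13,
                      expressingFractionG1 = 1)
  sc <- sampleScene(p)
  expect_identical(stackData(renderStack(sc, "FISH")),
                   stackData(renderStack(sc, "FISH")))
  f <- tempfile(fileext = ".csv")
  writeTruthTable(sc, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(sceneTruth(sc)))
})

test_that("z-drift injection is exact for integer drifts", {
  sc <- oneSpotScene(seed = 5)
  stk <- renderStack(sc, "FISH", noise = FALSE)
  expect_identical(stackData(injectZDrift(stk, c(0, 0))), stackData(stk))

  dr <- injectZDrift(stk, c(0, 1))
  d0 <- stackData(stk); d1 <- stackData(dr)
  nz <- dim(d0)[1]; nx <- dim(d0)[3]
  # plane k (1-based) is translated by (k - 1) px in x
  for (k in c(2L, 10L, nz)) {
    shift <- k - 1L
    skip_if(shift >= nx)
    expect_equal(d1[k, , (shift + 1L):nx], d0[k, , 1:(nx - shift)],
                 tolerance = 1e-12)
  }
})
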