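test_that("spot assignment follows point-in-polygon with smallest-wins", {
  sq <- function(x0, y0, w) cbind(c(x0, x0 + w, x0 + w, x0),
                                  c(y0, y0, y0 + w, y0 + w))
  outs <- list(cellOutline("big", sq(0, 0, 40)),
               cellOutline("small", sq(10, 10, 10)))
  mk <- function(xpx, ypx) {
    sp <- SpotQuant:::.emptyFit("none")[0, ]
    for (i in seq_along(xpx)) {
      r <- SpotQuant:::.emptyFit(NA_character_)
      r$x <- xpx[i] * 64.5; r$y <- ypx[i] * 64.5; r$z <- 4000
      r$converged <- TRUE; r$accepted <- TRUE
      sp <- rbind(sp, r)
    }
    new("SpotTable", positionId = "p", spots = sp,
        settings = detectionSettings(), histograms = list())
  }
  # centroid of the small square, a point only in the big one, one outside
  tab <- mk(c(15, 35, 90), c(15, 35, 90))
  asg <- assignSpots(tab, outs)
  expect_equal(asg$cell_id, c("small", "big", "unassigned"))

  # on-edge counts inside
  tabE <- mk(10, 15)
  expect_equal(assignSpots(tabE, outs)$cell_id, "small")
})

test_that("assignment conserves accepted non-TS spots", {
  p <- sparseSceneParams(seed = 17, nCells = 8, matureMean = 5)
  sc <- sampleScene(p)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  out <- sceneOutlines(sc)
  ts <- findTS(st, out, QRef = median(acceptedSpots(st)$Q))
  rec <- buildCellRecords(st, ts, out)
  nAccepted <- nrow(acceptedSpots(st))
  asg <- assignSpots(st, out)
  unassigned <- sum(asg$cell_id == "unassigned")
  tsAccepted <- if (nrow(ts) > 0)
    sum(spotFits(st)$accepted[ts$spot]) else 0L
  expect_equal(sum(rec$n_mature) + unassigned, nAccepted - tsAccepted)
})

test_that("per-cell counts match generator truth at sparse density", {
  p <- sparseSceneParams(seed = 19, nCells = 10, matureMean = 3)
  sc <- sampleScene(p)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  filt <- filterSpots(st, relativeQ = c(0.5, 1.5))
  out <- sceneOutlines(sc)
  rec <- buildCellRecords(filt, findTS(filt, out,
                                       median(acceptedSpots(filt)$Q)), out,
                          decomposeBright = TRUE,
                          QRef = median(acceptedSpots(filt)$Q))
  tr <- sceneCellTruth(sc)
  m <- merge(rec, tr, by = "cell_id")
  exact <- mean(m$n_mature.x == m$n_mature.y)
  expect_gte(exact, 0.9)
})

test_that("IF integration is background-corrected, local and linear", {
  p <- scenarioParams(nCells = 2, fieldShape = c(41L, 192L, 192L), seed = 23,
                      phaseFractions = c(G2 = 1, G1 = 0, S = 0, M = 0))
  sc <- sampleScene(p)
  ifs <- renderStack(sc, "IF", noise = FALSE)
  out <- sceneOutlines(sc)
  v1 <- ifIntegratedIntensity(ifs, out[[1]], c(4, 41))
  truthIF <- sceneCellTruth(sc)$if_total
  # the projection does not conserve 3D mass; check order and positivity
  expect_gt(v1, 0)
  v2 <- ifIntegratedIntensity(ifs, out[[2]], c(4, 41))
  expect_equal(order(c(v1, v2)), order(truthIF))

  # doubling the stack doubles the backgroundless integral
  ifs2 <- imageStack(stackData(ifs) * 2, voxelSize(ifs), "IF", "x")
  expect_lt(abs(ifIntegratedIntensity(ifs2, out[[1]], c(4, 41)) - 2 * v1) /
              (2 * v1), 0.05)

  # blank stack integrates to ~0
  blank <- imageStack(array(100, dim(stackData(ifs))), voxelSize(ifs), "IF")
  expect_equal(ifIntegratedIntensity(blank, out[[1]], c(4, 41)), 0)

  expect_error(ifIntegratedIntensity(ifs, out[[1]], c(10, 4)))
})

test_that("bottom-slide debris is excluded by the plane interval", {
  p <- scenarioParams(nCells = 2, fieldShape = c(41L, 192L, 192L), seed = 23,
                      phaseFractions = c(G2 = 1, G1 = 0, S = 0, M = 0))
  pDeb <- p
  pDeb@artifacts$debris <- TRUE
  clean <- renderStack(sampleScene(p), "IF", noise = FALSE)
  dirty <- renderStack(sampleScene(pDeb), "IF", noise = FALSE)
  out <- sceneOutlines(sampleScene(p))
  vClean <- ifIntegratedIntensity(clean, out[[1]], c(4, 41))
  vDirty <- ifIntegratedIntensity(dirty, out[[1]], c(4, 41))
  expect_lt(abs(vDirty - vClean) / vClean, 0.01)
  # without the exclusion the debris is picked up
  vAll <- ifIntegratedIntensity(dirty, out[[1]], c(1, 41))
  expect_gt(abs(vAll - vClean) / vClean, 0.01)
})

test_that("the scoring decision list follows its order and thresholds", {
  f <- data.frame(
    if_integrated = c(1, 5, 5, 5, 10, 5),
    bud_ratio = c(0, 0.15, 0.5, 0.5, 0, NA),
    spindle_span = c(300, 400, 800, 2500, 300, 500))
  ph <- scoreCellCycle(f, thresholds = list(r_S = 0.05, r_G2 = 0.35,
                                            span_M = 2000,
                                            tau_G1_pct = 0.40))
  expect_equal(ph, c("G1", "S", "G2", "M", "unscored", "unscored"))
})

test_that("automated scoring recovers generator phases on a cohort", {
  scenes <- simulateCohort(scenarioParams(seed = 3, nCells = 20L), 60,
                           seed = 77)
  feats <- NULL; phasesTruth <- NULL
  for (sc in scenes) {
    ifs <- renderStack(sc, "IF")
    feats <- rbind(feats, cellFeatures(sceneOutlines(sc), ifs,
                                       zRange = c(4, 41)))
    phasesTruth <- c(phasesTruth,
                     vapply(sceneCells(sc), `[[`, "", "phase"))
  }
  ph <- scoreCellCycle(feats)
  expect_gte(mean(ph == phasesTruth), 0.9)
})

test_that("manual scoring overrides automated phases", {
  p <- sparseSceneParams(seed = 29, nCells = 3)
  sc <- sampleScene(p)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  out <- sceneOutlines(sc)
  ts <- findTS(st, out, QRef = 19200)
  rec <- buildCellRecords(st, ts, out,
                          phases = c(cell_001 = "M", cell_002 = "S"))
  expect_equal(rec$phase[rec$cell_id == "cell_001"], "M")
  expect_equal(rec$phase[rec$cell_id == "cell_002"], "S")
  expect_equal(rec$phase[rec$cell_id == "cell_003"], "unscored")
})
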