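mkRecords <- function(mature, nascent = 0L) {
  n <- length(mature)
  data.frame(cell_id = sprintf("c%03d", seq_len(n)), position_id = "p",
             phase = "unscored", n_mature = mature,
             n_nascent = rep_len(nascent, n),
             if_integrated = NA_real_, bud_ratio = NA_real_,
             spindle_span = NA_real_,
             expressing = (mature + rep_len(nascent, n)) >= 1)
}

test_that("summary aggregates follow their definitions", {
  s <- summarizeCells(mkRecords(c(0L, 5L, 15L)), nBoot = 1000L, seed = 1)
  a <- s$aggregates
  expect_equal(a$n_cells, 3L)
  expect_equal(a$n_expressing, 2L)
  expect_equal(a$mean_expressing, 10)
  expect_true(a$ci95_expressing[1] <= 10 && 10 <= a$ci95_expressing[2])
  expect_equal(a$n_ts, 0L)
  expect_true(is.na(a$mean_nascent))

  ts <- data.frame(cell_id = c("c002", "c003"), x = 0, y = 0, z = 0,
                   Q_ts = c(2, 3), nascent_frac = c(2, 3),
                   nascent_n = c(2L, 3L), in_nucleus = TRUE, spot = 1:2)
  s2 <- summarizeCells(mkRecords(c(0L, 5L, 15L), 0L), ts, nBoot = 1000L)
  expect_equal(s2$aggregates$mean_nascent, 2.5)
  expect_equal(s2$aggregates$n_ts, 2L)

  expect_error(summarizeCells(mkRecords(c(0L))[0, ]), "no cell records")
})

test_that("bootstrap statistics are deterministic and degenerate-safe", {
  x <- c(2, 5, 9, 14, 30, 1, 1, 7)
  e1 <- expressingStats(x, nBoot = 2000L, seed = 9)
  e2 <- expressingStats(x, nBoot = 2000L, seed = 9)
  expect_identical(e1, e2)
  e3 <- expressingStats(x, nBoot = 2000L, seed = 10)
  expect_false(identical(e1$ci95_lo, e3$ci95_lo))

  cst <- expressingStats(rep(7, 20), nBoot = 1000L, seed = 1)
  expect_equal(cst$mean, 7)
  expect_equal(cst$ci95_lo, 7)
  expect_equal(cst$ci95_hi, 7)

  expect_error(expressingStats(numeric(0)))
  expect_error(expressingStats(1:10, nBoot = 10L))
})

test_that("bootstrap CI width shrinks like n^(-1/2)", {
  set.seed(5)
  widths <- vapply(c(100, 400, 1600), function(n) {
    x <- rnbinom(n, mu = 10.1, size = 1.3)
    e <- expressingStats(x, nBoot = 2000L, seed = 3)
    e$ci95_hi - e$ci95_lo
  }, numeric(1))
  expect_lt(abs(widths[1] / widths[2] - 2), 0.5)
  expect_lt(abs(widths[2] / widths[3] - 2), 0.5)
})

test_that("frequency distributions bin right-open from zero and normalize", {
  fd <- frequencyDistribution(c(0, 0, 1))
  expect_equal(fd$frequency[fd$bin_lo == 0], 2 / 3)
  expect_equal(fd$frequency[fd$bin_lo == 1], 1 / 3)
  expect_equal(sum(fd$frequency), 1)

  fd2 <- frequencyDistribution(c(0, 4, 5, 9, 10), binWidth = 5)
  expect_equal(fd2$count, c(2, 2, 1))
  expect_equal(sum(fd2$frequency), 1)

  set.seed(11)
  x <- rnbinom(5000, mu = 10.1, size = 1.3)
  fd3 <- frequencyDistribution(x)
  pmf <- dnbinom(fd3$bin_lo, mu = 10.1, size = 1.3)
  tv <- 0.5 * sum(abs(fd3$frequency - pmf)) +
    0.5 * (1 - sum(pmf))  # mass beyond the observed range
  expect_lt(tv, 0.05)
  expect_error(frequencyDistribution(c(1, 2), binWidth = 0))
})

test_that("histogram mass equals record counts in summaries", {
  rec <- mkRecords(c(0L, 2L, 2L, 7L))
  s <- summarizeCells(rec, nBoot = 1000L)
  expect_equal(sum(s$histograms$mature_per_cell$count), nrow(rec))
})

test_that("truth evaluation requires matching identifiers", {
  p <- sparseSceneParams(seed = 37, nCells = 3)
  sc <- sampleScene(p)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  out <- sceneOutlines(sc)
  ts <- findTS(st, out, QRef = 19200)
  rec <- buildCellRecords(st, ts, out)
  m <- evaluateAgainstTruth(rec, ts, list(st), list(sc))
  expect_true(is.finite(m$spot_f1))

  recBad <- rec
  recBad$cell_id <- paste0("zz_", recBad$cell_id)
  expect_error(evaluateAgainstTruth(recBad, ts, list(st), list(sc)),
               "cell ids")
  stBad <- st
  stBad@positionId <- "other"
  expect_error(evaluateAgainstTruth(rec, ts, list(stBad), list(sc)),
               "position ids")
})

test_that("a noiseless sparse scene is recovered perfectly", {
  sc <- oneSpotScene(seed = 5, field = c(41L, 128L, 128L))
  cc <- sceneCells(sc)[[1]]
  cc$mrnas <- data.frame(x = 64.5 * c(30, 70, 95), y = 64.5 * c(30, 80, 40),
                         z = c(3600, 4100, 4600), Q = 19200)
  cc$polygon <- cbind(c(0, 8256, 8256, 0), c(0, 0, 8256, 8256))
  cc$nucleus <- cbind(c(1, 2, 2, 1), c(1, 1, 2, 2))
  sc@cells <- list(cc)
  stk <- renderStack(sc, "FISH", noise = FALSE)
  st <- detectSpots(stk)
  out <- sceneOutlines(sc)
  ts <- findTS(st, out, QRef = 19200)
  rec <- buildCellRecords(st, ts, out)
  m <- evaluateAgainstTruth(rec, ts, list(st), list(sc))
  expect_equal(m$spot_f1, 1)
  expect_equal(m$count_mae, 0)
})
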