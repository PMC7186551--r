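test_that("TIFF stacks round-trip bit-identically with z as page order", {
  s <- imageStack(array(round(runif(41 * 16 * 16, 0, 60000)),
                        c(41, 16, 16)))
  f <- tempfile(fileext = ".tif")
  writeStack(s, f)
  r <- readStack(f)
  expect_identical(stackData(r), stackData(s))
  expect_equal(dim(stackData(r))[1], 41L)

  # z really is page order: distinctive plane content survives
  s2 <- imageStack(array(0, c(3, 4, 4)))
  s2@data[2, 1, 1] <- 1234
  f2 <- tempfile(fileext = ".tif")
  writeStack(s2, f2)
  expect_equal(stackData(readStack(f2))[2, 1, 1], 1234)
})

test_that("malformed TIFF input errors", {
  f <- tempfile(fileext = ".tif")
  writeLines("not a tiff", f)
  expect_error(readStack(f))
  expect_error(writeStack(imageStack(array(1e6, c(1, 2, 2))), tempfile()),
               "16-bit")
})

test_that("maximal projection respects the plane interval", {
  d <- array(0, c(8, 6, 6))
  d[3, 2, 2] <- 50
  d[7, 5, 5] <- 80
  s <- imageStack(d)
  expect_equal(maxProject(s, c(3, 3)), d[3, , ])
  p <- maxProject(s, c(1, 4))
  expect_equal(p[2, 2], 50)
  expect_equal(p[5, 5], 0)  # the plane-7 spot is outside the interval
  full <- maxProject(s)
  for (k in 1:8) expect_true(all(full >= d[k, , ]))
  expect_error(maxProject(s, c(5, 3)), "empty or out-of-range")
  expect_error(maxProject(s, c(1, 9)), "empty or out-of-range")
})

test_that("outline files round-trip and tolerate unknown headers", {
  tri <- cellOutline("c1", cbind(c(0, 10, 5), c(0, 0, 8)))
  f <- tempfile(fileext = ".txt")
  writeOutlines(list(tri), f)
  back <- readOutlines(f)
  expect_length(back, 1L)
  expect_equal(nrow(back[[1]]@cell), 3L)
  expect_equal(back[[1]]@cell, tri@cell)

  # random integer polygons round-trip exactly (writer keeps full precision)
  set.seed(8)
  outs <- lapply(1:20, function(i) {
    n <- sample(6:12, 1)
    th <- sort(runif(n, 0, 2 * pi))
    r <- runif(1, 25, 40)
    poly <- round(cbind(100 + r * cos(th), 100 + r * sin(th)))
    # nucleus well inside so that integer rounding cannot push it out
    nuc <- round(cbind(100 + 0.25 * r * cos(th), 100 + 0.25 * r * sin(th)))
    cellOutline(sprintf("c%02d", i), poly, nucleus = nuc,
                group = sample(c("G1", "S", "G2", "M", "unscored"), 1))
  })
  f2 <- tempfile(fileext = ".txt")
  writeOutlines(outs, f2)
  back2 <- suppressWarnings(readOutlines(f2))
  expect_length(back2, 20L)
  for (i in seq_along(outs)) {
    expect_equal(unname(back2[[i]]@cell), unname(outs[[i]]@cell))
    expect_equal(unname(back2[[i]]@nucleus), unname(outs[[i]]@nucleus))
    expect_equal(back2[[i]]@group, outs[[i]]@group)
  }

  # tolerant reader: unknown keys, blank lines, trailing whitespace
  txt <- c("SOME_HEADER\tv3", "", "CELL c9  ", "FANCY_KEY\t1\t2",
           "X_POS\t0\t10\t5", "Y_POS\t0\t0\t8   ", "")
  f3 <- tempfile(fileext = ".txt")
  writeLines(txt, f3)
  b3 <- readOutlines(f3)
  expect_length(b3, 1L)
  expect_equal(b3[[1]]@cellId, "c9")
  expect_equal(suppressWarnings(countOutlinedCells(c(f2, f3))), 21L)
})

test_that("outline errors and warnings fire where required", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("CELL bad", "X_POS\t0\t1", "Y_POS\t0\t1\t2"), f)
  expect_error(readOutlines(f), "matching X_POS/Y_POS")

  f2 <- tempfile(fileext = ".txt")
  writeLines(c("CELL bad2", "X_POS\t0\tzz\t5", "Y_POS\t0\t0\t8"), f2)
  expect_error(readOutlines(f2), "line")

  # nucleus outside the cell: flagged with a warning, not an error
  f3 <- tempfile(fileext = ".txt")
  writeLines(c("CELL c1", "X_POS\t0\t10\t10\t0", "Y_POS\t0\t0\t10\t10",
               "Nucleus", "X_POS\t50\t60\t55", "Y_POS\t50\t50\t60"), f3)
  expect_warning(readOutlines(f3), "outside the cell")
})

test_that("scoring CSV reads, validates groups and joins to outlines", {
  df <- data.frame(position_id = "pos_01", x = c(5, 25, 100),
                   y = c(5, 25, 100),
                   group = c("G1", "M", "S"))
  f <- tempfile(fileext = ".csv")
  writeScoringCsv(df, f)
  back <- readScoringCsv(f)
  expect_equal(back$group, df$group)

  bad <- df; bad$group[2] <- "G3"
  f2 <- tempfile(fileext = ".csv")
  write.csv(bad, f2, row.names = FALSE)
  expect_error(readScoringCsv(f2), "allowed")

  outs <- list(cellOutline("a", cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))),
               cellOutline("b", cbind(c(20, 30, 30, 20), c(20, 20, 30, 30))))
  m <- matchScoringToOutlines(back, outs)
  expect_equal(m$cell_id, c("a", "b", NA))
})

test_that("settings files round-trip, preserve unknown keys and validate", {
  s0 <- detectionSettings(predetectThreshold = 12.5)
  s0@extra <- c(microscope = "BX-63")
  f <- tempfile(fileext = ".txt")
  writeSettings(s0, f)
  s1 <- readSettings(f)
  expect_equal(s1@filterSigma, s0@filterSigma)
  expect_equal(s1@predetectThreshold, 12.5)
  expect_equal(s1@acceptBounds, s0@acceptBounds)
  expect_identical(s1@extra[["microscope"]], "BX-63")

  # auto threshold survives the round trip as NA
  f2 <- tempfile(fileext = ".txt")
  writeSettings(detectionSettings(), f2)
  expect_true(is.na(readSettings(f2)@predetectThreshold))

  lines <- readLines(f)
  f3 <- tempfile(fileext = ".txt")
  writeLines(lines[!grepl("^predetect_threshold", lines)], f3)
  expect_error(readSettings(f3), "predetect_threshold")

  f4 <- tempfile(fileext = ".txt")
  lines4 <- sub("^sigma_small_xy=.*$", "sigma_small_xy=9", lines)
  writeLines(lines4, f4)
  expect_error(readSettings(f4), "sigma_small")
})

test_that("a scene's scoring export round-trips to its ground-truth phases", {
  p <- scenarioParams(nCells = 6, fieldShape = c(41L, 320L, 320L), seed = 44)
  sc <- sampleScene(p)
  outs <- sceneOutlines(sc, group = "phase")
  scoring <- do.call(rbind, lapply(outs, function(o) {
    data.frame(position_id = o@positionId, x = mean(o@cell[, 1]),
               y = mean(o@cell[, 2]), group = o@group)
  }))
  f <- tempfile(fileext = ".csv")
  writeScoringCsv(scoring, f)
  back <- readScoringCsv(f)
  m <- matchScoringToOutlines(back, outs)
  expect_equal(m$cell_id, vapply(outs, function(o) o@cellId, ""))
  truthPhase <- vapply(sceneCells(sc), `[[`, "", "phase")
  expect_equal(m$group, truthPhase)
})
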