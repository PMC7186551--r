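test_that("pre-detection finds isolated spots and applies its threshold", {
  blank <- imageStack(array(0, c(11, 32, 32)))
  expect_equal(nrow(predetect(blank, threshold = 5)), 0L)
  expect_error(predetect(blank, threshold = 0), "positive")
  expect_error(predetect(blank, threshold = -2), "positive")
  expect_error(predetect(blank), "not set")

  # two rendered spots 10 px apart -> two candidates at the true centres
  sc <- oneSpotScene(seed = 5, pos = c(x = 1500, y = 1500, z = 4100),
                     field = c(41L, 64L, 64L))
  cc <- sceneCells(sc)[[1]]
  cc$mrnas <- data.frame(x = c(1500, 1500 + 10 * 64.5), y = c(1500, 1500),
                         z = c(4100, 4100), Q = c(19200, 19200))
  sc@cells <- list(cc)
  stk <- renderStack(sc, "FISH", noise = FALSE)
  filt <- bandpassFilter(stk)
  cand <- predetect(filt, detectionSettings(minSeparation = 3),
                    threshold = 5)
  expect_equal(nrow(cand), 2L)
  expect_lt(max(abs(sort(cand$x) - sort(c(1500, 2145) / 64.5 + 0.5))), 1.01)
  expect_lt(max(abs(cand$y - (1500 / 64.5 + 0.5))), 1.01)

  # closer than min_separation -> merged, keeping the brighter
  candM <- predetect(filt, detectionSettings(minSeparation = 12),
                     threshold = 5)
  expect_equal(nrow(candM), 1L)
})

test_that("plateaus of equal maxima give a single first-in-order candidate", {
  d <- array(0, c(7, 16, 16))
  d[4, 8:9, 8:9] <- 10  # 2x2 plateau in one plane
  f <- imageStack(d)
  cand <- predetect(f, threshold = 1)
  expect_equal(nrow(cand), 1L)
  expect_equal(unname(unlist(cand[1, c("z", "y", "x")])), c(4, 8, 8))
})

test_that("noiseless fits recover the generator parameters exactly", {
  truePos <- c(x = 2065.3, y = 2001.7, z = 4100)
  sc <- oneSpotScene(seed = 5, Q = 19200, pos = truePos)
  stk <- renderStack(sc, "FISH", noise = FALSE)
  st <- detectSpots(stk)
  fit <- acceptedSpots(st)
  expect_equal(nrow(fit), 1L)
  expect_lt(abs(fit$x - truePos["x"]), 1)     # nm
  expect_lt(abs(fit$y - truePos["y"]), 1)
  expect_lt(abs(fit$z - truePos["z"]), 1)
  expect_lt(abs(fit$Q - 19200) / 19200, 1e-3)
  expect_lt(abs(fit$sigma_xy - 130) / 130, 1e-3)
  expect_lt(abs(fit$sigma_z - 350) / 350, 1e-3)
  expect_lt(abs(fit$background - 100), 0.1)
})

test_that("degenerate fits fail cleanly", {
  flat <- imageStack(array(100, c(41, 32, 32)))
  fit <- fitSpot3d(flat, c(20L, 16L, 16L))
  expect_false(fit$converged)
  expect_false(fit$accepted)
  expect_equal(fit$reject_reason, "fit_failure")

  # window cropped at the boundary is flagged but still fitted
  sc <- oneSpotScene(seed = 5, pos = c(x = 300, y = 300, z = 4100),
                     field = c(41L, 48L, 48L))
  stk <- renderStack(sc, "FISH", noise = FALSE)
  f2 <- fitSpot3d(stk, c(21L, 5L, 5L))
  expect_true(f2$cropped)
})

test_that("acceptance filtering tags per-bound reasons and is monotone", {
  p <- sparseSceneParams(seed = 12, nCells = 6, field = c(41L, 256L, 256L))
  stk <- renderStack(sampleScene(p), "FISH")
  st <- detectSpots(stk)
  sp <- spotFits(st)
  skip_if(sum(sp$converged) < 5)

  # infinite bounds: accepted = converged minus duplicates
  inf <- filterSpots(st, bounds = list(sigma_xy = c(-Inf, Inf),
                                       sigma_z = c(-Inf, Inf),
                                       amplitude = c(-Inf, Inf),
                                       Q = c(-Inf, Inf)))
  dup <- spotFits(inf)$reject_reason %in% "duplicate"
  expect_equal(which(spotFits(inf)$accepted),
               which(spotFits(inf)$converged & !dup))

  # Q_max below every Q: nothing accepted, all tagged Q_high
  lowQ <- filterSpots(st, bounds = list(sigma_xy = c(-Inf, Inf),
                                        sigma_z = c(-Inf, Inf),
                                        amplitude = c(-Inf, Inf),
                                        Q = c(0, 1)))
  spl <- spotFits(lowQ)
  expect_equal(sum(spl$accepted), 0L)
  expect_true(all(grepl("Q_high",
                        spl$reject_reason[spl$converged & !dup])))

  # widening any bound never decreases the accepted count
  med <- median(sp$Q[sp$converged])
  widths <- c(0.1, 0.3, 0.6, 1.5)
  nAcc <- vapply(widths, function(w) {
    f <- filterSpots(st, bounds = list(sigma_xy = c(-Inf, Inf),
                                       sigma_z = c(-Inf, Inf),
                                       amplitude = c(-Inf, Inf),
                                       Q = med * c(1 - w, 1 + w)))
    sum(spotFits(f)$accepted)
  }, numeric(1))
  expect_true(all(diff(nAcc) >= 0))
})

test_that("the relative intensity band isolates singles from doublets", {
  # mixed singles and co-located doublets, well separated
  sc <- oneSpotScene(seed = 5, field = c(41L, 128L, 128L))
  cc <- sceneCells(sc)[[1]]
  xs <- 64.5 * c(20, 45, 70, 95, 32, 83)
  qs <- c(19200, 19200, 19200, 19200, 2 * 19200, 2 * 19200)
  cc$mrnas <- data.frame(x = xs, y = rep(64.5 * 60, 6),
                         z = rep(4100, 6), Q = qs)
  cc$polygon <- cbind(c(0, 8200, 8200, 0), c(0, 0, 8200, 8200))
  sc@cells <- list(cc)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  filt <- filterSpots(st, relativeQ = c(0.5, 1.5))
  acc <- acceptedSpots(filt)
  expect_equal(nrow(acc), 4L)
  expect_true(all(abs(acc$Q - 19200) / 19200 < 0.25))
  rej <- spotFits(filt)
  expect_equal(sum(grepl("Q_high", rej$reject_reason), na.rm = TRUE), 2L)
})

test_that("the composed detector is deterministic", {
  p <- sparseSceneParams(seed = 4, nCells = 3, field = c(41L, 160L, 160L))
  stk <- renderStack(sampleScene(p), "FISH")
  s1 <- detectSpots(stk)
  s2 <- detectSpots(stk)
  expect_identical(spotFits(s1), spotFits(s2))
})

test_that("accepted-Q distribution on singles mirrors the brightness law", {
  p <- spotFieldParams(seed = 6, nSpots = 60)
  sc <- sampleScene(p)
  stk <- renderStack(sc, "FISH")
  st <- detectSpots(stk)
  filt <- filterSpots(st, relativeQ = c(0.5, 1.5))
  acc <- acceptedSpots(filt)
  skip_if(nrow(acc) < 30)
  cvTheory <- sqrt((1 - 0.8) / (48 * 0.8))
  cvObs <- sd(acc$Q) / mean(acc$Q)
  expect_lt(abs(cvObs - cvTheory), 0.2 * cvTheory)
  # a homogeneous single-molecule population: narrow and centred
  expect_gt(mean(abs(acc$Q - median(acc$Q)) < 2.5 * cvTheory * median(acc$Q)),
            0.95)
})
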