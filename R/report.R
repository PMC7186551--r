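# Cohort summaries: expressing-cell statistics, frequency distributions,
# evaluation against generator truth.

#' Bootstrap mean of expressing-cell counts
#'
#' Percentile bootstrap of the mean, the convention for reporting mean with a
#' 95% confidence interval on non-normally distributed count data.
#' Deterministic given the seed.
#'
#' @param counts numeric vector of per-cell counts (non-empty).
#' @param nBoot bootstrap replicates (>= 1000; default 10000).
#' @param seed RNG seed.
#' @return list with \code{mean}, \code{ci95_lo}, \code{ci95_hi}, \code{n}.
#' @examples
#' expressingStats(c(2, 5, 9, 14, 30), nBoot = 1000, seed = 1)
#' @export
expressingStats <- function(counts, nBoot = 10000L, seed = 1L) {
  stopifnot(length(counts) > 0, nBoot >= 1000L)
  .withSeed(seed, {
    n <- length(counts)
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = n)
    means <- colMeans(matrix(counts[idx], nrow = n))
    ci <- unname(quantile(means, c(0.025, 0.975)))
    list(mean = mean(counts), ci95_lo = ci[1], ci95_hi = ci[2], n = n)
  })
}

#' Frequency distribution of per-cell counts
#'
#' Right-open integer bins \code{[k w, (k+1) w)} starting at zero;
#' frequencies sum to one.
#'
#' @param counts non-negative integer counts.
#' @param binWidth bin width (>= 1).
#' @return data.frame with \code{bin_lo}, \code{bin_hi}, \code{count},
#'   \code{frequency}.
#' @examples
#' frequencyDistribution(c(0, 0, 1))
#' @export
frequencyDistribution <- function(counts, binWidth = 1L) {
  stopifnot(binWidth >= 1, all(counts >= 0))
  k <- floor(counts / binWidth)
  kmax <- max(k, 0)
  tab <- tabulate(k + 1L, nbins = kmax + 1L)
  data.frame(bin_lo = (0:kmax) * binWidth,
             bin_hi = (1:(kmax + 1)) * binWidth,
             count = tab, frequency = tab / length(counts))
}

#' Summarize per-cell records
#'
#' Aggregates the per-cell table into the study-level outputs: number of
#' cells and expressing cells, expressing-cell mean total (mature + nascent)
#' mRNA count with a percentile-bootstrap 95% CI, nascent mean and SD over
#' transcription sites, and the two frequency distributions (mature per cell
#' over all cells; nascent per site).
#'
#' @param records per-cell data.frame from \code{\link{buildCellRecords}}.
#' @param tsRecords transcription-site data.frame from \code{\link{findTS}}.
#' @param nBoot,seed bootstrap settings for the expressing-cell CI.
#' @return list of class \code{smfishSummary}: \code{cells} (the records),
#'   \code{aggregates}, \code{histograms}.
#' @export
summarizeCells <- function(records, tsRecords = NULL, nBoot = 10000L,
                           seed = 1L) {
  if (is.null(records) || nrow(records) == 0L) stop("no cell records")
  total <- records$n_mature + records$n_nascent
  expr <- records$expressing
  agg <- list(n_cells = nrow(records), n_expressing = sum(expr))
  if (any(expr)) {
    es <- expressingStats(total[expr], nBoot = nBoot, seed = seed)
    agg$mean_expressing <- es$mean
    agg$ci95_expressing <- c(es$ci95_lo, es$ci95_hi)
  } else {
    agg$mean_expressing <- NA_real_
    agg$ci95_expressing <- c(NA_real_, NA_real_)
  }
  if (!is.null(tsRecords) && nrow(tsRecords) > 0) {
    agg$n_ts <- nrow(tsRecords)
    agg$mean_nascent <- mean(tsRecords$nascent_n)
    agg$sd_nascent <- sd(tsRecords$nascent_n)
  } else {
    agg$n_ts <- 0L
    agg$mean_nascent <- NA_real_
    agg$sd_nascent <- NA_real_
  }
  hists <- list(mature_per_cell = frequencyDistribution(records$n_mature),
                nascent_per_ts = if (agg$n_ts > 0)
                  frequencyDistribution(tsRecords$nascent_n) else NULL)
  structure(list(cells = records, aggregates = agg, histograms = hists),
            class = "smfishSummary")
}

#' @export
print.smfishSummary <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("%d cells, %d expressing\n", a$n_cells, a$n_expressing))
  if (!is.na(a$mean_expressing))
    cat(sprintf("  expressing-cell mean: %.2f mRNAs/cell (95%% CI %.2f-%.2f)\n",
                a$mean_expressing, a$ci95_expressing[1],
                a$ci95_expressing[2]))
  if (a$n_ts > 0)
    cat(sprintf("  nascent: %.2f +/- %.2f RNA/TS over %d sites\n",
                a$mean_nascent, a$sd_nascent, a$n_ts))
  invisible(x)
}

# Greedy nearest-neighbour matching of detected to true positions within a
# radius (px units per axis). Returns matched counts.
.matchSpots <- function(det, truth, vox, radiusPx = 2) {
  if (nrow(det) == 0L || nrow(truth) == 0L)
    return(list(tp = 0L, fp = nrow(det), fn = nrow(truth),
                dx = numeric(0), dy = numeric(0)))
  d2 <- outer(det$x / vox[3], truth$x / vox[3], "-")^2 +
        outer(det$y / vox[2], truth$y / vox[2], "-")^2 +
        outer(det$z / vox[1], truth$z / vox[1], "-")^2
  usedD <- logical(nrow(det)); usedT <- logical(nrow(truth))
  dxs <- dys <- numeric(0)
  ord <- order(d2)
  r2 <- radiusPx^2
  for (k in ord) {
    if (d2[k] > r2) break
    i <- (k - 1) %% nrow(det) + 1
    j <- (k - 1) %/% nrow(det) + 1
    if (usedD[i] || usedT[j]) next
    usedD[i] <- TRUE; usedT[j] <- TRUE
    dxs <- c(dxs, det$x[i] - truth$x[j])
    dys <- c(dys, det$y[i] - truth$y[j])
  }
  list(tp = sum(usedD), fp = sum(!usedD), fn = sum(!usedT),
       dx = dxs, dy = dys)
}

#' Evaluate pipeline output against generator truth
#'
#' Matches accepted detections to true molecule positions (greedy nearest
#' neighbour within a 2 px radius), and reports the detection F1 score, the
#' per-cell total-count mean absolute error, the fraction of true
#' transcription sites whose rounded nascent estimate equals the truth, and
#' the phase-scoring accuracy (when phases were scored).
#'
#' @param records per-cell data.frame (pooled over positions).
#' @param tsRecords transcription-site data.frame (pooled).
#' @param spotTables list of \linkS4class{SpotTable}, one per position.
#' @param scenes list of \linkS4class{Scene} (same positions, same order).
#' @param radiusPx match radius in pixels.
#' @return list with \code{spot_f1}, \code{precision}, \code{recall},
#'   \code{count_mae}, \code{nascent_exact_rate}, \code{phase_accuracy},
#'   \code{lateral_errors} (nm).
#' @export
evaluateAgainstTruth <- function(records, tsRecords, spotTables, scenes,
                                 radiusPx = 2) {
  ids <- vapply(scenes, function(s) s@positionId, character(1))
  tabIds <- vapply(spotTables, function(t) t@positionId, character(1))
  if (!identical(sort(ids), sort(tabIds)))
    stop("position ids of spot tables and scenes do not match")
  tp <- fp <- fn <- 0L
  lateral <- numeric(0)
  for (s in scenes) {
    truth <- sceneTruth(s)
    tab <- spotTables[[match(s@positionId, tabIds)]]
    det <- acceptedSpots(tab)
    m <- .matchSpots(det, truth[truth$type == "mature", ],
                     s@params@voxelSize, radiusPx)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    lateral <- c(lateral, sqrt(m$dx^2 + m$dy^2))
  }
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)

  cellTruth <- do.call(rbind, lapply(scenes, function(s) {
    ct <- sceneCellTruth(s)
    ct$position_id <- s@positionId
    ct
  }))
  key <- paste(records$position_id, records$cell_id)
  tkey <- paste(cellTruth$position_id, cellTruth$cell_id)
  if (!all(key %in% tkey)) stop("cell ids do not match the scenes")
  mt <- cellTruth[match(key, tkey), ]
  countMae <- mean(abs((records$n_mature + records$n_nascent) -
                       (mt$n_mature + mt$n_nascent)))
  # nascent recovery over true TS
  tsTruth <- mt[mt$n_nascent > 0, c("cell_id", "position_id", "n_nascent")]
  exact <- NA_real_
  if (nrow(tsTruth) > 0) {
    got <- vapply(seq_len(nrow(tsTruth)), function(i) {
      rec <- records$cell_id == tsTruth$cell_id[i] &
             records$position_id == tsTruth$position_id[i]
      sum(records$n_nascent[rec]) == tsTruth$n_nascent[i]
    }, logical(1))
    exact <- mean(got)
  }
  phaseAcc <- if (all(records$phase == "unscored")) NA_real_
              else mean(records$phase == mt$phase)
  list(spot_f1 = f1, precision = if (tp + fp > 0) tp / (tp + fp) else NA,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA,
       count_mae = countMae, nascent_exact_rate = exact,
       phase_accuracy = phaseAcc, lateral_errors = lateral)
}
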