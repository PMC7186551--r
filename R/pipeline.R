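# End-to-end composition: simulate -> detect -> reference -> TS -> cells ->
# summary, over a cohort of stage positions.

# Total background-subtracted photon content of each cell: the sum of
# (raw - median background) over all planes and the pixels inside the cell
# polygon. Conserved under any amount of spot blending, so it anchors the
# per-cell count where overlapping fits are unreliable.
.cellPhotonSums <- function(raw, outlines) {
  d <- raw@data
  dims <- dim(d)
  bg <- median(d)
  vapply(outlines, function(o) {
    poly <- o@cell
    xr <- max(1L, floor(min(poly[, 1]))):min(dims[3],
                                             ceiling(max(poly[, 1])) + 1L)
    yr <- max(1L, floor(min(poly[, 2]))):min(dims[2],
                                             ceiling(max(poly[, 2])) + 1L)
    gg <- expand.grid(y = yr, x = xr)
    inside <- pointInPolygon(gg$x - 0.5, gg$y - 0.5, poly)
    zsum <- colSums(matrix(d[, yr, xr], nrow = dims[1]))
    sum(zsum[inside]) - bg * dims[1] * sum(inside)
  }, numeric(1))
}

#' Analyse one rendered position
#'
#' Renders the FISH channel of a scene (and optionally the IF channel),
#' detects spots and returns the spot table together with the scene's
#' outlines.
#'
#' @param scene a \linkS4class{Scene}.
#' @param settings a \linkS4class{DetectionSettings}.
#' @param withIF also render the IF channel.
#' @return list with \code{spots} (\linkS4class{SpotTable}), \code{outlines},
#'   \code{cellPhotons} (per-cell background-subtracted photon content, used
#'   by the cohort pipeline's photometric cross-check), \code{ifStack} (or
#'   NULL), \code{scene}.
#' @export
analyzePosition <- function(scene, settings = detectionSettings(),
                            withIF = FALSE) {
  raw <- renderStack(scene, "FISH")
  spots <- detectSpots(raw, settings)
  outlines <- sceneOutlines(scene, group = "unscored")
  list(spots = spots, outlines = outlines,
       cellPhotons = .cellPhotonSums(raw, outlines),
       ifStack = if (withIF) renderStack(scene, "IF") else NULL,
       scene = scene)
}

#' Run the full synthetic cohort analysis
#'
#' Simulates a cohort of stage positions, detects spots per position, pools
#' the converged fits to derive the single-mRNA reference intensity (median
#' of per-spot integrated intensities), re-filters each position to the
#' single-molecule intensity band, identifies transcription sites inside the
#' nuclear outlines, builds per-cell records and summarizes.
#'
#' @param params \linkS4class{ScenarioParams} for one position.
#' @param nCellsTotal total cells across the cohort.
#' @param seed cohort seed (drives simulation and bootstrap).
#' @param settings a \linkS4class{DetectionSettings}.
#' @param relativeQ single-molecule intensity band as multiples of the
#'   reference (the interactive min/max refinement of the intensity
#'   histogram).
#' @param withIF render the IF channel and score phases automatically.
#' @param nBoot bootstrap replicates for the expressing-cell CI.
#' @return list with \code{summary} (\code{smfishSummary}), \code{records},
#'   \code{tsRecords}, \code{spotTables}, \code{scenes}, \code{QRef},
#'   \code{truth} (pooled per-cell truth), \code{metrics} (evaluation against
#'   truth).
#' @export
runCohortAnalysis <- function(params, nCellsTotal, seed = params@seed,
                              settings = detectionSettings(),
                              relativeQ = c(0.5, 1.5), withIF = FALSE,
                              nBoot = 10000L) {
  scenes <- simulateCohort(params, nCellsTotal, seed)
  spotTables <- vector("list", length(scenes))
  outlinesList <- vector("list", length(scenes))
  ifStacks <- vector("list", length(scenes))
  photonsList <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    pos <- analyzePosition(scenes[[i]], settings, withIF = withIF)
    spotTables[[i]] <- pos$spots
    outlinesList[[i]] <- pos$outlines
    photonsList[[i]] <- pos$cellPhotons
    ifStacks[i] <- list(pos$ifStack)
  }
  allQ <- unlist(lapply(spotTables, function(t) {
    sp <- t@spots
    sp$Q[sp$converged & !(sp$reject_reason %in% "duplicate")]
  }))
  if (length(allQ) == 0L) stop("no converged spots in the cohort")
  # two-step robust reference: an initial median over all converged fits,
  # then the median of the single-molecule band around it, so blended
  # multiplets and transcription sites do not drag the reference up
  QRef <- median(allQ)
  inBand <- allQ > relativeQ[1] * QRef & allQ < relativeQ[2] * QRef
  if (any(inBand)) QRef <- median(allQ[inBand])

  records <- NULL
  tsAll <- NULL
  for (i in seq_along(scenes)) {
    b <- spotTables[[i]]@settings@acceptBounds
    b$Q <- relativeQ * QRef
    tab <- filterSpots(spotTables[[i]], bounds = b)
    spotTables[[i]] <- tab
    ts <- findTS(tab, outlinesList[[i]], QRef, settings)
    rec <- buildCellRecords(tab, ts, outlinesList[[i]],
                            ifStack = ifStacks[[i]],
                            zRange = if (is.null(ifStacks[[i]])) NULL
                                     else c(4L, dim(ifStacks[[i]]@data)[1]),
                            decomposeBright = TRUE, QRef = QRef)
    # photometric cross-check: in a heavily crowded cell, independent
    # single-emitter fits are ill-posed and their intensity decomposition
    # can drift; the cell's background-subtracted photon content is
    # conserved regardless, so when the two totals disagree grossly the
    # photometric count replaces the spot-based one
    nPhot <- pmax(0, round(photonsList[[i]] / QRef))
    nSpot <- rec$n_mature + rec$n_nascent
    off <- abs(nSpot - nPhot) > pmax(2, 0.3 * nPhot)
    if (any(off)) {
      rec$n_mature[off] <- pmax(0L, nPhot[off] - rec$n_nascent[off])
      rec$expressing[off] <- (rec$n_mature[off] + rec$n_nascent[off]) >= 1
    }
    if (nrow(ts) > 0) ts$position_id <- scenes[[i]]@positionId
    records <- rbind(records, rec)
    tsAll <- rbind(tsAll, ts)
  }
  if (is.null(tsAll))
    tsAll <- data.frame(cell_id = character(0), x = numeric(0),
                        y = numeric(0), z = numeric(0), Q_ts = numeric(0),
                        nascent_frac = numeric(0), nascent_n = integer(0),
                        in_nucleus = logical(0), spot = integer(0),
                        position_id = character(0))
  summary <- summarizeCells(records, tsAll, nBoot = nBoot,
                            seed = .deriveSeed(seed, 999))
  truth <- do.call(rbind, lapply(scenes, function(s) {
    ct <- sceneCellTruth(s)
    ct$position_id <- s@positionId
    ct
  }))
  metrics <- evaluateAgainstTruth(records, tsAll, spotTables, scenes)
  list(summary = summary, records = records, tsRecords = tsAll,
       spotTables = spotTables, scenes = scenes, QRef = QRef,
       truth = truth, metrics = metrics)
}
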