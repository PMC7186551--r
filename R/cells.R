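# Per-cell quantification: spot assignment, IF integrated intensity,
# morphology features and cell-cycle scoring.

#' Assign spots to cell outlines
#'
#' Point-in-polygon on the lateral spot coordinates, even-odd rule with
#' on-edge points counted inside. Each spot is assigned at most once; when
#' outlines overlap the smaller polygon wins. Spots in no polygon go to the
#' \code{"unassigned"} bucket.
#'
#' @param spots a \linkS4class{SpotTable}.
#' @param outlines list of \linkS4class{CellOutline}.
#' @param which which spot rows to assign: \code{"accepted"} (default) or
#'   \code{"all"} converged fits.
#' @return data.frame with \code{spot} (row index into the spot table) and
#'   \code{cell_id} (\code{"unassigned"} when outside every outline).
#' @export
assignSpots <- function(spots, outlines, which = c("accepted", "all")) {
  which <- match.arg(which)
  sp <- spots@spots
  idx <- if (which == "accepted") base::which(sp$accepted)
         else base::which(sp$converged)
  if (length(idx) == 0L)
    return(data.frame(spot = integer(0), cell_id = character(0)))
  dy <- spots@settings@voxelSize[2]; dx <- spots@settings@voxelSize[3]
  px <- sp$x[idx] / dx
  py <- sp$y[idx] / dy
  areas <- vapply(outlines, function(o) .polyArea(o@cell), numeric(1))
  ord <- order(areas)
  cellId <- rep("unassigned", length(idx))
  open <- rep(TRUE, length(idx))
  for (j in ord) {
    if (!any(open)) break
    o <- outlines[[j]]
    hit <- open
    hit[open] <- pointInPolygon(px[open], py[open], o@cell)
    cellId[hit] <- o@cellId
    open <- open & !hit
  }
  data.frame(spot = idx, cell_id = cellId)
}

#' Integrated IF intensity within a cell outline
#'
#' Sum, over the pixels inside the cell polygon, of the maximal projection of
#' the IF stack over \code{zRange}, after subtracting the projection's median
#' (whole-image) background. Restricting \code{zRange} to the planes where
#' the cells sit excludes bottom-of-slide debris from the quantification.
#'
#' @param ifStack the IF \linkS4class{ImageStack}.
#' @param outline a \linkS4class{CellOutline}.
#' @param zRange inclusive 1-based plane interval; must be non-empty.
#' @return integrated intensity (ADU) above background.
#' @export
ifIntegratedIntensity <- function(ifStack, outline, zRange = NULL) {
  proj <- maxProject(ifStack, zRange)
  bg <- median(proj)
  poly <- outline@cell
  xr <- max(1L, floor(min(poly[, 1]))):min(ncol(proj),
                                           ceiling(max(poly[, 1])) + 1L)
  yr <- max(1L, floor(min(poly[, 2]))):min(nrow(proj),
                                           ceiling(max(poly[, 2])) + 1L)
  gg <- expand.grid(y = yr, x = xr)
  # pixel (row i, col j) has centre (j - 0.5, i - 0.5) in 0-based px coords
  inside <- pointInPolygon(gg$x - 0.5, gg$y - 0.5, poly)
  sum(proj[cbind(gg$y[inside], gg$x[inside])] - bg)
}

#' Morphology and IF features of outlined cells
#'
#' Computes, per cell: the bud-to-mother area ratio (mother lobe estimated as
#' the largest inscribed circle of the cell polygon; bud area is the polygon
#' area in excess of it), the spindle span (largest pairwise distance between
#' above-threshold IF pixels inside the cell, nm) and the integrated IF
#' intensity.
#'
#' @param outlines list of \linkS4class{CellOutline}.
#' @param ifStack optional IF \linkS4class{ImageStack}; without it the
#'   IF-derived features are \code{NA}.
#' @param zRange plane interval for the IF projection.
#' @param voxelSize \code{(dz, dy, dx)} nm (pixel pitch for spans).
#' @return data.frame with \code{cell_id}, \code{bud_ratio},
#'   \code{spindle_span}, \code{if_integrated}.
#' @export
cellFeatures <- function(outlines, ifStack = NULL, zRange = NULL,
                         voxelSize = c(200, 64.5, 64.5)) {
  proj <- NULL; bg <- NA; madProj <- NA
  if (!is.null(ifStack)) {
    proj <- maxProject(ifStack, zRange)
    bg <- median(proj)
    madProj <- mad(proj)
  }
  dx <- voxelSize[3]
  rows <- lapply(outlines, function(o) {
    poly <- o@cell
    # mother lobe = polygon within the (slightly inflated) largest inscribed
    # disk; the excess polygon area is the bud. Grid-counted at 1 px so the
    # two areas are measured consistently.
    mic <- .maxInscribedCircle(poly)
    xr <- max(1L, floor(min(poly[, 1]))):ceiling(max(poly[, 1]) + 1)
    yr <- max(1L, floor(min(poly[, 2]))):ceiling(max(poly[, 2]) + 1)
    gg <- expand.grid(y = yr, x = xr)
    gx <- gg$x - 0.5; gy <- gg$y - 0.5
    inside <- pointInPolygon(gx, gy, poly)
    inMother <- inside &
      ((gx - mic$center[1])^2 + (gy - mic$center[2])^2 <=
         (1.08 * mic$radius)^2)
    budRatio <- max(0, (sum(inside) - sum(inMother)) / max(sum(inMother), 1))
    ifInt <- NA_real_; span <- NA_real_
    if (!is.null(proj)) {
      keep <- inside & gg$y >= 1 & gg$y <= nrow(proj) &
        gg$x >= 1 & gg$x <= ncol(proj)
      vals <- proj[cbind(gg$y[keep], gg$x[keep])]
      ifInt <- sum(vals - bg)
      thr <- bg + max(6 * madProj, 0.25 * (max(vals) - bg))
      bx <- gg$x[keep][vals > thr]; by <- gg$y[keep][vals > thr]
      span <- 0
      if (length(bx) >= 2L) {
        if (length(bx) > 40L) {
          hull <- chull(bx, by)
          bx <- bx[hull]; by <- by[hull]
        }
        span <- sqrt(max(outer(bx, bx, "-")^2 + outer(by, by, "-")^2)) * dx
      }
    }
    data.frame(cell_id = o@cellId, bud_ratio = budRatio,
               spindle_span = span, if_integrated = ifInt)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score cell-cycle phases from IF and morphology features
#'
#' Ordered decision list encoding the qualitative scoring rules: an extended
#' spindle marks M; a large bud marks G2; a small bud marks S; an unbudded
#' cell with tubulin signal below the cohort percentile threshold is G1;
#' anything else (including cells with missing features) is unscored.
#'
#' @param features data.frame from \code{\link{cellFeatures}} (columns
#'   \code{if_integrated}, \code{bud_ratio}, \code{spindle_span}).
#' @param thresholds list: \code{r_S}, \code{r_G2} (bud-area ratios),
#'   \code{span_M} (nm), \code{tau_G1_pct} (cohort IF percentile for the G1
#'   intensity cut).
#' @return character vector of phases, one per row of \code{features}.
#' @examples
#' f <- data.frame(if_integrated = c(1, 10), bud_ratio = c(0, 0.15),
#'                 spindle_span = c(300, 400))
#' scoreCellCycle(f)
#' @export
scoreCellCycle <- function(features,
                           thresholds = list(r_S = 0.05, r_G2 = 0.35,
                                             span_M = 2000,
                                             tau_G1_pct = 0.40)) {
  tau <- quantile(features$if_integrated, thresholds$tau_G1_pct,
                  na.rm = TRUE, names = FALSE)
  phase <- rep("unscored", nrow(features))
  for (i in seq_len(nrow(features))) {
    sp <- features$spindle_span[i]
    br <- features$bud_ratio[i]
    ii <- features$if_integrated[i]
    if (is.na(sp) || is.na(br) || is.na(ii)) next
    phase[i] <- if (sp > thresholds$span_M) "M"
      else if (br > thresholds$r_G2) "G2"
      else if (br > thresholds$r_S) "S"
      else if (ii < tau) "G1"
      else "unscored"
  }
  phase
}

#' Build per-cell records
#'
#' Combines spot assignment, transcription sites and (optionally) IF-based
#' features and scoring into one row per cell: phase, mature count (accepted
#' spots in the cell minus its transcription sites), nascent count, IF
#' integrated intensity and the expressing flag (at least one mature or
#' nascent transcript).
#'
#' @param spots a filtered \linkS4class{SpotTable}.
#' @param tsRecords transcription-site data.frame from \code{\link{findTS}}.
#' @param outlines list of \linkS4class{CellOutline}.
#' @param ifStack optional IF \linkS4class{ImageStack}.
#' @param zRange plane interval for IF quantification.
#' @param phases optional named character vector (cell_id -> phase) that
#'   overrides automated scoring, e.g. from a manual scoring CSV.
#' @param decomposeBright count cytoplasmic spots rejected as too bright
#'   (\code{Q_high}) as \code{round(Q / QRef)} unresolved mRNAs instead of
#'   discarding them. At ~10 mRNAs per cell a pair of transcripts can sit
#'   within the axial resolution limit and fuse into one bright spot; the
#'   same intensity ratio that counts nascent RNAs at a transcription site
#'   decomposes such multiplets. Off by default (one accepted spot = one
#'   mRNA).
#' @param QRef single-mRNA reference intensity, required when
#'   \code{decomposeBright = TRUE}.
#' @return data.frame of cell records.
#' @export
buildCellRecords <- function(spots, tsRecords, outlines, ifStack = NULL,
                             zRange = NULL, phases = NULL,
                             decomposeBright = FALSE, QRef = NULL) {
  asg <- assignSpots(spots, outlines,
                     which = if (decomposeBright) "all" else "accepted")
  sp <- spots@spots
  weight <- rep(0, nrow(sp))
  weight[sp$accepted] <- 1
  if (decomposeBright) {
    stopifnot(!is.null(QRef), QRef > 0)
    bright <- sp$converged & !sp$accepted &
      grepl("Q_high", ifelse(is.na(sp$reject_reason), "", sp$reject_reason))
    weight[bright] <- pmax(1, floor(sp$Q[bright] / QRef + 0.5))
  }
  tsSpots <- if (nrow(tsRecords) > 0) tsRecords$spot else integer(0)
  feats <- cellFeatures(outlines, ifStack, zRange,
                        voxelSize = spots@settings@voxelSize)
  auto <- if (!is.null(ifStack)) scoreCellCycle(feats)
          else rep("unscored", length(outlines))
  rows <- lapply(seq_along(outlines), function(j) {
    o <- outlines[[j]]
    mine <- asg$spot[asg$cell_id == o@cellId]
    nMature <- sum(weight[setdiff(mine, tsSpots)])
    nNascent <- if (nrow(tsRecords) > 0)
      sum(tsRecords$nascent_n[tsRecords$cell_id == o@cellId]) else 0L
    phase <- if (!is.null(phases) && o@cellId %in% names(phases))
      phases[[o@cellId]] else auto[j]
    data.frame(cell_id = o@cellId, position_id = o@positionId,
               phase = phase, n_mature = nMature, n_nascent = nNascent,
               if_integrated = feats$if_integrated[j],
               bud_ratio = feats$bud_ratio[j],
               spindle_span = feats$spindle_span[j],
               expressing = (nMature + nNascent) >= 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
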