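# Transcription-site identification and nascent-RNA counting.

#' Identify transcription sites inside nuclear outlines
#'
#' A transcription site is a spot whose centre lies inside a cell's nucleus
#' polygon and whose integrated intensity reaches \code{tsFactor} times the
#' single-mRNA reference. Both accepted spots and spots rejected only for
#' being too bright (\code{Q_high}) qualify, since the intensity filter that
#' isolates single mRNAs deliberately rejects the brighter sites. At most
#' \code{maxTS} sites are kept per cell, by descending intensity. When the
#' raw stack is supplied, each site is refitted with width bounds relaxed
#' 1.5-fold to absorb the larger emitting region.
#'
#' @param spots a filtered \linkS4class{SpotTable}.
#' @param outlines list of \linkS4class{CellOutline} with nucleus polygons;
#'   cells without a nucleus are skipped with a warning.
#' @param QRef single-mRNA reference intensity (> 0).
#' @param settings a \linkS4class{DetectionSettings}.
#' @param raw optional raw \linkS4class{ImageStack} for the relaxed refit.
#' @return data.frame of transcription-site records: \code{cell_id},
#'   \code{x}, \code{y}, \code{z} (nm), \code{Q_ts}, \code{nascent_frac},
#'   \code{nascent_n}, \code{in_nucleus}, \code{spot} (row index into the
#'   spot table).
#' @export
findTS <- function(spots, outlines, QRef, settings = detectionSettings(),
                   raw = NULL) {
  stopifnot(QRef > 0)
  sp <- spots@spots
  emptyTS <- data.frame(cell_id = character(0), x = numeric(0),
                        y = numeric(0), z = numeric(0), Q_ts = numeric(0),
                        nascent_frac = numeric(0), nascent_n = integer(0),
                        in_nucleus = logical(0), spot = integer(0))
  if (nrow(sp) == 0L) return(emptyTS)
  eligible <- sp$converged &
    (sp$accepted | grepl("Q_high", ifelse(is.na(sp$reject_reason), "",
                                          sp$reject_reason))) &
    sp$Q >= settings@tsFactor * QRef
  idx <- which(eligible)
  if (length(idx) == 0L) return(emptyTS)
  dy <- settings@voxelSize[2]; dx <- settings@voxelSize[3]
  px <- sp$x[idx] / dx
  py <- sp$y[idx] / dy
  recs <- list()
  for (o in outlines) {
    if (is.null(o@nucleus)) {
      warning(sprintf("cell '%s' has no nucleus outline; skipped", o@cellId))
      next
    }
    inNuc <- pointInPolygon(px, py, o@nucleus)
    if (!any(inNuc)) next
    cand <- idx[inNuc]
    cand <- cand[order(-sp$Q[cand])]
    cand <- head(cand, settings@maxTS)
    for (ci in cand) {
      Qts <- sp$Q[ci]
      xx <- sp$x[ci]; yy <- sp$y[ci]; zz <- sp$z[ci]
      if (!is.null(raw)) {
        vox <- raw@voxelSize
        refit <- fitSpot3d(raw, c(round(zz / vox[1] + 0.5),
                                  round(yy / vox[2] + 0.5),
                                  round(xx / vox[3] + 0.5)),
                           settings, relaxWidths = 1.5)
        if (refit$converged) {
          Qts <- refit$Q; xx <- refit$x; yy <- refit$y; zz <- refit$z
        }
      }
      recs[[length(recs) + 1L]] <- data.frame(
        cell_id = o@cellId, x = xx, y = yy, z = zz, Q_ts = Qts,
        nascent_frac = NA_real_, nascent_n = NA_integer_,
        in_nucleus = TRUE, spot = ci)
    }
  }
  if (length(recs) == 0L) return(emptyTS)
  nascentCount(do.call(rbind, recs), QRef)
}

#' Nascent-RNA count of transcription sites
#'
#' The nascent count estimate is the site's integrated intensity divided by
#' the single-mRNA reference, rounded to the nearest integer with a floor of
#' one; the fractional value is retained for audit.
#'
#' @param ts transcription-site data.frame (see \code{\link{findTS}}).
#' @param QRef single-mRNA reference intensity (> 0).
#' @return the data.frame with \code{nascent_frac} and \code{nascent_n}
#'   filled in.
#' @examples
#' ts <- data.frame(cell_id = "c1", x = 0, y = 0, z = 0, Q_ts = 3.4,
#'                  nascent_frac = NA, nascent_n = NA, in_nucleus = TRUE,
#'                  spot = 1L)
#' nascentCount(ts, QRef = 1)$nascent_n
#' @export
nascentCount <- function(ts, QRef) {
  if (QRef <= 0) stop("QRef must be positive")
  ts$nascent_frac <- ts$Q_ts / QRef
  ts$nascent_n <- pmax(1L, as.integer(floor(ts$nascent_frac + 0.5)))
  ts
}
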