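# Averaged single-molecule image and the single-mRNA reference intensity.

# Trilinear interpolation of a 3D array at continuous 1-based voxel-index
# coordinates (vectors z, y, x of equal length); outside -> NA.
.sampleTrilinear <- function(arr, z, y, x) {
  dims <- dim(arr)
  z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  get <- function(zi, yi, xi) {
    ok <- zi >= 1 & zi <= dims[1] & yi >= 1 & yi <= dims[2] &
          xi >= 1 & xi <= dims[3]
    v <- rep(NA_real_, length(zi))
    v[ok] <- arr[cbind(zi[ok], yi[ok], xi[ok])]
    v
  }
  v <- (1 - fz) * (1 - fy) * (1 - fx) * get(z0, y0, x0) +
       (1 - fz) * (1 - fy) * fx * get(z0, y0, x0 + 1) +
       (1 - fz) * fy * (1 - fx) * get(z0, y0 + 1, x0) +
       (1 - fz) * fy * fx * get(z0, y0 + 1, x0 + 1) +
       fz * (1 - fy) * (1 - fx) * get(z0 + 1, y0, x0) +
       fz * (1 - fy) * fx * get(z0 + 1, y0, x0 + 1) +
       fz * fy * (1 - fx) * get(z0 + 1, y0 + 1, x0) +
       fz * fy * fx * get(z0 + 1, y0 + 1, x0 + 1)
  v
}

#' Average the accepted single-molecule images
#'
#' Extracts the fit window around each accepted spot with subvoxel
#' re-centring (trilinear interpolation, which preserves positivity),
#' subtracts each spot's fitted background, takes the voxel-wise mean and
#' refits the averaged image with the same 3D Gaussian. Two single-mRNA
#' reference estimators are returned: the refit integral (\code{QRef}) and
#' the median of the per-spot integrals (\code{QRefRobust}, the default used
#' downstream, robust to residual doublet contamination).
#'
#' @param raw the raw \linkS4class{ImageStack}.
#' @param table a filtered \linkS4class{SpotTable} with accepted spots.
#' @param settings a \linkS4class{DetectionSettings}.
#' @return an \linkS4class{AvgMolecule}.
#' @export
averageMolecule <- function(raw, table, settings = detectionSettings()) {
  acc <- acceptedSpots(table)
  if (nrow(acc) == 0L) stop("no molecules to average")
  vox <- raw@voxelSize
  hw <- (settings@fitWindow - 1L) %/% 2L
  offs <- expand.grid(z = -hw[1]:hw[1], y = -hw[2]:hw[2], x = -hw[3]:hw[3])
  shape <- settings@fitWindow
  accum <- array(0, shape)
  nUsed <- 0L
  for (i in seq_len(nrow(acc))) {
    cz <- acc$z[i] / vox[1] + 0.5
    cy <- acc$y[i] / vox[2] + 0.5
    cx <- acc$x[i] / vox[3] + 0.5
    v <- .sampleTrilinear(raw@data, cz + offs$z, cy + offs$y, cx + offs$x)
    if (anyNA(v)) next  # window clipped by the field boundary
    accum <- accum + array(v - acc$background[i], shape)
    nUsed <- nUsed + 1L
  }
  if (nUsed == 0L) stop("no molecules to average (all windows clipped)")
  avg <- accum / nUsed
  avgPos <- pmax(avg, 0)
  stk <- imageStack(avgPos, vox, raw@channel, raw@positionId)
  centre <- (shape + 1L) %/% 2L
  fit <- fitSpot3d(stk, centre, settings)
  m <- .spotModel(c(fit$x, fit$y, fit$z, fit$sigma_xy, fit$sigma_z, fit$Q,
                    fit$background),
                  seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]),
                  vox)
  resid <- avg - m$pred
  new("AvgMolecule", avgStack = avg, nContributing = nUsed, fit = fit,
      residualStack = resid, QRef = fit$Q, QRefRobust = median(acc$Q))
}

#' Single-mRNA reference intensity
#'
#' @param avg an \linkS4class{AvgMolecule}.
#' @param mode \code{"robust"} (median of per-spot integrated intensities,
#'   default) or \code{"fit"} (integral of the averaged-image refit).
#' @return the reference integrated intensity (ADU voxel).
#' @export
referenceIntensity <- function(avg, mode = c("robust", "fit")) {
  mode <- match.arg(mode)
  switch(mode, robust = avg@QRefRobust, fit = avg@QRef)
}
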