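# Candidate pre-detection, voxel-integrated 3D Gaussian fitting, acceptance
# filtering, and the composed detector.

# Optimizer box constraints on the PSF widths (nm); a transcription site
# refit relaxes them by `relax`.
.fitSigmaBounds <- function(relax = 1) {
  list(sigma_xy = c(50, 400 * relax), sigma_z = c(150, 1000 * relax))
}

#' Pre-detect spot candidates on a filtered stack
#'
#' 3D local maxima (26-connectivity) above the pre-detection threshold.
#' Candidates closer than \code{minSeparation} are merged keeping the
#' brighter one; ties and plateaus resolve to the first voxel in (z, y, x)
#' order. Candidates are returned in deterministic order: descending filtered
#' value, then ascending z, y, x.
#'
#' @param filtered band-pass filtered \linkS4class{ImageStack} (from
#'   \code{\link{bandpassFilter}}).
#' @param settings a \linkS4class{DetectionSettings}.
#' @param threshold override of the ADU threshold (must be > 0); defaults to
#'   the settings value.
#' @return data.frame of candidates: 1-based voxel indices \code{z, y, x} and
#'   the filtered \code{value}.
#' @export
predetect <- function(filtered, settings = detectionSettings(),
                      threshold = NULL) {
  if (is.null(threshold)) threshold <- settings@predetectThreshold
  if (is.na(threshold))
    stop("predetect threshold is not set; pass one or use detectSpots()")
  if (threshold <= 0) stop("predetect threshold must be positive")
  m <- cpp_local_max3d(filtered@data, dim(filtered@data), threshold)
  cand <- as.data.frame(m)
  ord <- order(-cand$value, cand$z, cand$y, cand$x)
  cand <- cand[ord, , drop = FALSE]
  # merge close candidates, keeping the brighter (earlier in order)
  if (nrow(cand) > 1L) {
    keep <- rep(TRUE, nrow(cand))
    minSep2 <- settings@minSeparation^2
    for (i in seq_len(nrow(cand) - 1L)) {
      if (!keep[i]) next
      j <- (i + 1L):nrow(cand)
      j <- j[keep[j]]
      if (length(j) == 0L) next
      d2 <- (cand$z[j] - cand$z[i])^2 + (cand$y[j] - cand$y[i])^2 +
            (cand$x[j] - cand$x[i])^2
      keep[j[d2 < minSep2]] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

# Model and analytic Jacobian of the voxel-integrated tri-axial Gaussian
# over a window. par = (x0, y0, z0, sxy, sz, Q, B); ix/iy/iz are 1-based
# voxel indices of the window.
.spotModel <- function(par, iz, iy, ix, vox) {
  pz <- .voxelMass(iz, par[3], par[5], vox[1])
  py <- .voxelMass(iy, par[2], par[4], vox[2])
  px <- .voxelMass(ix, par[1], par[4], vox[3])
  list(pred = par[7] + par[6] * outer(outer(pz, py), px),
       pz = pz, py = py, px = px)
}

.spotJacobian <- function(par, iz, iy, ix, vox, m) {
  dMass <- function(idx, mu, sigma, d) {
    a <- ((idx - 1) * d - mu) / sigma
    b <- (idx * d - mu) / sigma
    list(dmu = (dnorm(a) - dnorm(b)) / sigma,
         dsig = (a * dnorm(a) - b * dnorm(b)) / sigma)
  }
  gz <- dMass(iz, par[3], par[5], vox[1])
  gy <- dMass(iy, par[2], par[4], vox[2])
  gx <- dMass(ix, par[1], par[4], vox[3])
  Q <- par[6]
  n <- length(m$pz) * length(m$py) * length(m$px)
  J <- matrix(0, n, 7)
  J[, 1] <- Q * as.numeric(outer(outer(m$pz, m$py), gx$dmu))
  J[, 2] <- Q * as.numeric(outer(outer(m$pz, gy$dmu), m$px))
  J[, 3] <- Q * as.numeric(outer(outer(gz$dmu, m$py), m$px))
  J[, 4] <- Q * (as.numeric(outer(outer(m$pz, m$py), gx$dsig)) +
                 as.numeric(outer(outer(m$pz, gy$dsig), m$px)))
  J[, 5] <- Q * as.numeric(outer(outer(gz$dsig, m$py), m$px))
  J[, 6] <- as.numeric(outer(outer(m$pz, m$py), m$px))
  J[, 7] <- 1
  J
}

# Peak-amplitude equivalent of an integrated intensity Q (continuous
# Gaussian approximation): A = Q dz dy dx / ((2 pi)^{3/2} sxy^2 sz).
.amplitudeFromQ <- function(Q, sxy, sz, vox) {
  Q * prod(vox) / ((2 * pi)^1.5 * sxy^2 * sz)
}

.emptyFit <- function(reason) {
  data.frame(x = NA_real_, y = NA_real_, z = NA_real_,
             amplitude = NA_real_, background = NA_real_,
             sigma_xy = NA_real_, sigma_z = NA_real_, Q = NA_real_,
             residual_rms = NA_real_, converged = FALSE, cropped = FALSE,
             accepted = FALSE, reject_reason = reason)
}

#' Fit one candidate with a voxel-integrated 3D Gaussian
#'
#' Bounded Levenberg-Marquardt least squares of
#' \code{B + Q * g(x - x0, y - y0, z - z0; sigma_xy, sigma_xy, sigma_z)} on
#' the raw stack over the fit window, where \code{g} is integrated over each
#' voxel (error-function differences per axis) so the fitted \code{Q} is the
#' spot's total integrated intensity in ADU voxel. The peak amplitude is
#' derived from the fit. Windows cropped by the stack boundary are fitted
#' with the \code{cropped} flag set.
#'
#' @param raw the raw \linkS4class{ImageStack}.
#' @param candidate one candidate row (\code{z, y, x} 1-based voxel indices)
#'   or a length-3 vector \code{c(z, y, x)}.
#' @param settings a \linkS4class{DetectionSettings}.
#' @param relaxWidths multiply the upper width bounds (transcription-site
#'   refits use 1.5).
#' @param subtractFits optional data.frame of other fitted spots
#'   (\code{x, y, z, sigma_xy, sigma_z, Q}); their model contribution is
#'   subtracted from the window before fitting, so neighbouring spots do not
#'   inflate this spot's intensity.
#' @return one-row data.frame (a spot fit; see \linkS4class{SpotTable}).
#' @export
fitSpot3d <- function(raw, candidate, settings = detectionSettings(),
                      relaxWidths = 1, subtractFits = NULL) {
  if (is.data.frame(candidate))
    candidate <- c(candidate$z[1], candidate$y[1], candidate$x[1])
  dims <- dim(raw@data)
  vox <- raw@voxelSize
  hw <- (settings@fitWindow - 1L) %/% 2L
  zr <- max(1L, candidate[1] - hw[1]):min(dims[1], candidate[1] + hw[1])
  yr <- max(1L, candidate[2] - hw[2]):min(dims[2], candidate[2] + hw[2])
  xr <- max(1L, candidate[3] - hw[3]):min(dims[3], candidate[3] + hw[3])
  cropped <- length(zr) < settings@fitWindow[1] ||
    length(yr) < settings@fitWindow[2] || length(xr) < settings@fitWindow[3]
  win <- raw@data[zr, yr, xr, drop = FALSE]
  if (!is.null(subtractFits) && nrow(subtractFits) > 0) {
    for (s in seq_len(nrow(subtractFits))) {
      win <- win - .spotModel(
        c(subtractFits$x[s], subtractFits$y[s], subtractFits$z[s],
          subtractFits$sigma_xy[s], subtractFits$sigma_z[s],
          subtractFits$Q[s], 0), zr, yr, xr, vox)$pred
    }
  }

  b0 <- as.numeric(quantile(win, 0.25))
  peak <- win[candidate[1] - min(zr) + 1L, candidate[2] - min(yr) + 1L,
              candidate[3] - min(xr) + 1L]
  sxy0 <- 130; sz0 <- 350
  q0 <- max((peak - b0) * (2 * pi)^1.5 * sxy0^2 * sz0 / prod(vox), 10)
  p0 <- c(x = (candidate[3] - 0.5) * vox[3],
          y = (candidate[2] - 0.5) * vox[2],
          z = (candidate[1] - 0.5) * vox[1],
          sxy = sxy0, sz = sz0, Q = q0, B = b0)
  # the centre may move at most the candidate-separation radius from its
  # pre-detection voxel, so fits cannot slide onto a brighter neighbour
  sb <- .fitSigmaBounds(relaxWidths)
  sep <- settings@minSeparation
  # background is bounded below at zero: camera counts cannot go negative,
  # and an unbounded B lets runaway fits trade intensity against background
  lower <- c(p0[1] - sep * vox[3], p0[2] - sep * vox[2], p0[3] - sep * vox[1],
             sb$sigma_xy[1], sb$sigma_z[1], 0, 0)
  upper <- c(p0[1] + sep * vox[3], p0[2] + sep * vox[2], p0[3] + sep * vox[1],
             sb$sigma_xy[2], sb$sigma_z[2], Inf, Inf)
  obs <- as.numeric(win)
  resFn <- function(par) {
    as.numeric(.spotModel(par, zr, yr, xr, vox)$pred) - obs
  }
  jacFn <- function(par) {
    m <- .spotModel(par, zr, yr, xr, vox)
    # window data are laid out (z, y, x); model/jacobian share that order
    .spotJacobian(par, zr, yr, xr, vox, m)
  }
  fit <- tryCatch(
    suppressWarnings(  # non-convergence is read off the info code instead
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resFn,
                         jac = jacFn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-8, ptol = 1e-8))),
    error = function(e) NULL)
  if (is.null(fit)) return(.emptyFit("fit_failure"))
  par <- fit$par
  amp <- .amplitudeFromQ(par[6], par[4], par[5], vox)
  converged <- fit$info %in% 1:4 && all(is.finite(par)) && amp > 1e-6
  out <- data.frame(
    x = par[1], y = par[2], z = par[3], amplitude = amp, background = par[7],
    sigma_xy = par[4], sigma_z = par[5], Q = par[6],
    residual_rms = sqrt(mean(fit$fvec^2)), converged = converged,
    cropped = cropped, accepted = FALSE,
    reject_reason = if (converged) NA_character_ else "fit_failure")
  rownames(out) <- NULL
  out
}

#' Filter fitted spots into accepted detections
#'
#' A fit is accepted when it converged and every parameter lies within its
#' \code{[min, max]} acceptance bound. Rejected fits are retained with a
#' \code{reject_reason} tag per violated bound (e.g. \code{Q_high},
#' \code{sigma_xy_low}); integrated-intensity histograms of the accepted and
#' rejected populations are recomputed.
#'
#' @param table a \linkS4class{SpotTable}.
#' @param bounds named list of \code{c(min, max)} bounds for \code{sigma_xy},
#'   \code{sigma_z}, \code{amplitude}, \code{Q}; defaults to the table's
#'   settings snapshot. Bounds may also be given relative to the accepted
#'   median Q via \code{relativeQ = c(lo, hi)}.
#' @param relativeQ optional \code{c(lo, hi)} multiples of the median
#'   converged Q, overriding the absolute Q bound (the interactive
#'   min/max-intensity refinement).
#' @return the filtered \linkS4class{SpotTable}.
#' @export
filterSpots <- function(table, bounds = NULL, relativeQ = NULL) {
  sp <- table@spots
  if (nrow(sp) == 0L) return(table)
  if (is.null(bounds)) bounds <- table@settings@acceptBounds
  if (!is.null(relativeQ)) {
    medQ <- median(sp$Q[sp$converged &
                          !(sp$reject_reason %in% "duplicate")], na.rm = TRUE)
    bounds$Q <- relativeQ * medQ
  }
  dup <- !is.na(sp$reject_reason) & sp$reject_reason == "duplicate"
  reasons <- character(nrow(sp))
  for (nm in c("sigma_xy", "sigma_z", "amplitude", "Q")) {
    b <- bounds[[nm]]
    v <- sp[[nm]]
    reasons <- paste0(reasons,
                      ifelse(!is.na(v) & v < b[1], paste0(nm, "_low;"), ""),
                      ifelse(!is.na(v) & v > b[2], paste0(nm, "_high;"), ""))
  }
  reasons <- sub(";$", "", reasons)
  sp$accepted <- sp$converged & !dup & reasons == ""
  sp$reject_reason <- ifelse(sp$accepted, NA_character_,
                             ifelse(!sp$converged, "fit_failure",
                                    ifelse(dup, "duplicate", reasons)))
  histOf <- function(q) {
    q <- q[is.finite(q)]
    if (length(q) < 2L) return(NULL)
    tryCatch(graphics::hist(q, breaks = "FD", plot = FALSE),
             error = function(e) graphics::hist(q, plot = FALSE))
  }
  new("SpotTable", positionId = table@positionId, spots = sp,
      settings = table@settings,
      histograms = list(accepted = histOf(sp$Q[sp$accepted]),
                        rejected = histOf(sp$Q[!sp$accepted &
                                                 is.finite(sp$Q)])))
}

#' Detect spots in a raw stack
#'
#' The composed detector: band-pass filter, pre-detection, per-candidate 3D
#' Gaussian fit on the raw stack, sub-resolution duplicate removal (two
#' converged centres closer than \code{minSeparation} keep the lower
#' residual), and acceptance filtering. When the settings'
#' \code{predetectThreshold} is \code{NA} the threshold is derived from the
#' unclipped band-pass response as median + \code{thresholdFactor} * MAD.
#' Deterministic given its inputs.
#'
#' @param raw the raw \linkS4class{ImageStack}.
#' @param settings a \linkS4class{DetectionSettings}.
#' @return a \linkS4class{SpotTable}.
#' @examples
#' sc <- sampleScene(scenarioParams(nCells = 2, fieldShape = c(41, 160, 160),
#'                                  seed = 11))
#' st <- detectSpots(renderStack(sc, "FISH"), detectionSettings())
#' nrow(acceptedSpots(st))
#' @export
detectSpots <- function(raw, settings = detectionSettings()) {
  dog <- .dog3d(raw@data, settings@filterSigma)
  thr <- settings@predetectThreshold
  if (is.na(thr)) {
    v <- as.numeric(dog)
    thr <- median(v) + settings@thresholdFactor * mad(v)
  }
  dog[dog < 0] <- 0
  filtered <- imageStack(dog, raw@voxelSize, raw@channel, raw@positionId)
  cand <- predetect(filtered, settings, threshold = thr)
  fits <- if (nrow(cand) == 0L) .emptyFit("none")[0, ] else
    do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
      fitSpot3d(raw, cand[i, ], settings)))
  # neighbour-subtraction refinement: refit each spot on the window with the
  # current model of all other spots removed, so nearby spots do not inflate
  # each other's integrated intensity or pull each other's centres together.
  # The intensity update is damped (geometric mean of old and new Q) to keep
  # overlapping fits from oscillating. De-duplication runs afterwards, once
  # genuinely distinct neighbours have relaxed back onto their own spots.
  # Heavily crowded clusters remain ill-posed for independent single-emitter
  # fits; the cohort pipeline cross-checks per-cell counts photometrically.
  for (pass in 1:3) {
    live <- which(fits$converged &
                    !(fits$reject_reason %in% "duplicate"))
    if (length(live) < 2L) break
    prev <- fits
    for (i in live) {
      others <- setdiff(live, i)
      near <- others[abs(prev$z[others] - prev$z[i]) < 2400 &
                     abs(prev$y[others] - prev$y[i]) < 1100 &
                     abs(prev$x[others] - prev$x[i]) < 1100]
      if (length(near) == 0L) next
      refit <- fitSpot3d(raw, cand[i, ], settings,
                         subtractFits = prev[near, ])
      if (refit$converged) {
        refit$Q <- sqrt(pmax(refit$Q, 1) * pmax(prev$Q[i], 1))
        refit$amplitude <- .amplitudeFromQ(refit$Q, refit$sigma_xy,
                                           refit$sigma_z, raw@voxelSize)
        fits[i, ] <- refit
      }
    }
  }
  fits <- .dedupeFits(fits, raw@voxelSize, settings@minSeparation)
  tab <- new("SpotTable", positionId = raw@positionId, spots = fits,
             settings = settings, histograms = list())
  filterSpots(tab)
}

# Sub-resolution duplicates (two converged centres closer than the
# candidate-separation radius): keep the lower-residual fit.
.dedupeFits <- function(fits, vox, minSep) {
  if (nrow(fits) < 2L) return(fits)
  conv <- which(fits$converged)
  if (length(conv) < 2L) return(fits)
  ord <- conv[order(fits$residual_rms[conv])]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) > 0L) {
      d2 <- ((fits$x[i] - fits$x[kept]) / vox[3])^2 +
            ((fits$y[i] - fits$y[kept]) / vox[2])^2 +
            ((fits$z[i] - fits$z[kept]) / vox[1])^2
      if (any(d2 < minSep^2)) {
        fits$reject_reason[i] <- "duplicate"
        next
      }
    }
    kept <- c(kept, i)
  }
  fits
}
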