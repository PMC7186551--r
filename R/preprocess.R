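# Background estimation, band-pass (difference-of-Gaussians) SNR enhancement,
# z-drift QC by phase correlation, DIC-to-fluorescence registration.

# Sampled, normalized 1D Gaussian kernel; half-width ceil(3.5 sigma).
.gaussKernel1d <- function(sigma) {
  if (sigma < 1e-3) return(1)
  h <- max(1L, ceiling(3.5 * sigma))
  k <- dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

.blur3d <- function(data, sigmaZ, sigmaY, sigmaX) {
  cpp_gauss_blur3d(data, dim(data), .gaussKernel1d(sigmaZ),
                   .gaussKernel1d(sigmaY), .gaussKernel1d(sigmaX))
}

#' Robust background of a stack
#'
#' @param stack an \linkS4class{ImageStack}.
#' @return list with \code{median} and \code{mad} over all voxels.
#' @examples
#' estimateBackground(imageStack(array(100, c(3, 4, 4))))
#' @export
estimateBackground <- function(stack) {
  v <- as.numeric(stack@data)
  list(median = median(v), mad = mad(v))
}

#' Band-pass filter a stack (difference of Gaussians)
#'
#' \code{G(sigma_small) * I - G(sigma_large) * I}, computed with separable,
#' edge-renormalized Gaussian kernels (a constant image maps to exactly
#' zero). Negative values are clipped to zero. Lateral sigmas are in pixels,
#' axial in planes.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param settings a \linkS4class{DetectionSettings} (filter widths).
#' @return the filtered \linkS4class{ImageStack}.
#' @export
bandpassFilter <- function(stack, settings = detectionSettings()) {
  out <- .dog3d(stack@data, settings@filterSigma)
  out[out < 0] <- 0
  imageStack(out, stack@voxelSize, stack@channel, stack@positionId)
}

# Unclipped difference-of-Gaussians response (plain array).
.dog3d <- function(data, fs) {
  .blur3d(data, fs["small_z"], fs["small_xy"], fs["small_xy"]) -
    .blur3d(data, fs["large_z"], fs["large_xy"], fs["large_xy"])
}

# ---- phase correlation ------------------------------------------------------

# Shift of image b relative to image a (b is a translated by the returned
# (dy, dx)), by windowed phase correlation with parabolic subpixel
# refinement. Returns the shift, the correlation-peak z-score used as a
# confidence measure, and whether the estimate is usable.
.phaseCorrelate <- function(a, b, window = TRUE) {
  ny <- nrow(a); nx <- ncol(a)
  a <- a - mean(a); b <- b - mean(b)
  if (sd(a) < 1e-12 || sd(b) < 1e-12)
    return(list(shift = c(NA_real_, NA_real_), conf = 0, ok = FALSE))
  if (window) {
    wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / (ny - 1))
    wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / (nx - 1))
    w <- outer(wy, wx)
    a <- a * w; b <- b * w
  }
  fa <- fft(a); fb <- fft(b)
  cp <- fb * Conj(fa)
  mag <- Mod(cp)
  cp <- cp / pmax(mag, 1e-12)
  # regularize the whitened spectrum with a Gaussian low-pass so the
  # correlation peak has a finite (Gaussian) width; a raw phase-correlation
  # peak is delta-like and its sub-pixel interpolation snaps to integers
  sigmaR <- 1.3
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / ny
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / nx
  H <- outer(exp(-2 * pi^2 * sigmaR^2 * fy^2),
             exp(-2 * pi^2 * sigmaR^2 * fx^2))
  r <- Re(fft(cp * H, inverse = TRUE)) / length(cp)
  pk <- which.max(r)
  py <- (pk - 1) %% ny; px <- (pk - 1) %/% ny
  peak <- r[pk]
  conf <- (peak - mean(r)) / max(sd(r), 1e-12)
  # sub-pixel refinement: log-parabola (exact on a Gaussian peak), with a
  # plain parabola fallback when a neighbour is non-positive
  wrap <- function(i, n) ((i %% n) + n) %% n
  rym <- r[wrap(py - 1, ny) + 1 + px * ny]
  ryp <- r[wrap(py + 1, ny) + 1 + px * ny]
  rxm <- r[py + 1 + wrap(px - 1, nx) * ny]
  rxp <- r[py + 1 + wrap(px + 1, nx) * ny]
  subp <- function(rm, r0, rp) {
    if (rm > 0 && r0 > 0 && rp > 0) {
      lm_ <- log(rm); l0 <- log(r0); lp <- log(rp)
      den <- lm_ - 2 * l0 + lp
      if (abs(den) > 1e-12)
        return(max(-0.5, min(0.5, 0.5 * (lm_ - lp) / den)))
    }
    den <- rm - 2 * r0 + rp
    if (abs(den) < 1e-12) 0 else max(-0.5, min(0.5, 0.5 * (rm - rp) / den))
  }
  dy <- py + subp(rym, peak, ryp)
  dx <- px + subp(rxm, peak, rxp)
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  list(shift = c(dy, dx), conf = conf, ok = is.finite(conf) && conf > 6)
}

#' Estimate axial drift of a z-stack
#'
#' Lateral shift between consecutive planes is measured by windowed phase
#' correlation on the band-pass-filtered stack (adjacent planes share spot
#' structure through the axial PSF extent, and the filter removes the flat
#' background so featureless planes carry no spurious signal). Consecutive
#' shifts are cumulated into a per-plane shift relative to plane 1 and the
#' drift slope (px/plane) is the component-wise median of the consecutive
#' shifts, refined by least squares over the cumulated series. The stack is
#' flagged when either slope component exceeds the threshold. Plane pairs
#' without enough shared content are reported as not estimable and never
#' flag the stack on their own.
#'
#' @param stack an \linkS4class{ImageStack} with at least 3 planes.
#' @param threshold flag threshold in px/plane (default 0.5).
#' @param settings a \linkS4class{DetectionSettings} (band-pass widths).
#' @return a \code{DriftReport} list: \code{per_plane_shift} (nz x 2 matrix,
#'   dy/dx, NA where not estimable), \code{slope} (dy, dx px/plane),
#'   \code{flagged}, \code{threshold}, \code{n_estimable}.
#' @export
estimateZDrift <- function(stack, threshold = 0.5,
                           settings = detectionSettings()) {
  nz <- dim(stack@data)[1]
  if (nz < 3L) stop("drift estimation needs at least 3 planes")
  # per-plane 2D band-pass: filtering across z would smear the laterally
  # shifted planes into each other and bias the estimate towards zero
  fs <- settings@filterSigma
  d <- .blur3d(stack@data, 0, fs["small_xy"], fs["small_xy"]) -
       .blur3d(stack@data, 0, fs["large_xy"], fs["large_xy"])
  d[d < 0] <- 0
  # only planes with real spot content support a shift estimate
  planeSd <- vapply(seq_len(nz), function(k) sd(d[k, , ]), numeric(1))
  sdFloor <- 0.25 * max(planeSd)
  delta <- matrix(NA_real_, nz - 1L, 2)
  conf <- logical(nz - 1L)
  for (k in seq_len(nz - 1L)) {
    if (planeSd[k] < sdFloor || planeSd[k + 1L] < sdFloor) next
    pc <- .phaseCorrelate(d[k, , ], d[k + 1L, , ])
    if (pc$ok && pc$conf > 10) {
      delta[k, ] <- pc$shift
      conf[k] <- TRUE
    }
  }
  per <- matrix(NA_real_, nz, 2)
  colnames(per) <- c("dy", "dx")
  per[1, ] <- 0
  if (sum(conf) < 3L) {
    return(structure(list(per_plane_shift = per, slope = c(dy = NA, dx = NA),
                          flagged = FALSE, threshold = threshold,
                          n_estimable = sum(conf)), class = "DriftReport"))
  }
  slope0 <- apply(delta[conf, , drop = FALSE], 2, median)
  run <- c(0, cumsum(ifelse(conf, delta[, 1], slope0[1])))
  per[, 1] <- ifelse(c(TRUE, conf), run, NA)
  run <- c(0, cumsum(ifelse(conf, delta[, 2], slope0[2])))
  per[, 2] <- ifelse(c(TRUE, conf), run, NA)
  k <- seq_len(nz) - 1
  fitSlope <- function(y, fallback) {
    ok <- !is.na(y)
    if (sum(ok) < 2) return(fallback)
    unname(coef(lm(y[ok] ~ k[ok]))[2])
  }
  slope <- c(dy = fitSlope(per[, 1], slope0[1]),
             dx = fitSlope(per[, 2], slope0[2]))
  flagged <- isTRUE(max(abs(slope)) > threshold)
  structure(list(per_plane_shift = per, slope = slope, flagged = flagged,
                 threshold = threshold, n_estimable = sum(conf)),
            class = "DriftReport")
}

#' @export
print.DriftReport <- function(x, ...) {
  cat(sprintf(
    "DriftReport: slope (dy, dx) = (%.3f, %.3f) px/plane, %s (threshold %g)\n",
    x$slope[1], x$slope[2],
    if (x$flagged) "FLAGGED" else "not flagged", x$threshold))
  cat(sprintf("  %d of %d plane pairs estimable\n", x$n_estimable,
              nrow(x$per_plane_shift) - 1L))
  invisible(x)
}

#' Register a DIC image to a fluorescence reference
#'
#' Corrects the systematic DIC-to-fluorescence translation offset. If
#' \code{shift} is given it is applied directly (integer translation, zero
#' fill); otherwise the shift is estimated by maximizing the normalized
#' cross-correlation over a bounded integer search window. When no shift in
#' the window reaches \code{minCorr}, the image is returned unshifted with a
#' warning.
#'
#' @param dic 2D matrix (the DIC plane).
#' @param reference 2D matrix of the same shape.
#' @param shift optional known \code{(dy, dx)} displacement of the DIC image
#'   relative to the reference; when given it is undone directly.
#' @param searchWindow half-width of the integer search window, px.
#' @param minCorr confidence floor on the correlation peak.
#' @return list with \code{image} (registered DIC), \code{shift} (estimated
#'   dy, dx displacement of the DIC), \code{correlation}, \code{confident}.
#' @export
registerDic <- function(dic, reference, shift = NULL, searchWindow = 10L,
                        minCorr = 0.2) {
  stopifnot(identical(dim(dic), dim(reference)))
  ny <- nrow(dic); nx <- ncol(dic)
  if (2L * searchWindow + 1L > min(ny, nx))
    stop("search window larger than the image")
  if (is.null(shift)) {
    best <- c(0, 0); bestC <- -Inf
    for (sy in -searchWindow:searchWindow) {
      ys <- max(1, 1 - sy):min(ny, ny - sy)
      for (sx in -searchWindow:searchWindow) {
        xs <- max(1, 1 - sx):min(nx, nx - sx)
        cc <- suppressWarnings(cor(as.numeric(dic[ys + sy, xs + sx]),
                                   as.numeric(reference[ys, xs])))
        if (is.finite(cc) && cc > bestC) {
          bestC <- cc
          best <- c(sy, sx)
        }
      }
    }
    if (bestC < minCorr) {
      warning("correlation peak below confidence floor; image left unshifted")
      return(list(image = dic, shift = c(0, 0), correlation = bestC,
                  confident = FALSE))
    }
    shift <- best
    corrOut <- bestC
  } else {
    shift <- round(shift)
    corrOut <- NA_real_
  }
  out <- matrix(0, ny, nx)
  ys <- max(1, 1 - shift[1]):min(ny, ny - shift[1])
  xs <- max(1, 1 - shift[2]):min(nx, nx - shift[2])
  out[ys, xs] <- dic[ys + shift[1], xs + shift[2]]
  list(image = out, shift = shift, correlation = corrOut, confident = TRUE)
}
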