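# Forward model: voxel-integrated Gaussian PSF rendering and camera noise.

# Per-axis voxel probability masses for a Gaussian centred at mu (nm) with
# width sigma, over 1-based voxel indices idx (voxel i spans [(i-1)d, i d)).
.voxelMass <- function(idx, mu, sigma, d) {
  pnorm((idx * d - mu) / sigma) - pnorm(((idx - 1) * d - mu) / sigma)
}

# Add voxel-integrated Gaussian emitters into a (nz, ny, nx) array.
# emitters: data.frame with x, y, z (nm), q (total ADU voxel) and optional
# sigma_xy, sigma_z overriding the defaults. Emitters outside the field
# contribute their in-field tail only.
.renderEmitters <- function(data, emitters, voxelSize, sigmaXY, sigmaZ,
                            nSigma = 4.5) {
  if (is.null(emitters) || nrow(emitters) == 0L) return(data)
  dims <- dim(data)
  dz <- voxelSize[1]; dy <- voxelSize[2]; dx <- voxelSize[3]
  sxy <- if ("sigma_xy" %in% names(emitters)) emitters$sigma_xy
         else rep(sigmaXY, nrow(emitters))
  sz <- if ("sigma_z" %in% names(emitters)) emitters$sigma_z
        else rep(sigmaZ, nrow(emitters))
  for (i in seq_len(nrow(emitters))) {
    q <- emitters$q[i]
    if (q <= 0) next
    zr <- max(1L, floor((emitters$z[i] - nSigma * sz[i]) / dz)):
          min(dims[1], ceiling((emitters$z[i] + nSigma * sz[i]) / dz) + 1L)
    yr <- max(1L, floor((emitters$y[i] - nSigma * sxy[i]) / dy)):
          min(dims[2], ceiling((emitters$y[i] + nSigma * sxy[i]) / dy) + 1L)
    xr <- max(1L, floor((emitters$x[i] - nSigma * sxy[i]) / dx)):
          min(dims[3], ceiling((emitters$x[i] + nSigma * sxy[i]) / dx) + 1L)
    if (!length(zr) || !length(yr) || !length(xr)) next
    pz <- .voxelMass(zr, emitters$z[i], sz[i], dz)
    py <- .voxelMass(yr, emitters$y[i], sxy[i], dy)
    px <- .voxelMass(xr, emitters$x[i], sxy[i], dx)
    data[zr, yr, xr] <- data[zr, yr, xr] + q * outer(outer(pz, py), px)
  }
  data
}

# Camera model: counts = offset + gain * Poisson(photons / gain) + read noise,
# rounded to integer ADU and clipped at 0 (16-bit ceiling).
.applyCameraNoise <- function(signal, noise) {
  n <- length(signal)
  counts <- noise["offset"] +
    noise["gain"] * rpois(n, pmax(signal, 0) / noise["gain"]) +
    rnorm(n, 0, noise["read_sd"])
  out <- pmin(pmax(round(counts), 0), 65535)
  dim(out) <- dim(signal)
  out
}

#' Render a scene into an image stack
#'
#' Forward model for one channel of one stage position. Molecules (and
#' transcription sites, as co-located nascent-molecule equivalents) are
#' rendered as voxel-integrated tri-axial Gaussians whose total integral is
#' the molecule's true brightness, so that with noise off the rendered mass
#' equals the ground-truth brightness up to the out-of-field tail. Camera
#' noise is \code{offset + gain * Poisson(signal/gain) + N(0, read_sd)},
#' rounded to integer ADU. Deterministic given the scene's seed.
#'
#' Channels: \code{FISH} (mRNAs + TS), \code{IF} (spindle primitives, plus
#' bottom-slide debris when \code{artifacts$debris}), \code{DAPI} (nuclear
#' blobs), \code{DIC} (single-plane cell-edge proxy, shifted by
#' \code{artifacts$dicOffset}).
#'
#' @param scene a \linkS4class{Scene}.
#' @param channel one of \code{"FISH"}, \code{"IF"}, \code{"DAPI"},
#'   \code{"DIC"}.
#' @param noise logical; render camera noise (default) or the noiseless
#'   photon image plus offset.
#' @return An \linkS4class{ImageStack}.
#' @examples
#' sc <- sampleScene(scenarioParams(nCells = 2, fieldShape = c(21, 128, 128),
#'                                  seed = 3))
#' stk <- renderStack(sc, "FISH")
#' @export
renderStack <- function(scene, channel = c("FISH", "IF", "DAPI", "DIC"),
                        noise = TRUE) {
  channel <- match.arg(channel)
  p <- scene@params
  chIdx <- match(channel, c("FISH", "IF", "DAPI", "DIC"))
  .withSeed(.deriveSeed(p@seed, 100 + chIdx), {
    dims <- p@fieldShape
    if (channel == "DIC") return(.renderDIC(scene, noise))
    data <- array(0, dims)
    for (cc in scene@cells) {
      em <- switch(channel,
        FISH = {
          e <- cc$mrnas
          names(e)[names(e) == "Q"] <- "q"
          if (!is.null(cc$ts))
            e <- rbind(e, data.frame(x = cc$ts$x, y = cc$ts$y, z = cc$ts$z,
                                     q = cc$ts$Q))
          e
        },
        IF = cc$spindle,
        DAPI = data.frame(x = cc$nucleusCenter[1], y = cc$nucleusCenter[2],
                          z = cc$zc, q = p@dapiPhotons,
                          sigma_xy = 0.45 * cc$nucleusRadius,
                          sigma_z = 0.5 * cc$nucleusRadius))
      data <- .renderEmitters(data, em, p@voxelSize,
                              p@psfSigma["xy"], p@psfSigma["z"])
    }
    if (channel == "IF" && isTRUE(p@artifacts$debris)) {
      # antibody debris sits on the slide surface, i.e. the lowest planes
      nb <- 30L
      debris <- data.frame(
        x = runif(nb, 0, dims[3] * p@voxelSize[3]),
        y = runif(nb, 0, dims[2] * p@voxelSize[2]),
        z = runif(nb, 0.1 * p@voxelSize[1], 1.2 * p@voxelSize[1]),
        q = runif(nb, 2000, 12000),
        sigma_xy = runif(nb, 150, 500), sigma_z = rep(120, nb))
      data <- .renderEmitters(data, debris, p@voxelSize,
                              p@psfSigma["xy"], p@psfSigma["z"])
    }
    out <- if (noise) .applyCameraNoise(data, p@noise)
           else data + p@noise["offset"]
    imageStack(out, p@voxelSize, channel, scene@positionId)
  })
}

# Single-plane DIC proxy: cell boundaries rasterized into an edge map,
# lightly blurred, with the configured systematic DIC-vs-fluorescence offset.
.renderDIC <- function(scene, noise = TRUE) {
  p <- scene@params
  dims <- p@fieldShape
  dy <- p@voxelSize[2]; dx <- p@voxelSize[3]
  img <- matrix(0, dims[2], dims[3])
  for (cc in scene@cells) {
    poly <- cc$polygon
    n <- nrow(poly)
    nxt <- c(2:n, 1)
    for (e in seq_len(n)) {
      len <- sqrt(sum((poly[nxt[e], ] - poly[e, ])^2))
      m <- max(2L, ceiling(len / dx))
      tt <- seq(0, 1, length.out = m)
      xs <- round((poly[e, 1] + tt * (poly[nxt[e], 1] - poly[e, 1])) / dx + 0.5)
      ys <- round((poly[e, 2] + tt * (poly[nxt[e], 2] - poly[e, 2])) / dy + 0.5)
      ok <- xs >= 1 & xs <= dims[3] & ys >= 1 & ys <= dims[2]
      img[cbind(ys[ok], xs[ok])] <- 300
    }
  }
  arr <- array(img, c(1L, dims[2], dims[3]))
  k <- .gaussKernel1d(1)
  arr <- cpp_gauss_blur3d(arr, dim(arr), .gaussKernel1d(1e-6), k, k)
  off <- p@artifacts$dicOffset
  if (any(off != 0)) arr[1, , ] <- .shiftBilinear(arr[1, , ], off[1], off[2])
  out <- if (noise) {
    v <- p@noise["offset"] + arr +
      rnorm(length(arr), 0, max(p@noise["read_sd"], 1))
    array(pmin(pmax(round(v), 0), 65535), dim(arr))
  } else arr + p@noise["offset"]
  imageStack(out, p@voxelSize, "DIC", scene@positionId)
}

# Bilinear translation of a matrix by (dy, dx) pixels; out-of-field -> 0.
.shiftBilinear <- function(mat, dy, dx) {
  ny <- nrow(mat); nx <- ncol(mat)
  yi <- matrix(seq_len(ny), ny, nx) - dy
  xi <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - dx
  y0 <- floor(yi); x0 <- floor(xi)
  fy <- yi - y0; fx <- xi - x0
  get <- function(y, x) {
    ok <- y >= 1 & y <= ny & x >= 1 & x <= nx
    v <- numeric(length(y))
    v[ok] <- mat[cbind(y[ok], x[ok])]
    v
  }
  v <- (1 - fy) * (1 - fx) * get(y0, x0) +
       (1 - fy) * fx * get(y0, x0 + 1) +
       fy * (1 - fx) * get(y0 + 1, x0) +
       fy * fx * get(y0 + 1, x0 + 1)
  matrix(v, ny, nx)
}

#' Inject a linear per-plane drift into a stack
#'
#' Translates plane \code{k} (0-based) by \code{k * driftPerPlane} pixels
#' using bilinear interpolation with zero fill, emulating the axial-drift
#' artifact seen when a bubble in the immersion oil moves during z-stack
#' acquisition. Used to exercise the drift QC.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param driftPerPlane \code{(dy, dx)} pixels per plane.
#' @return the drifted \linkS4class{ImageStack}.
#' @examples
#' s <- imageStack(array(runif(5 * 16 * 16), c(5, 16, 16)))
#' identical(stackData(injectZDrift(s, c(0, 0))), stackData(s))
#' @export
injectZDrift <- function(stack, driftPerPlane) {
  stopifnot(length(driftPerPlane) == 2L, all(is.finite(driftPerPlane)))
  if (all(driftPerPlane == 0)) return(stack)
  d <- stack@data
  for (k in seq_len(dim(d)[1])[-1]) {
    d[k, , ] <- .shiftBilinear(d[k, , ], (k - 1) * driftPerPlane[1],
                               (k - 1) * driftPerPlane[2])
  }
  imageStack(d, stack@voxelSize, stack@channel, stack@positionId)
}
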