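#' @useDynLib SpotQuant, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats pnorm dnorm qpois ppois rpois rnorm rbinom rnbinom runif
#'   median mad quantile sd lm coef uniroot fft mvfft cor complete.cases
#' @importFrom utils read.csv write.csv head
#' @importFrom grDevices chull
#' @importFrom graphics hist
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Multichannel 3D image stack
#'
#' A 3D fluorescence (or single-plane transmitted-light) image with its voxel
#' geometry. Data are stored as an array with dimensions \code{(nz, ny, nx)}
#' in camera counts (ADU). Voxel sizes are in nanometres, ordered
#' \code{(dz, dy, dx)}; the default geometry is 41 z-planes spaced 200 nm with
#' a 64.5 nm lateral pixel (6.45 um camera pixel behind a 100x objective).
#'
#' Continuous coordinates follow the convention that voxel \code{i} (1-based R
#' index) spans \code{[(i-1)*d, i*d)} nm along its axis, with centre
#' \code{(i-0.5)*d}.
#'
#' @slot data numeric 3D array, \code{(nz, ny, nx)}, finite and non-negative.
#' @slot voxelSize numeric length-3, \code{(dz, dy, dx)} in nm, all positive.
#' @slot channel one of \code{"FISH"}, \code{"IF"}, \code{"DAPI"},
#'   \code{"DIC"}. DIC stacks must have a single plane.
#' @slot positionId character tag identifying the stage position.
#' @export
setClass("ImageStack",
  representation(data = "array", voxelSize = "numeric",
                 channel = "character", positionId = "character"))

setValidity("ImageStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array (nz, ny, nx)")
  if (!all(is.finite(d))) return("data must be finite")
  if (any(d < 0)) return("data must be non-negative")
  v <- object@voxelSize
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    return("voxelSize must be three positive values (dz, dy, dx) in nm")
  if (!object@channel %in% c("FISH", "IF", "DAPI", "DIC"))
    return("channel must be one of FISH, IF, DAPI, DIC")
  if (object@channel == "DIC" && dim(d)[1] != 1L)
    return("DIC stacks must have nz = 1")
  TRUE
})

#' Construct an ImageStack
#'
#' @param data 3D array \code{(nz, ny, nx)} of intensities (ADU).
#' @param voxelSize \code{(dz, dy, dx)} in nm.
#' @param channel channel tag.
#' @param positionId stage-position identifier.
#' @return An \linkS4class{ImageStack}.
#' @examples
#' s <- imageStack(array(0, c(5, 8, 8)))
#' dim(stackData(s))
#' @export
imageStack <- function(data, voxelSize = c(200, 64.5, 64.5),
                       channel = "FISH", positionId = "pos_01") {
  new("ImageStack", data = data,
      voxelSize = as.numeric(voxelSize),
      channel = channel, positionId = positionId)
}

#' @describeIn imageStack the intensity array.
#' @param x,object an \code{ImageStack}.
#' @export
stackData <- function(x) x@data

#' @describeIn imageStack voxel size \code{(dz, dy, dx)} in nm.
#' @export
voxelSize <- function(x) x@voxelSize

#' @describeIn imageStack channel tag.
#' @export
channelName <- function(x) x@channel

#' @describeIn imageStack stage-position identifier.
#' @export
positionId <- function(x) x@positionId

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack [%s] %s: %d z x %d y x %d x voxels, %g/%g/%g nm\n",
              object@channel, object@positionId, d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  cat(sprintf("  intensity range [%.1f, %.1f] ADU\n",
              min(object@data), max(object@data)))
})

#' Oligonucleotide probe set
#'
#' An ordered set of single-labelled DNA probes tiling one transcript.
#' Sequences are lowercase and restricted to the alphabet \code{a,c,g,t}.
#'
#' @slot probes character vector of probe sequences.
#' @slot name name of the probe set.
#' @export
setClass("ProbeSet", representation(probes = "character", name = "character"))

setValidity("ProbeSet", function(object) {
  if (length(object@probes) == 0L) return("probe set must be non-empty")
  bad <- grepl("[^acgt]", object@probes)
  if (any(bad))
    return(sprintf("probe %d contains characters outside a,c,g,t",
                   which(bad)[1]))
  TRUE
})

#' Cell outline
#'
#' Cell (and optionally nucleus) boundary polygon of one segmented cell, in
#' lateral pixel units. Polygons are implicitly closed (last vertex connects
#' back to the first) and use 0-based continuous pixel coordinates: vertex
#' coordinate \code{u} corresponds to \code{u * dx} nm.
#'
#' @slot cellId cell identifier.
#' @slot cell n x 2 matrix of (x, y) vertices, at least 3, simple polygon.
#' @slot nucleus optional n x 2 matrix of nucleus (x, y) vertices.
#' @slot group cell-cycle scoring label (\code{G1,S,G2,M,unscored}).
#' @slot positionId stage-position identifier.
#' @export
setClass("CellOutline",
  representation(cellId = "character", cell = "matrix",
                 nucleus = "matrixOrNULL", group = "character",
                 positionId = "character"))

setValidity("CellOutline", function(object) {
  if (nrow(object@cell) < 3L) return("cell polygon needs at least 3 vertices")
  if (ncol(object@cell) != 2L) return("cell polygon must be n x 2 (x, y)")
  if (!is.null(object@nucleus)) {
    if (nrow(object@nucleus) < 3L)
      return("nucleus polygon needs at least 3 vertices")
    if (ncol(object@nucleus) != 2L)
      return("nucleus polygon must be n x 2 (x, y)")
  }
  if (!object@group %in% c("G1", "S", "G2", "M", "unscored"))
    return("group must be one of G1, S, G2, M, unscored")
  TRUE
})

#' Construct a CellOutline
#'
#' @param cellId identifier.
#' @param cell n x 2 matrix of (x, y) vertices in pixels.
#' @param nucleus optional n x 2 matrix of nucleus vertices.
#' @param group scoring label, default \code{"unscored"}.
#' @param positionId stage-position identifier.
#' @return A \linkS4class{CellOutline}.
#' @export
cellOutline <- function(cellId, cell, nucleus = NULL, group = "unscored",
                        positionId = "pos_01") {
  new("CellOutline", cellId = as.character(cellId),
      cell = unname(as.matrix(cell)),
      nucleus = if (is.null(nucleus)) NULL else unname(as.matrix(nucleus)),
      group = group, positionId = positionId)
}

setMethod("show", "CellOutline", function(object) {
  cat(sprintf("CellOutline %s (%s): %d vertices%s, group %s\n",
              object@cellId, object@positionId, nrow(object@cell),
              if (is.null(object@nucleus)) "" else
                sprintf(" + nucleus (%d)", nrow(object@nucleus)),
              object@group))
})

#' Spot detection settings
#'
#' All tunable parameters of the detection chain: difference-of-Gaussians
#' filter widths, pre-detection threshold, candidate separation, fit window
#' and acceptance bounds for the fitted parameters.
#'
#' @slot filterSigma named numeric: \code{small_xy}, \code{large_xy} (pixels),
#'   \code{small_z}, \code{large_z} (planes); small < large per axis.
#' @slot predetectThreshold ADU threshold on the filtered stack; \code{NA}
#'   means automatic (median + \code{thresholdFactor} * MAD of the unclipped
#'   band-pass response).
#' @slot thresholdFactor multiplier for the automatic threshold.
#' @slot minSeparation minimal candidate separation in pixels.
#' @slot fitWindow odd window size \code{(wz, wy, wx)} in voxels.
#' @slot acceptBounds named list of \code{c(min, max)} for \code{sigma_xy},
#'   \code{sigma_z} (nm), \code{amplitude} (ADU) and \code{Q} (ADU voxel).
#' @slot tsFactor a transcription site must exceed this multiple of the
#'   single-molecule reference intensity.
#' @slot maxTS maximum transcription sites kept per cell.
#' @slot voxelSize \code{(dz, dy, dx)} nm.
#' @slot extra named character vector of unknown keys preserved from file.
#' @export
setClass("DetectionSettings",
  representation(filterSigma = "numeric", predetectThreshold = "numeric",
                 thresholdFactor = "numeric", minSeparation = "numeric",
                 fitWindow = "integer", acceptBounds = "list",
                 tsFactor = "numeric", maxTS = "integer",
                 voxelSize = "numeric", extra = "character"))

setValidity("DetectionSettings", function(object) {
  fs <- object@filterSigma
  need <- c("small_xy", "large_xy", "small_z", "large_z")
  if (!all(need %in% names(fs))) return("filterSigma needs small/large xy/z")
  if (fs["small_xy"] >= fs["large_xy"] || fs["small_z"] >= fs["large_z"])
    return("filter sigma_small must be < sigma_large per axis")
  if (any(fs <= 0)) return("filter sigmas must be positive")
  if (length(object@fitWindow) != 3L || any(object@fitWindow %% 2L != 1L))
    return("fitWindow must be three odd sizes (wz, wy, wx)")
  need <- c("sigma_xy", "sigma_z", "amplitude", "Q")
  if (!all(need %in% names(object@acceptBounds)))
    return("acceptBounds needs sigma_xy, sigma_z, amplitude, Q")
  for (nm in need) {
    b <- object@acceptBounds[[nm]]
    if (length(b) != 2L || b[1] > b[2])
      return(sprintf("acceptBounds$%s must be c(min, max) with min <= max", nm))
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive values")
  if (object@minSeparation <= 0) return("minSeparation must be positive")
  TRUE
})

#' Construct detection settings
#'
#' Defaults correspond to widefield yeast smFISH at 64.5 nm lateral pixel and
#' 200 nm plane spacing: band-pass 1/5 px laterally and 0.5/2.5 planes
#' axially, a 15 x 15 x 11 voxel fit window (about +/- 3 PSF sigma), lateral
#' width bounds 50-400 nm and axial 150-1000 nm.
#'
#' @param filterSigma named numeric of band-pass widths.
#' @param predetectThreshold ADU, or \code{NA} for automatic.
#' @param thresholdFactor MAD multiplier for the automatic threshold.
#' @param minSeparation minimal candidate separation, pixels.
#' @param fitWindow odd \code{(wz, wy, wx)} window.
#' @param acceptBounds named list of \code{c(min, max)} acceptance bounds.
#' @param tsFactor transcription-site brightness factor over a single mRNA.
#' @param maxTS maximum transcription sites per cell (haploid default 1).
#' @param voxelSize \code{(dz, dy, dx)} nm.
#' @return A \linkS4class{DetectionSettings}.
#' @examples
#' detectionSettings()
#' @export
detectionSettings <- function(
    filterSigma = c(small_xy = 1, large_xy = 5, small_z = 0.5, large_z = 2.5),
    predetectThreshold = NA_real_,
    thresholdFactor = 8,
    minSeparation = 3,
    fitWindow = c(11L, 15L, 15L),
    acceptBounds = list(sigma_xy = c(50, 400), sigma_z = c(150, 1000),
                        amplitude = c(0, Inf), Q = c(0, Inf)),
    tsFactor = 1.5,
    maxTS = 1L,
    voxelSize = c(200, 64.5, 64.5)) {
  new("DetectionSettings", filterSigma = filterSigma,
      predetectThreshold = as.numeric(predetectThreshold),
      thresholdFactor = thresholdFactor,
      minSeparation = minSeparation,
      fitWindow = as.integer(fitWindow),
      acceptBounds = acceptBounds, tsFactor = tsFactor,
      maxTS = as.integer(maxTS), voxelSize = as.numeric(voxelSize),
      extra = character(0))
}

setMethod("show", "DetectionSettings", function(object) {
  fs <- object@filterSigma
  cat("DetectionSettings\n")
  cat(sprintf("  band-pass sigma xy %g/%g px, z %g/%g planes\n",
              fs["small_xy"], fs["large_xy"], fs["small_z"], fs["large_z"]))
  cat(sprintf("  predetect threshold: %s (factor %g), min separation %g px\n",
              ifelse(is.na(object@predetectThreshold), "auto",
                     format(object@predetectThreshold)),
              object@thresholdFactor, object@minSeparation))
  cat(sprintf("  fit window %s voxels, TS factor %g, max TS/cell %d\n",
              paste(object@fitWindow, collapse = "x"), object@tsFactor,
              object@maxTS))
})

#' Table of fitted spots
#'
#' One row per fitted candidate. Columns: \code{x,y,z} (nm), \code{amplitude},
#' \code{background} (ADU), \code{sigma_xy}, \code{sigma_z} (nm), \code{Q}
#' (integrated intensity, ADU voxel), \code{residual_rms}, \code{converged},
#' \code{cropped}, \code{accepted}, \code{reject_reason}.
#'
#' @slot positionId stage position the spots come from.
#' @slot spots data.frame of fits.
#' @slot settings the \linkS4class{DetectionSettings} snapshot used.
#' @slot histograms list with \code{Q} histograms of the accepted and
#'   rejected populations (as returned by \code{\link[graphics]{hist}},
#'   uncomputed until \code{\link{filterSpots}} runs).
#' @export
setClass("SpotTable",
  representation(positionId = "character", spots = "data.frame",
                 settings = "DetectionSettings", histograms = "list"))

setValidity("SpotTable", function(object) {
  sp <- object@spots
  need <- c("x", "y", "z", "amplitude", "background", "sigma_xy", "sigma_z",
            "Q", "residual_rms", "converged", "cropped", "accepted",
            "reject_reason")
  if (nrow(sp) > 0 && !all(need %in% names(sp)))
    return("spots is missing required columns")
  if (nrow(sp) > 0 && any(sp$accepted & !sp$converged, na.rm = TRUE))
    return("accepted spots must be a subset of converged spots")
  TRUE
})

#' Accessors for SpotTable
#'
#' @param x a \linkS4class{SpotTable}.
#' @return \code{spotFits}: the full data.frame of fits;
#'   \code{acceptedSpots}: only the accepted rows.
#' @export
spotFits <- function(x) x@spots

#' @rdname spotFits
#' @export
acceptedSpots <- function(x) x@spots[which(x@spots$accepted), , drop = FALSE]

setMethod("show", "SpotTable", function(object) {
  sp <- object@spots
  cat(sprintf("SpotTable %s: %d fits, %d converged, %d accepted\n",
              object@positionId, nrow(sp), sum(sp$converged),
              sum(sp$accepted, na.rm = TRUE)))
})

#' Averaged single-molecule image
#'
#' The voxel-wise mean of background-subtracted, re-centred windows around all
#' accepted single-molecule detections, together with its 3D Gaussian refit
#' and the two single-mRNA reference-intensity estimators.
#'
#' @slot avgStack small 3D array (fit window) centred on the consensus
#'   molecule.
#' @slot nContributing number of spots averaged.
#' @slot fit one-row data.frame: Gaussian refit of the averaged image.
#' @slot residualStack array of refit residuals (same shape as avgStack).
#' @slot QRef reference integrated intensity from the refit (ADU voxel).
#' @slot QRefRobust median of the per-spot integrated intensities.
#' @export
setClass("AvgMolecule",
  representation(avgStack = "array", nContributing = "integer",
                 fit = "data.frame", residualStack = "array",
                 QRef = "numeric", QRefRobust = "numeric"))

setValidity("AvgMolecule", function(object) {
  if (object@nContributing < 1L) return("nContributing must be >= 1")
  if (object@QRef <= 0 || object@QRefRobust <= 0)
    return("reference intensities must be positive")
  TRUE
})

setMethod("show", "AvgMolecule", function(object) {
  cat(sprintf(
    "AvgMolecule: %d spots averaged, Q_ref(fit) = %.1f, Q_ref(robust) = %.1f\n",
    object@nContributing, object@QRef, object@QRefRobust))
})

#' Synthetic scene parameters
#'
#' Study conditions for the ground-truth generator. Defaults emulate the
#' deposited experiments: 41 z-planes at 200 nm, 64.5 nm lateral pixels,
#' negative-binomial mature counts with mean 10.1 mRNAs per expressing cell,
#' zero-truncated-Poisson nascent counts with mean 3.6 RNAs per transcription
#' site, and per-molecule brightness from binomial occupancy of a 48-probe
#' set.
#'
#' @slot nCells number of cells in the scene.
#' @slot fieldShape \code{(nz, ny, nx)} voxels.
#' @slot voxelSize \code{(dz, dy, dx)} nm.
#' @slot phaseFractions named simplex over \code{G1, S, G2, M}.
#' @slot expressingFractionG1 probability that a G1 cell expresses.
#' @slot tsFraction probability an expressing cell shows a transcription site.
#' @slot matureMean negative-binomial mean, mRNAs per expressing cell.
#' @slot matureDispersion negative-binomial size parameter.
#' @slot nascentMean zero-truncated-Poisson mean, RNAs per TS.
#' @slot nProbes probes per transcript.
#' @slot pBind per-probe binding probability.
#' @slot qProbe ADU voxel contributed by one bound probe.
#' @slot psfSigma \code{(xy, z)} PSF widths in nm.
#' @slot noise named numeric \code{gain}, \code{offset}, \code{read_sd}.
#' @slot cellRadius \code{(mean, sd)} mother-cell radius in nm.
#' @slot cellThicknessFactor cell z-extent as a multiple of the diameter.
#' @slot ifPhotons named per-phase integrated IF brightness (ADU voxel).
#' @slot ifCV lognormal coefficient of variation of the IF brightness.
#' @slot dapiPhotons integrated DAPI brightness per nucleus.
#' @slot artifacts list: \code{zDrift} (dy, dx px/plane), \code{dicOffset}
#'   (dy, dx px), \code{debris} (logical, IF bottom-slide debris).
#' @slot seed integer random seed.
#' @export
setClass("ScenarioParams",
  representation(nCells = "integer", fieldShape = "integer",
                 voxelSize = "numeric", phaseFractions = "numeric",
                 expressingFractionG1 = "numeric", tsFraction = "numeric",
                 matureMean = "numeric", matureDispersion = "numeric",
                 nascentMean = "numeric", nProbes = "integer",
                 pBind = "numeric", qProbe = "numeric", psfSigma = "numeric",
                 noise = "numeric", cellRadius = "numeric",
                 cellThicknessFactor = "numeric", ifPhotons = "numeric",
                 ifCV = "numeric", dapiPhotons = "numeric",
                 artifacts = "list", seed = "integer"))

setValidity("ScenarioParams", function(object) {
  pf <- object@phaseFractions
  if (!all(c("G1", "S", "G2", "M") %in% names(pf)))
    return("phaseFractions must be named G1, S, G2, M")
  if (abs(sum(pf) - 1) > 1e-9) return("phaseFractions must sum to 1")
  if (any(pf < 0)) return("phaseFractions must be non-negative")
  if (object@nCells < 0L) return("nCells must be >= 0")
  if (any(object@fieldShape <= 0L)) return("fieldShape must be positive")
  if (object@matureMean <= 0 || object@matureDispersion <= 0 ||
      object@nascentMean <= 0)
    return("count means and dispersion must be positive")
  if (object@expressingFractionG1 < 0 || object@expressingFractionG1 > 1 ||
      object@tsFraction < 0 || object@tsFraction > 1 ||
      object@pBind < 0 || object@pBind > 1)
    return("probabilities must lie in [0, 1]")
  if (!all(c("gain", "offset", "read_sd") %in% names(object@noise)))
    return("noise must be named gain, offset, read_sd")
  TRUE
})

#' Construct scenario parameters
#'
#' @param nCells cells per scene (one stage position).
#' @param fieldShape \code{(nz, ny, nx)} voxels.
#' @param voxelSize \code{(dz, dy, dx)} nm.
#' @param phaseFractions named simplex over the four phases.
#' @param expressingFractionG1 fraction of G1 cells that express.
#' @param tsFraction fraction of expressing cells with an active
#'   transcription site.
#' @param matureMean,matureDispersion negative-binomial mean/size of the
#'   mature count per expressing cell.
#' @param nascentMean zero-truncated-Poisson mean nascent RNAs per TS.
#' @param nProbes,pBind,qProbe probe-binding brightness model: per-molecule
#'   integrated intensity is \code{qProbe * Binomial(nProbes, pBind)}.
#' @param psfSigma \code{(xy, z)} Gaussian PSF widths, nm.
#' @param noise camera model \code{gain}, \code{offset}, \code{read_sd}.
#' @param cellRadius \code{(mean, sd)} mother radius, nm.
#' @param cellThicknessFactor z-extent as a multiple of the cell diameter.
#' @param ifPhotons per-phase IF integrated brightness.
#' @param ifCV lognormal CV of IF brightness.
#' @param dapiPhotons DAPI integrated brightness per nucleus.
#' @param artifacts list \code{zDrift}, \code{dicOffset}, \code{debris}.
#' @param seed integer seed; scenes and renders are deterministic given it.
#' @return A \linkS4class{ScenarioParams}.
#' @examples
#' p <- scenarioParams(nCells = 4, seed = 1)
#' @export
scenarioParams <- function(
    nCells = 25L,
    fieldShape = c(41L, 512L, 512L),
    voxelSize = c(200, 64.5, 64.5),
    phaseFractions = c(G1 = 0.40, S = 0.25, G2 = 0.20, M = 0.15),
    expressingFractionG1 = 0.5,
    tsFraction = 154 / 688,
    matureMean = 10.1,
    matureDispersion = 1.3,
    nascentMean = 3.6,
    nProbes = 48L,
    pBind = 0.8,
    qProbe = 500,
    psfSigma = c(xy = 130, z = 350),
    noise = c(gain = 2, offset = 100, read_sd = 3),
    cellRadius = c(mean = 1450, sd = 120),
    cellThicknessFactor = 1.0,
    ifPhotons = c(G1 = 6000, S = 12000, G2 = 20000, M = 30000),
    ifCV = 0.15,
    dapiPhotons = 60000,
    artifacts = list(zDrift = c(0, 0), dicOffset = c(0, 0), debris = FALSE),
    seed = 1L) {
  new("ScenarioParams", nCells = as.integer(nCells),
      fieldShape = as.integer(fieldShape), voxelSize = as.numeric(voxelSize),
      phaseFractions = phaseFractions,
      expressingFractionG1 = expressingFractionG1, tsFraction = tsFraction,
      matureMean = matureMean, matureDispersion = matureDispersion,
      nascentMean = nascentMean, nProbes = as.integer(nProbes), pBind = pBind,
      qProbe = qProbe, psfSigma = psfSigma, noise = noise,
      cellRadius = cellRadius, cellThicknessFactor = cellThicknessFactor,
      ifPhotons = ifPhotons, ifCV = ifCV, dapiPhotons = dapiPhotons,
      artifacts = artifacts, seed = as.integer(seed))
}

#' Ground-truth scene
#'
#' World description produced by \code{\link{sampleScene}}: per-cell polygons
#' (in nm), phase, mRNA positions and brightnesses, optional transcription
#' site and spindle-like IF primitives.
#'
#' @slot cells list of per-cell truth records.
#' @slot params the \linkS4class{ScenarioParams} used.
#' @slot positionId stage-position identifier.
#' @export
setClass("Scene",
  representation(cells = "list", params = "ScenarioParams",
                 positionId = "character"))

setMethod("show", "Scene", function(object) {
  n <- length(object@cells)
  nexpr <- sum(vapply(object@cells, function(cc) nrow(cc$mrnas) > 0 ||
                        !is.null(cc$ts), logical(1)))
  nts <- sum(vapply(object@cells, function(cc) !is.null(cc$ts), logical(1)))
  cat(sprintf("Scene %s: %d cells (%d expressing, %d with TS)\n",
              object@positionId, n, nexpr, nts))
})

#' @describeIn scenarioParams number of cells in a scene or parameter object.
#' @param x a \code{Scene} or \code{ScenarioParams}.
#' @export
nCells <- function(x) {
  if (is(x, "Scene")) length(x@cells) else x@nCells
}

#' @describeIn sampleScene list of per-cell ground-truth records.
#' @export
sceneCells <- function(scene) scene@cells

#' @describeIn sampleScene the generating parameters.
#' @export
sceneParams <- function(scene) scene@params
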