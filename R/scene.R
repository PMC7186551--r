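# Ground-truth scene generation: cell geometry, count laws, brightness model.

# Evaluate expr with a temporary RNG state so generation is deterministic
# given a seed and never disturbs the caller's stream.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

# Derived per-position / per-channel seeds, kept below 2^31.
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(k)) %% 2147483629)
}

#' Zero-truncated Poisson law from its mean
#'
#' Solves for the underlying Poisson rate \code{lambda} such that the
#' zero-truncated mean \code{lambda / (1 - exp(-lambda))} equals \code{m},
#' and returns the first two moments.
#'
#' @param m target zero-truncated mean (> 1).
#' @return list with \code{lambda}, \code{mean}, \code{sd}.
#' @examples
#' ztpFromMean(3.6)
#' @export
ztpFromMean <- function(m) {
  stopifnot(m > 1)
  lambda <- uniroot(function(l) l / (1 - exp(-l)) - m,
                    c(1e-9, m + 10), tol = 1e-12)$root
  mu <- lambda / (1 - exp(-lambda))
  ex2 <- lambda * (lambda + 1) / (1 - exp(-lambda))
  list(lambda = lambda, mean = mu, sd = sqrt(ex2 - mu^2))
}

.rztp <- function(n, lambda) {
  if (n == 0L) return(integer(0))
  u <- runif(n, exp(-lambda), 1)
  qpois(u, lambda)
}

# Mature mRNA count law for expressing cells.
.rMature <- function(n, mean, dispersion) {
  rnbinom(n, mu = mean, size = dispersion)
}

# Per-molecule integrated brightness: binomial probe occupancy.
.rBrightness <- function(n, nProbes, pBind, qProbe) {
  qProbe * rbinom(n, nProbes, pBind)
}

# ---- cell shapes ------------------------------------------------------------

# Area of the union of two circles at centre distance d.
.twoCircleUnionArea <- function(R1, R2, d) {
  if (d >= R1 + R2) return(pi * R1^2 + pi * R2^2)
  if (d <= abs(R1 - R2)) return(pi * max(R1, R2)^2)
  a1 <- acos((d^2 + R1^2 - R2^2) / (2 * d * R1))
  a2 <- acos((d^2 + R2^2 - R1^2) / (2 * d * R2))
  lens <- R1^2 * (a1 - sin(2 * a1) / 2) + R2^2 * (a2 - sin(2 * a2) / 2)
  pi * R1^2 + pi * R2^2 - lens
}

# Bud radius achieving a target bud/mother area ratio, with the bud centre
# at d = R1 + R2 / 2.
.solveBudRadius <- function(R1, ratio) {
  f <- function(R2) {
    (.twoCircleUnionArea(R1, R2, R1 + R2 / 2) - pi * R1^2) / (pi * R1^2) -
      ratio
  }
  uniroot(f, c(0.02 * R1, 1.3 * R1), tol = 1e-6 * R1)$root
}

# Boundary polygon of the union of mother circle (centre 0,0, radius R1) and
# bud circle (centre d along theta0, radius R2), traversed CCW.
.budPolygon <- function(R1, R2, d, theta0, step = pi / 60) {
  a1 <- acos((d^2 + R1^2 - R2^2) / (2 * d * R1))
  a2 <- acos((d^2 + R2^2 - R1^2) / (2 * d * R2))
  th1 <- seq(theta0 + a1, theta0 + 2 * pi - a1,
             length.out = max(8L, ceiling((2 * pi - 2 * a1) / step)))
  arc1 <- cbind(R1 * cos(th1), R1 * sin(th1))
  half2 <- pi - a2
  th2 <- seq(theta0 - half2, theta0 + half2,
             length.out = max(6L, ceiling(2 * half2 / step)))
  cx <- d * cos(theta0); cy <- d * sin(theta0)
  arc2 <- cbind(cx + R2 * cos(th2), cy + R2 * sin(th2))
  rbind(arc1, arc2)
}

# Slightly irregular circle for round (G1) cells.
.roundPolygon <- function(R1, nArc = 96L) {
  ph <- runif(2, 0, 2 * pi)
  amp <- runif(2, 0.005, 0.02)
  th <- seq(0, 2 * pi, length.out = nArc + 1L)[-(nArc + 1L)]
  r <- R1 * (1 + amp[1] * sin(2 * th + ph[1]) + amp[2] * sin(3 * th + ph[2]))
  cbind(r * cos(th), r * sin(th))
}

# One cell shape (centred at origin, nm units). Returns polygon, nucleus,
# truth features and a bounding radius used for packing.
.makeCellShape <- function(phase, R1) {
  theta0 <- runif(1, 0, 2 * pi)
  budRatio <- switch(phase,
    G1 = 0,
    S  = runif(1, 0.10, 0.22),
    G2 = runif(1, 0.42, 0.62),
    M  = runif(1, 0.55, 0.75))
  if (budRatio == 0) {
    poly <- .roundPolygon(R1)
    bound <- 1.04 * R1
    R2 <- 0; d <- 0
  } else {
    R2 <- .solveBudRadius(R1, budRatio)
    d <- R1 + R2 / 2
    poly <- .budPolygon(R1, R2, d, theta0)
    bound <- d + R2
  }
  nucR <- 0.38 * R1
  nucOff <- runif(1, 0, 0.18 * R1)
  nucDir <- theta0 + pi + runif(1, -0.6, 0.6)  # keep nucleus in the mother
  nucC <- c(nucOff * cos(nucDir), nucOff * sin(nucDir))
  th <- seq(0, 2 * pi, length.out = 41L)[-41L]
  nucleus <- cbind(nucC[1] + nucR * cos(th), nucC[2] + nucR * sin(th))
  # per-lobe disks (cell-local) used for overlap-free packing
  disks <- cbind(cx = 0, cy = 0, r = 1.04 * R1)
  if (budRatio > 0)
    disks <- rbind(disks, c(d * cos(theta0), d * sin(theta0), R2))
  list(poly = poly, nucleus = nucleus, nucleusCenter = nucC,
       nucleusRadius = nucR, budRatio = budRatio, budDir = theta0,
       R1 = R1, R2 = R2, budDist = d, bound = bound, disks = disks)
}

# Spindle-like IF primitives for one cell (emitter list, nm, relative to the
# cell centre). Foci carry 60% of the photons, the connecting bar 40%.
.makeSpindle <- function(phase, shape, photons, psfSigma) {
  nc <- shape$nucleusCenter
  sxy <- psfSigma["xy"] * 1.2
  sz <- psfSigma["z"] * 1.2
  mkEm <- function(x, y, q) data.frame(x = x, y = y, q = q)
  if (phase == "G1") {
    a <- runif(1, 0, 2 * pi)
    em <- mkEm(nc[1] + 0.9 * shape$nucleusRadius * cos(a),
               nc[2] + 0.9 * shape$nucleusRadius * sin(a), photons)
    span <- 0
  } else {
    span <- switch(phase,
      S  = runif(1, 300, 600),
      G2 = runif(1, 900, 1400),
      M  = runif(1, 2600, 3600))
    dir <- shape$budDir
    mid <- if (phase == "M") {
      c(shape$budDist / 2 * cos(dir), shape$budDist / 2 * sin(dir))
    } else nc
    e1 <- mid - span / 2 * c(cos(dir), sin(dir))
    e2 <- mid + span / 2 * c(cos(dir), sin(dir))
    fociQ <- if (phase == "S") photons else 0.6 * photons
    em <- mkEm(c(e1[1], e2[1]), c(e1[2], e2[2]), rep(fociQ / 2, 2))
    if (phase != "S") {
      nBar <- if (phase == "M") 15L else 7L
      tt <- seq(0.1, 0.9, length.out = nBar)
      em <- rbind(em, mkEm(e1[1] + tt * (e2[1] - e1[1]),
                           e1[2] + tt * (e2[2] - e1[2]),
                           rep(0.4 * photons / nBar, nBar)))
    }
    span <- span
  }
  em$sigma_xy <- sxy
  em$sigma_z <- sz
  list(emitters = em, span = span)
}

# ---- scene sampling ---------------------------------------------------------

#' Sample a ground-truth scene
#'
#' Draws one stage position: cell shapes and phases, which G1 cells express,
#' mature mRNA counts (negative binomial), nascent transcription-site counts
#' (zero-truncated Poisson), per-molecule brightness (binomial probe
#' occupancy) and spindle-like IF structures. Deterministic given
#' \code{params@seed}.
#'
#' Mature mRNAs are placed uniformly over the cytoplasm (cell polygon minus
#' nucleus); the transcription site, when present, is uniform over the
#' nucleus. Cells are packed without overlap by rejection sampling; an
#' infeasible request errors after bounded retries.
#'
#' @param params a \linkS4class{ScenarioParams}.
#' @param positionId identifier for the rendered stage position.
#' @return A \linkS4class{Scene}.
#' @examples
#' sc <- sampleScene(scenarioParams(nCells = 3, fieldShape = c(41, 200, 200),
#'                                  seed = 7))
#' nCells(sc)
#' @export
sampleScene <- function(params, positionId = "pos_01") {
  validObject(params)
  .withSeed(params@seed, {
    n <- params@nCells
    if (n == 0L)
      return(new("Scene", cells = list(), params = params,
                 positionId = positionId))
    dz <- params@voxelSize[1]; dy <- params@voxelSize[2]
    dx <- params@voxelSize[3]
    fieldZ <- params@fieldShape[1] * dz
    fieldY <- params@fieldShape[2] * dy
    fieldX <- params@fieldShape[3] * dx

    phases <- sample(names(params@phaseFractions), n, replace = TRUE,
                     prob = params@phaseFractions)
    R1 <- pmax(rnorm(n, params@cellRadius["mean"], params@cellRadius["sd"]),
               0.6 * params@cellRadius["mean"])
    shapes <- lapply(seq_len(n), function(i) .makeCellShape(phases[i], R1[i]))
    ord <- order(vapply(shapes, `[[`, numeric(1), "bound"),
                 decreasing = TRUE)
    phases <- phases[ord]; R1 <- R1[ord]; shapes <- shapes[ord]

    # non-overlapping placement, largest cells first; overlap is tested
    # between the per-lobe disks, so budded shapes pack tightly
    pad <- 2 * dx
    centers <- matrix(NA_real_, n, 2)
    bounds <- vapply(shapes, `[[`, numeric(1), "bound")
    placedDisks <- matrix(numeric(0), 0, 3)
    for (i in seq_len(n)) {
      m <- bounds[i] + pad
      if (2 * m >= min(fieldX, fieldY))
        stop("field too small for requested cells")
      dsk <- shapes[[i]]$disks
      placed <- FALSE
      for (att in seq_len(500L)) {
        cx <- runif(1, m, fieldX - m); cy <- runif(1, m, fieldY - m)
        cand <- cbind(dsk[, 1] + cx, dsk[, 2] + cy, dsk[, 3])
        ok <- TRUE
        if (nrow(placedDisks) > 0) {
          for (k in seq_len(nrow(cand))) {
            dd <- sqrt((placedDisks[, 1] - cand[k, 1])^2 +
                       (placedDisks[, 2] - cand[k, 2])^2)
            if (any(dd < placedDisks[, 3] + cand[k, 3] + pad)) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) {
          centers[i, ] <- c(cx, cy)
          placedDisks <- rbind(placedDisks, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("unable to place cell %d of %d without overlap; ",
                     i, n), "reduce nCells or enlarge the field")
    }

    lawTS <- ztpFromMean(params@nascentMean)
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      sh <- shapes[[i]]
      poly <- sweep(sh$poly, 2, centers[i, ], "+")
      nuc <- sweep(sh$nucleus, 2, centers[i, ], "+")
      thick <- params@cellThicknessFactor * 2 * R1[i]
      zc <- runif(1, 0.40, 0.55) * fieldZ
      expressing <- phases[i] == "G1" &&
        runif(1) < params@expressingFractionG1
      nMature <- if (expressing)
        .rMature(1, params@matureMean, params@matureDispersion) else 0L
      mr <- if (nMature > 0) {
        xy <- .sampleInPolygon(nMature, poly, exclude = nuc)
        data.frame(x = xy[, 1], y = xy[, 2],
                   z = runif(nMature, zc - thick / 2, zc + thick / 2),
                   Q = .rBrightness(nMature, params@nProbes, params@pBind,
                                    params@qProbe))
      } else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        Q = numeric(0))
      ts <- NULL
      if (expressing && runif(1) < params@tsFraction) {
        nn <- .rztp(1L, lawTS$lambda)
        xy <- .sampleInPolygon(1L, nuc)
        ts <- list(x = xy[1, 1], y = xy[1, 2],
                   z = zc + runif(1, -0.8, 0.8) * sh$nucleusRadius,
                   nascent_n = nn,
                   Q = sum(.rBrightness(nn, params@nProbes, params@pBind,
                                        params@qProbe)))
      }
      ifTotal <- params@ifPhotons[phases[i]] *
        exp(rnorm(1, 0, params@ifCV)) / exp(params@ifCV^2 / 2)
      sp <- .makeSpindle(phases[i], sh, ifTotal, params@psfSigma)
      spindle <- sp$emitters
      spindle$x <- spindle$x + centers[i, 1]
      spindle$y <- spindle$y + centers[i, 2]
      spindle$z <- zc + runif(nrow(spindle), -100, 100)
      cells[[i]] <- list(
        cellId = sprintf("cell_%03d", i), phase = phases[i],
        expressing = nMature > 0 || !is.null(ts),
        center = centers[i, ], polygon = poly, nucleus = nuc,
        nucleusCenter = centers[i, ] + sh$nucleusCenter,
        nucleusRadius = sh$nucleusRadius,
        zc = zc, thickness = thick, bound = sh$bound,
        mrnas = mr, ts = ts, spindle = spindle,
        ifTotal = unname(ifTotal), budRatio = sh$budRatio,
        spindleSpan = sp$span)
    }
    new("Scene", cells = cells, params = params, positionId = positionId)
  })
}

#' Ground-truth molecule table of a scene
#'
#' One row per molecule: cytoplasmic mRNAs (\code{type = "mature"}) and
#' transcription sites (\code{type = "ts"}, with their nascent count).
#' Coordinates in nm, brightness in ADU voxel.
#'
#' @param scene a \linkS4class{Scene}.
#' @return data.frame with \code{cell_id}, \code{phase}, \code{type},
#'   \code{x}, \code{y}, \code{z}, \code{Q_true}, \code{nascent_n}.
#' @export
sceneTruth <- function(scene) {
  rows <- lapply(scene@cells, function(cc) {
    out <- NULL
    if (nrow(cc$mrnas) > 0)
      out <- data.frame(cell_id = cc$cellId, phase = cc$phase,
                        type = "mature", x = cc$mrnas$x, y = cc$mrnas$y,
                        z = cc$mrnas$z, Q_true = cc$mrnas$Q,
                        nascent_n = NA_integer_)
    if (!is.null(cc$ts))
      out <- rbind(out, data.frame(cell_id = cc$cellId, phase = cc$phase,
                                   type = "ts", x = cc$ts$x, y = cc$ts$y,
                                   z = cc$ts$z, Q_true = cc$ts$Q,
                                   nascent_n = cc$ts$nascent_n))
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = character(0), phase = character(0),
                      type = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), Q_true = numeric(0),
                      nascent_n = integer(0))
  rownames(out) <- NULL
  out
}

#' Per-cell ground truth of a scene
#'
#' @param scene a \linkS4class{Scene}.
#' @return data.frame with one row per cell: phase, expressing flag, mature
#'   and nascent counts, bud-area ratio, spindle span (nm) and total IF
#'   brightness.
#' @export
sceneCellTruth <- function(scene) {
  do.call(rbind, lapply(scene@cells, function(cc) {
    data.frame(cell_id = cc$cellId, phase = cc$phase,
               expressing = cc$expressing, n_mature = nrow(cc$mrnas),
               n_nascent = if (is.null(cc$ts)) 0L else cc$ts$nascent_n,
               bud_ratio = cc$budRatio, spindle_span = cc$spindleSpan,
               if_total = cc$ifTotal)
  }))
}

#' Cell outlines of a scene, in pixel units
#'
#' Converts the scene's nm polygons to the 0-based lateral pixel coordinates
#' used by outline files and downstream assignment.
#'
#' @param scene a \linkS4class{Scene}.
#' @param group one of \code{"phase"} (truth labels) or \code{"unscored"}.
#' @return list of \linkS4class{CellOutline}.
#' @export
sceneOutlines <- function(scene, group = c("phase", "unscored")) {
  group <- match.arg(group)
  dy <- scene@params@voxelSize[2]; dx <- scene@params@voxelSize[3]
  lapply(scene@cells, function(cc) {
    cellOutline(cc$cellId,
                cbind(cc$polygon[, 1] / dx, cc$polygon[, 2] / dy),
                nucleus = cbind(cc$nucleus[, 1] / dx, cc$nucleus[, 2] / dy),
                group = if (group == "phase") cc$phase else "unscored",
                positionId = scene@positionId)
  })
}

#' Write the truth table of a scene to CSV
#'
#' @param scene a \linkS4class{Scene}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTruthTable <- function(scene, path) {
  write.csv(sceneTruth(scene), path, row.names = FALSE)
  invisible(path)
}

#' Simulate a cohort of stage positions
#'
#' Splits a requested total cell count over stage positions of
#' \code{params@nCells} cells each, with per-position seeds derived from
#' \code{seed}.
#'
#' @param params \linkS4class{ScenarioParams} for one position.
#' @param nCellsTotal total number of cells across positions.
#' @param seed cohort seed.
#' @return list of \linkS4class{Scene}.
#' @export
simulateCohort <- function(params, nCellsTotal, seed = params@seed) {
  per <- params@nCells
  nPos <- ceiling(nCellsTotal / per)
  lapply(seq_len(nPos), function(i) {
    p <- params
    p@seed <- .deriveSeed(seed, i)
    p@nCells <- as.integer(min(per, nCellsTotal - (i - 1L) * per))
    sampleScene(p, positionId = sprintf("pos_%02d", i))
  })
}
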