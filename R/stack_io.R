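# File dialects: multi-page grayscale TIFF stacks, outline coordinate text
# files, key=value detection-settings files, cell-cycle scoring CSV.

#' Read and write multi-page TIFF stacks
#'
#' Stacks are stored as 16-bit grayscale multi-page TIFF, one page per
#' z-plane (z = page order). \code{writeStack} rounds to integer ADU (camera
#' counts are integers; rendered stacks already are) and errors if values
#' exceed the 16-bit range, so a write-read round trip is bit-identical.
#'
#' @param path TIFF file path.
#' @param voxelSize,channel,positionId metadata attached to the stack on
#'   read (TIFF pages carry no calibrated geometry in this dialect).
#' @return \code{readStack}: an \linkS4class{ImageStack};
#'   \code{writeStack}: the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' s <- imageStack(array(round(runif(4 * 8 * 8, 0, 1000)), c(4, 8, 8)))
#' writeStack(s, f)
#' identical(stackData(readStack(f)), stackData(s))
#' @export
readStack <- function(path, voxelSize = c(200, 64.5, 64.5),
                      channel = "FISH", positionId = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0L) stop("TIFF file has no pages: ", path)
  if (length(dim(pages[[1]])) != 2L)
    stop("expected grayscale TIFF, got multi-channel pages: ", path)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, c(length(pages), ny, nx))
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]]), c(ny, nx)))
      stop("TIFF pages have inconsistent dimensions: ", path)
    data[k, , ] <- pages[[k]]
  }
  if (is.na(positionId))
    positionId <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  imageStack(data, voxelSize, channel, positionId)
}

#' @rdname readStack
#' @param stack an \linkS4class{ImageStack} to write.
#' @export
writeStack <- function(stack, path) {
  d <- round(stack@data)
  if (max(d) > 65535) stop("stack exceeds the 16-bit range")
  pages <- lapply(seq_len(dim(d)[1]), function(k) d[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Maximal intensity projection over a plane range
#'
#' Per-pixel maximum over an inclusive interval of z-planes, the standard
#' projection over the planes where the cells are located.
#'
#' @param stack an \linkS4class{ImageStack}.
#' @param zRange inclusive 1-based plane interval \code{c(z1, z2)}; default
#'   all planes.
#' @return an ny x nx matrix.
#' @examples
#' s <- imageStack(array(runif(5 * 8 * 8), c(5, 8, 8)))
#' p <- maxProject(s, c(2, 4))
#' @export
maxProject <- function(stack, zRange = NULL) {
  nz <- dim(stack@data)[1]
  if (is.null(zRange)) zRange <- c(1L, nz)
  z1 <- zRange[1]; z2 <- zRange[2]
  if (z1 > z2 || z1 < 1 || z2 > nz)
    stop(sprintf("empty or out-of-range z interval [%d, %d] for %d planes",
                 z1, z2, nz))
  Reduce(pmax, lapply(z1:z2, function(k) stack@data[k, , ]))
}

# ---- outline files ----------------------------------------------------------

#' Read and write cell-outline coordinate files
#'
#' Block-structured text dialect mirroring segmentation-export outline files:
#' a \code{CELL <id>} line opens a block, followed by tab-separated
#' \code{X_POS} and \code{Y_POS} vertex lines, an optional \code{Nucleus}
#' sub-block with its own \code{X_POS}/\code{Y_POS}, and an optional
#' \code{GROUP <label>} line. Unknown header lines are skipped, trailing
#' whitespace and blank lines are ignored. A nucleus falling outside its cell
#' polygon is flagged with a warning, not an error.
#'
#' @param path outline file path.
#' @param positionId position tag attached to the outlines.
#' @return \code{readOutlines}: list of \linkS4class{CellOutline};
#'   \code{writeOutlines}: the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' o <- cellOutline("c1", cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' writeOutlines(list(o), f)
#' length(readOutlines(f))
#' @export
readOutlines <- function(path, positionId = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (is.na(positionId)) positionId <- sub("__outline.*$", "", basename(path))
  outlines <- list()
  i <- 1L
  parseVec <- function(line, lineNo) {
    parts <- strsplit(sub("^[XY]_POS\\t?", "", line), "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(parts[nzchar(parts)]))
    if (length(v) == 0L || any(is.na(v)))
      stop(sprintf("unparseable coordinate line %d in %s", lineNo, path))
    v
  }
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^CELL\\b", ln)) {
      id <- sub("^CELL\\s+", "", ln)
      xs <- ys <- NULL; nxs <- nys <- NULL; group <- "unscored"
      inNucleus <- FALSE
      i <- i + 1L
      while (i <= length(lines) && !grepl("^CELL\\b", lines[i])) {
        l2 <- lines[i]
        if (grepl("^X_POS", l2)) {
          if (inNucleus) nxs <- parseVec(l2, i) else xs <- parseVec(l2, i)
        } else if (grepl("^Y_POS", l2)) {
          if (inNucleus) nys <- parseVec(l2, i) else ys <- parseVec(l2, i)
        } else if (grepl("^Nucleus\\b", l2, ignore.case = TRUE)) {
          inNucleus <- TRUE
        } else if (grepl("^GROUP\\b", l2)) {
          group <- sub("^GROUP\\s+", "", l2)
        }
        # unknown keys are skipped (tolerant reader)
        i <- i + 1L
      }
      if (is.null(xs) || is.null(ys) || length(xs) != length(ys))
        stop(sprintf("cell block '%s' in %s lacks matching X_POS/Y_POS",
                     id, path))
      nucleus <- NULL
      if (!is.null(nxs)) {
        if (is.null(nys) || length(nxs) != length(nys))
          stop(sprintf("nucleus block of '%s' in %s lacks matching vertices",
                       id, path))
        nucleus <- cbind(nxs, nys)
      }
      out <- cellOutline(id, cbind(xs, ys), nucleus = nucleus,
                         group = group, positionId = positionId)
      if (!is.null(nucleus) && !.polyInside(nucleus, out@cell))
        warning(sprintf("nucleus of cell '%s' extends outside the cell", id))
      outlines[[length(outlines) + 1L]] <- out
    } else {
      i <- i + 1L
    }
  }
  outlines
}

#' @rdname readOutlines
#' @param outlines list of \linkS4class{CellOutline} to write.
#' @export
writeOutlines <- function(outlines, path) {
  fmt <- function(v) paste(sprintf("%.10g", v), collapse = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("FISH_outline_file\tv1", con)
  for (o in outlines) {
    writeLines(sprintf("CELL %s", o@cellId), con)
    writeLines(paste0("X_POS\t", fmt(o@cell[, 1])), con)
    writeLines(paste0("Y_POS\t", fmt(o@cell[, 2])), con)
    if (!is.null(o@nucleus)) {
      writeLines("Nucleus", con)
      writeLines(paste0("X_POS\t", fmt(o@nucleus[, 1])), con)
      writeLines(paste0("Y_POS\t", fmt(o@nucleus[, 2])), con)
    }
    if (o@group != "unscored") writeLines(sprintf("GROUP %s", o@group), con)
  }
  invisible(path)
}

#' Count cells across outline files
#'
#' @param paths character vector of outline file paths.
#' @return total number of cell outlines.
#' @export
countOutlinedCells <- function(paths) {
  sum(vapply(paths, function(p) length(readOutlines(p)), integer(1)))
}

# ---- scoring CSV ------------------------------------------------------------

.scoringGroups <- c("G1", "S", "G2", "M", "unscored")

#' Read and write the cell-cycle scoring CSV
#'
#' The manual-scoring export: one row per scored cell with its stage
#' position, a click position (x, y in pixels) and the assigned cell-cycle
#' group.
#'
#' @param path CSV path.
#' @return \code{readScoringCsv}: data.frame with \code{position_id},
#'   \code{x}, \code{y}, \code{group}.
#' @export
readScoringCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("position_id", "x", "y", "group")
  if (!all(need %in% names(df)))
    stop("scoring CSV must have columns: ", paste(need, collapse = ", "))
  bad <- !df$group %in% .scoringGroups
  if (any(bad))
    stop(sprintf("unknown scoring group '%s'; allowed: %s",
                 df$group[which(bad)[1]],
                 paste(.scoringGroups, collapse = ", ")))
  df[need]
}

#' @rdname readScoringCsv
#' @param scoring data.frame as returned by \code{readScoringCsv}.
#' @export
writeScoringCsv <- function(scoring, path) {
  stopifnot(all(scoring$group %in% .scoringGroups))
  write.csv(scoring[c("position_id", "x", "y", "group")], path,
            row.names = FALSE)
  invisible(path)
}

#' Match scoring rows to cell outlines
#'
#' Each scored click is assigned to the outline polygon containing it
#' (same position; smallest containing polygon wins on overlap). Unmatched
#' rows are reported with \code{cell_id = NA}.
#'
#' @param scoring data.frame from \code{\link{readScoringCsv}}.
#' @param outlines list of \linkS4class{CellOutline}.
#' @return the scoring data.frame with a \code{cell_id} column added.
#' @export
matchScoringToOutlines <- function(scoring, outlines) {
  areas <- vapply(outlines, function(o) .polyArea(o@cell), numeric(1))
  ord <- order(areas)
  scoring$cell_id <- NA_character_
  for (i in seq_len(nrow(scoring))) {
    for (j in ord) {
      o <- outlines[[j]]
      if (o@positionId != scoring$position_id[i]) next
      if (pointInPolygon(scoring$x[i], scoring$y[i], o@cell)) {
        scoring$cell_id[i] <- o@cellId
        break
      }
    }
  }
  scoring
}

# ---- settings files ---------------------------------------------------------

.settingsKeys <- c("sigma_small_xy", "sigma_large_xy", "sigma_small_z",
                   "sigma_large_z", "predetect_threshold", "threshold_factor",
                   "min_separation", "fit_window_z", "fit_window_y",
                   "fit_window_x", "sigma_xy_min", "sigma_xy_max",
                   "sigma_z_min", "sigma_z_max", "amplitude_min",
                   "amplitude_max", "Q_min", "Q_max", "ts_factor", "max_ts",
                   "voxel_dz", "voxel_dy", "voxel_dx")

#' Read and write detection-settings text files
#'
#' \code{key=value} text; unknown keys are preserved verbatim through a
#' read-write round trip. A missing mandatory key raises an error naming it.
#'
#' @param path settings file path.
#' @return \code{readSettings}: a \linkS4class{DetectionSettings};
#'   \code{writeSettings}: the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeSettings(detectionSettings(), f)
#' readSettings(f)
#' @export
readSettings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  keys <- vapply(kv, function(m) if (length(m) == 3) m[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(m) if (length(m) == 3) m[3] else NA_character_,
                 character(1))
  ok <- !is.na(keys)
  keys <- keys[ok]; vals <- vals[ok]
  missing <- setdiff(.settingsKeys, keys)
  if (length(missing) > 0)
    stop("settings file is missing mandatory key(s): ",
         paste(missing, collapse = ", "))
  num <- function(k) {
    v <- vals[match(k, keys)]
    if (identical(v, "auto") || identical(v, "NA")) NA_real_
    else if (identical(v, "Inf")) Inf
    else as.numeric(v)
  }
  s <- detectionSettings(
    filterSigma = c(small_xy = num("sigma_small_xy"),
                    large_xy = num("sigma_large_xy"),
                    small_z = num("sigma_small_z"),
                    large_z = num("sigma_large_z")),
    predetectThreshold = num("predetect_threshold"),
    thresholdFactor = num("threshold_factor"),
    minSeparation = num("min_separation"),
    fitWindow = c(num("fit_window_z"), num("fit_window_y"),
                  num("fit_window_x")),
    acceptBounds = list(
      sigma_xy = c(num("sigma_xy_min"), num("sigma_xy_max")),
      sigma_z = c(num("sigma_z_min"), num("sigma_z_max")),
      amplitude = c(num("amplitude_min"), num("amplitude_max")),
      Q = c(num("Q_min"), num("Q_max"))),
    tsFactor = num("ts_factor"),
    maxTS = num("max_ts"),
    voxelSize = c(num("voxel_dz"), num("voxel_dy"), num("voxel_dx")))
  extraKeys <- setdiff(keys, .settingsKeys)
  s@extra <- stats::setNames(vals[match(extraKeys, keys)], extraKeys)
  validObject(s)
  s
}

#' @rdname readSettings
#' @param settings a \linkS4class{DetectionSettings} to write.
#' @export
writeSettings <- function(settings, path) {
  fs <- settings@filterSigma
  ab <- settings@acceptBounds
  fmtv <- function(x) {
    if (is.na(x)) "auto" else sprintf("%.10g", x)
  }
  vals <- c(sigma_small_xy = fmtv(fs["small_xy"]),
            sigma_large_xy = fmtv(fs["large_xy"]),
            sigma_small_z = fmtv(fs["small_z"]),
            sigma_large_z = fmtv(fs["large_z"]),
            predetect_threshold = fmtv(settings@predetectThreshold),
            threshold_factor = fmtv(settings@thresholdFactor),
            min_separation = fmtv(settings@minSeparation),
            fit_window_z = fmtv(settings@fitWindow[1]),
            fit_window_y = fmtv(settings@fitWindow[2]),
            fit_window_x = fmtv(settings@fitWindow[3]),
            sigma_xy_min = fmtv(ab$sigma_xy[1]),
            sigma_xy_max = fmtv(ab$sigma_xy[2]),
            sigma_z_min = fmtv(ab$sigma_z[1]),
            sigma_z_max = fmtv(ab$sigma_z[2]),
            amplitude_min = fmtv(ab$amplitude[1]),
            amplitude_max = fmtv(ab$amplitude[2]),
            Q_min = fmtv(ab$Q[1]), Q_max = fmtv(ab$Q[2]),
            ts_factor = fmtv(settings@tsFactor),
            max_ts = fmtv(settings@maxTS),
            voxel_dz = fmtv(settings@voxelSize[1]),
            voxel_dy = fmtv(settings@voxelSize[2]),
            voxel_dx = fmtv(settings@voxelSize[3]))
  vals <- c(vals, settings@extra)
  writeLines(paste0(names(vals), "=", vals), path)
  invisible(path)
}
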