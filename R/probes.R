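#' Parse a probe-sequence list into a ProbeSet
#'
#' Accepts comma- and/or newline-separated DNA sequences (lowercase
#' \code{acgt}); whitespace around tokens is stripped and lines starting with
#' \code{#} are ignored. Tokens with characters outside the alphabet raise an
#' error naming the offending token index.
#'
#' @param rawText character scalar (or vector of lines) with the sequences,
#'   or the path of a text file when \code{file = TRUE}.
#' @param name name for the probe set.
#' @param file if \code{TRUE}, \code{rawText} is a file path.
#' @return A \linkS4class{ProbeSet}.
#' @examples
#' ps <- makeProbeSet("acgt, ttgatgacgagtcccatacg")
#' length(probeSequences(ps))
#' probeLengths(ps)
#' @export
makeProbeSet <- function(rawText, name = "probe_set", file = FALSE) {
  if (file) rawText <- readLines(rawText, warn = FALSE)
  txt <- paste(rawText, collapse = "\n")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*#", lines)]
  tokens <- unlist(strsplit(paste(lines, collapse = ","), ",", fixed = TRUE))
  tokens <- gsub("\\s+", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    stop("no probe sequences found in input")
  bad <- grepl("[^acgt]", tokens)
  if (any(bad))
    stop(sprintf("probe token %d ('%s') contains characters outside a,c,g,t",
                 which(bad)[1], tokens[which(bad)[1]]))
  new("ProbeSet", probes = tokens, name = name)
}

#' @describeIn makeProbeSet the probe sequences, in input order.
#' @param x a \code{ProbeSet}.
#' @export
probeSequences <- function(x) x@probes

#' @describeIn makeProbeSet per-probe length table (integer vector named by
#'   probe index).
#' @export
probeLengths <- function(x) {
  stats::setNames(nchar(x@probes), seq_along(x@probes))
}

setMethod("show", "ProbeSet", function(object) {
  len <- nchar(object@probes)
  cat(sprintf("ProbeSet '%s': %d probes, lengths %d-%d nt (median %g)\n",
              object@name, length(object@probes), min(len), max(len),
              stats::median(len)))
})

setMethod("length", "ProbeSet", function(x) length(x@probes))

#' Validate a probe set against the expected uniform length
#'
#' Singly-labelled smFISH probe sets are designed at a uniform length
#' (typically 20 nt). This reports, without correcting, any probe whose
#' length deviates from the modal length, e.g. a truncated sequence in a
#' published probe list.
#'
#' @param probeSet a \linkS4class{ProbeSet}.
#' @return data.frame with columns \code{index}, \code{sequence},
#'   \code{length}, \code{flagged} (TRUE when the length differs from the
#'   modal length).
#' @examples
#' ps <- makeProbeSet("acgtacgtacgt, acgtacgtacg, gtcagtcagtca")
#' subset(validateProbeSet(ps), flagged)
#' @export
validateProbeSet <- function(probeSet) {
  len <- nchar(probeSet@probes)
  tab <- table(len)
  modal <- as.integer(names(tab)[which.max(tab)])
  data.frame(index = seq_along(len), sequence = probeSet@probes,
             length = len, flagged = len != modal)
}
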