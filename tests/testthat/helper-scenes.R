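# Shared fixtures: all synthetic, generated in code.

# A scene with exactly one molecule at a known position/brightness, inside a
# single round cell. Used for forward-model oracles and localization studies.
oneSpotScene <- function(seed = 5, Q = 19200,
                         pos = c(x = 2065.3, y = 2001.7, z = 4100),
                         field = c(41L, 64L, 64L), radius = 1100) {
  p <- scenarioParams(nCells = 1, fieldShape = field, seed = seed,
                      phaseFractions = c(G1 = 1, S = 0, G2 = 0, M = 0),
                      cellRadius = c(mean = radius, sd = 1))
  sc <- sampleScene(p)
  cc <- sceneCells(sc)[[1]]
  cc$mrnas <- data.frame(x = pos[["x"]], y = pos[["y"]], z = pos[["z"]],
                         Q = Q)
  cc$ts <- NULL
  sc@cells <- list(cc)
  sc
}

# Parameters for a sparse 100-spot detection field: one giant round cell
# filling most of the field, no transcription sites.
spotFieldParams <- function(seed, nSpots = 100) {
  scenarioParams(nCells = 1, fieldShape = c(41L, 256L, 256L), seed = seed,
                 phaseFractions = c(G1 = 1, S = 0, G2 = 0, M = 0),
                 expressingFractionG1 = 1, tsFraction = 0,
                 matureMean = nSpots, matureDispersion = 1e8,
                 cellRadius = c(mean = 6200, sd = 1),
                 cellThicknessFactor = 0.37)
}

# Small all-G1 expressing scene parameters for sparse single-molecule work.
sparseSceneParams <- function(seed, nCells = 10, matureMean = 4,
                              field = c(41L, 320L, 320L), qProbe = 500) {
  scenarioParams(nCells = nCells, fieldShape = field, seed = seed,
                 phaseFractions = c(G1 = 1, S = 0, G2 = 0, M = 0),
                 expressingFractionG1 = 1, tsFraction = 0,
                 matureMean = matureMean, qProbe = qProbe)
}
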