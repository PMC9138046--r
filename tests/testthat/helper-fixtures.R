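# Shared fixtures. Heavy objects are memoized so the default abandonment
# experiment is simulated once per test run.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# Small single-country grid with deterministic climate (no interannual
# noise) used by most model-level tests.
smallWorld <- function(years = 1990:1999, nLat = 5L, nLon = 5L, seed = 11L) {
  grid <- genGrid(nLat, nLon, latRange = c(48, 58), lonRange = c(30, 50),
                  nCountries = 1L, seed = seed)
  forcing <- genClimate(grid, years, seed = seed + 1L, tNoiseSd = 0, pNoiseCv = 0)
  clima <- climatology(forcing)
  list(grid = grid, forcing = forcing, clima = clima,
       clim = climSummary(clima),
       crop = genHydeLike(grid, years, seed = seed + 2L))
}

# A one-row PFT parameter table for hand-built flux tests.
grassParams <- function(resp_frac = 0.5) {
  p <- defaultPFTParams()["coldgrass", ]
  p$resp_frac <- resp_frac
  p$a_leaf <- 0.5; p$a_froot <- 0.5
  p
}

# Spun-up small world (memoized).
smallSpinup <- function() {
  memo("smallSpinup", {
    w <- smallWorld()
    sp <- spinUp(w$grid, w$crop@fraction[, , 1], w$clima, maxIters = 300L)
    list(world = w, spinup = sp)
  })
}

# The default synthetic abandonment experiment: full pipeline at the
# package's default configuration and seed (memoized; used by the
# acceptance suite).
defaultExperiment <- function() {
  memo("defaultExperiment", {
    runPipeline(defaultPipelineConfig(seed = 1L),
                outDir = file.path(tempdir(), "accept-pipeline"),
                quiet = TRUE)
  })
}
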