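# Land-use transitions, initial cover/state construction, and secondary
# succession on abandoned cropland.

PFT_BROADLEAF <- 1L; PFT_NEEDLELEAF <- 2L
PFT_COLDGRASS <- 3L; PFT_WARMGRASS <- 4L; PFT_CROP <- 5L

# Mix a PFT's pool densities when area with zero biomass is added: the new
# density is the area-weighted mean, conserving cover * density exactly.
diluteDensity <- function(veg, pft, oldCover, addArea) {
  newCover <- oldCover + addArea
  w <- ifelse(newCover > 0, oldCover / pmax(newCover, 1e-300), 0)
  veg[, pft, ] <- veg[, pft, ] * w
  veg
}

#' Initial carbon and cover state
#'
#' Prescribes cropland from a fraction field; the remaining land gets a
#' natural partition: on forest-suitable cells a forest share (broadleaf or
#' needleleaf by mean annual temperature) plus grass and a little bare
#' ground; on unsuitable (steppe) cells grass and bare ground only. Pools
#' start from small seed values and are equilibrated by [spinUp()].
#'
#' @param grid a [LandGrid-class].
#' @param cropFrac per-cell cropland fraction (vector, or matrix
#'   `[nlat, nlon]`).
#' @param clim climate summary from [climSummary()].
#' @param params model parameter list.
#' @return A [CarbonState-class].
#' @export
initialState <- function(grid, cropFrac, clim, params = defaultModelParams()) {
  n <- nCells(grid)
  land <- as.vector(grid@landMask)
  crop <- pmin(pmax(as.vector(cropFrac), 0), 1)
  crop[!land] <- 0
  cover <- matrix(0, n, 5L)
  cover[, PFT_CROP] <- crop
  rest <- pmax(1 - crop, 0)
  suit <- clim$suitableForest & land
  warm <- clim$warmGrass
  broad <- clim$treePft == PFT_BROADLEAF
  fFor <- ifelse(suit, params$initForest, 0)
  fGrass <- ifelse(suit, params$initGrassSuit, params$initGrassUnsuit)
  fBare <- 1 - fFor - fGrass
  cover[, PFT_BROADLEAF] <- rest * fFor * as.numeric(broad) * land
  cover[, PFT_NEEDLELEAF] <- rest * fFor * as.numeric(!broad) * land
  cover[, PFT_COLDGRASS] <- rest * fGrass * as.numeric(!warm) * land
  cover[, PFT_WARMGRASS] <- rest * fGrass * as.numeric(warm) * land
  bare <- 1 - rowSums(cover)
  bare[!land] <- 1
  veg <- array(0, c(n, 5L, 5L))
  for (p in 1:5) {
    seedPools <- if (p <= 2) c(0.15, 0.15, 0.4, 0.8, 1.5) else c(0.08, 0.08, 0, 0, 0)
    for (k in 1:5) veg[land, p, k] <- seedPools[k]
  }
  litter <- matrix(0, n, 2L)
  litter[land, 1] <- 0.15; litter[land, 2] <- 0.25
  soil <- matrix(0, n, 3L)
  soil[land, 1] <- 0.3; soil[land, 2] <- 1.0; soil[land, 3] <- 5.0
  dec <- ifelse(land, 0.05, 0)
  methods::new("CarbonState", grid = grid, veg = veg, litter = litter,
               decomposer = dec, soil = soil, product = numeric(n),
               cover = cover, bare = bare,
               abnGrass = matrix(0, n, 2L), abnTree = numeric(n),
               age = numeric(n), soilWater = rep(params$wcap / 2, n) * land)
}

#' Apply a prescribed cropland change to a cell state
#'
#' Abandonment (cropland shrinking): the vacated fraction's crop biomass
#' moves, area-weighted, into the litter pools; the area becomes grass (cold
#' or warm by mean annual temperature) in the abandonment year and its
#' succession age restarts at zero. Expansion (cropland growing): area is
#' taken proportionally from natural PFTs and bare ground, and the cleared
#' biomass moves entirely into litter. Carbon is conserved exactly at the
#' cell level; emissions occur only through subsequent decomposition (a
#' configurable `burnFrac` releases part of the cleared biomass immediately;
#' default 0).
#'
#' @param state a [CarbonState-class].
#' @param newCrop target per-cell cropland fraction (vector in `[0, 1]`).
#' @param clim climate summary from [climSummary()].
#' @param params model parameter list.
#' @return list with `state` (updated), `transfer` (per-cell carbon moved to
#'   litter, kgC m-2) and `burned` (per-cell carbon released immediately).
#' @export
applyLandUse <- function(state, newCrop, clim, params = defaultModelParams()) {
  n <- nCells(state)
  land <- as.vector(state@grid@landMask)
  newCrop <- pmin(pmax(as.vector(newCrop), 0), 1)
  newCrop[!land] <- 0
  cover <- state@cover; bare <- state@bare; veg <- state@veg
  litter <- state@litter
  transfer <- numeric(n); burned <- numeric(n)
  keep <- 1 - params$burnFrac

  delta <- newCrop - cover[, PFT_CROP]
  ab <- pmax(-delta, 0)    # abandoned fraction
  ex <- pmax(delta, 0)     # expansion fraction

  # --- abandonment: crop biomass -> litter, area -> grass; the succession
  # age of the cell's abandoned pool is the area-weighted mix of the old
  # cohort and the new (age-0) area, so incremental abandonment does not
  # wipe out prior succession progress
  if (any(ab > 0)) {
    met <- ab * (veg[, PFT_CROP, 1] + veg[, PFT_CROP, 2])
    str <- ab * (veg[, PFT_CROP, 3] + veg[, PFT_CROP, 4] + veg[, PFT_CROP, 5])
    litter[, 1] <- litter[, 1] + keep * met
    litter[, 2] <- litter[, 2] + keep * str
    burned <- burned + params$burnFrac * (met + str)
    transfer <- transfer + keep * (met + str)
    cover[, PFT_CROP] <- cover[, PFT_CROP] - ab
    oldAbn <- rowSums(state@abnGrass) + state@abnTree
    gi <- ifelse(clim$warmGrass, PFT_WARMGRASS, PFT_COLDGRASS)
    for (g in c(PFT_COLDGRASS, PFT_WARMGRASS)) {
      add <- ifelse(gi == g, ab, 0)
      veg <- diluteDensity(veg, g, cover[, g], add)
      cover[, g] <- cover[, g] + add
      state@abnGrass[, g - 2L] <- state@abnGrass[, g - 2L] + add
    }
    state@age <- ifelse(oldAbn + ab > 0,
                        state@age * oldAbn / pmax(oldAbn + ab, 1e-300), state@age)
  }

  # --- expansion (re-cultivation): reclaim land in priority order --
  # abandoned grass first, then other grass, bare ground, and forest only
  # as a last resort; cleared biomass -> litter
  if (any(ex > 0)) {
    rem <- ex
    takeFrom <- function(avail, rem) pmin(pmax(avail, 0), rem)
    clearHost <- function(p, take) {
      metT <- take * (veg[, p, 1] + veg[, p, 2])
      strT <- take * (veg[, p, 3] + veg[, p, 4] + veg[, p, 5])
      litter[, 1] <<- litter[, 1] + keep * metT
      litter[, 2] <<- litter[, 2] + keep * strT
      burned <<- burned + params$burnFrac * (metT + strT)
      transfer <<- transfer + keep * (metT + strT)
      cover[, p] <<- cover[, p] - take
    }
    # 1-2: abandoned-origin grass (cold, warm)
    for (g in c(PFT_COLDGRASS, PFT_WARMGRASS)) {
      take <- takeFrom(pmin(state@abnGrass[, g - 2L], cover[, g]), rem)
      clearHost(g, take)
      state@abnGrass[, g - 2L] <- state@abnGrass[, g - 2L] - take
      rem <- rem - take
    }
    # 3-4: other grass
    for (g in c(PFT_COLDGRASS, PFT_WARMGRASS)) {
      take <- takeFrom(cover[, g], rem)
      clearHost(g, take)
      rem <- rem - take
    }
    # 5: bare ground (no biomass)
    take <- takeFrom(bare, rem)
    bare <- bare - take
    rem <- rem - take
    # 6: forest, proportionally over the two tree PFTs
    treeCov <- cover[, PFT_BROADLEAF] + cover[, PFT_NEEDLELEAF]
    take <- takeFrom(treeCov, rem)
    if (any(take > 0)) {
      w <- ifelse(treeCov > 0, take / pmax(treeCov, 1e-300), 0)
      for (p in c(PFT_BROADLEAF, PFT_NEEDLELEAF)) clearHost(p, cover[, p] * w)
      state@abnTree <- state@abnTree * (1 - w)
      rem <- rem - take
    }
    if (any(rem > 1e-9))
      stop("cropland expansion exceeds displaceable cover in some cell")
    veg <- diluteDensity(veg, PFT_CROP, cover[, PFT_CROP], ex)
    cover[, PFT_CROP] <- cover[, PFT_CROP] + ex
  }

  state@cover <- cover; state@bare <- bare; state@veg <- veg
  state@litter <- litter
  state@product <- state@product + burned  # burned C leaves via product ledger
  list(state = state, transfer = transfer, burned = burned)
}

#' Annual vegetation dynamics: secondary succession on abandoned land
#'
#' Succession ages advance by `dt` on cells carrying abandoned-origin
#' vegetation. Where the climate is forest-suitable and the pure-grassland
#' establishment lag has passed, abandoned grass converts to tree cover at
#' rate `1/tauSucc` (so a fully grassy suitable cell retains
#' `exp(-t/tauSucc)` grass after `t` years of conversion); the displaced
#' grass biomass enters metabolic litter and the new tree area starts from
#' zero biomass. On unsuitable cells abandoned area remains grass
#' indefinitely. Cropland cover is prescribed and never competed away;
#' without abandonment and with a stable climate the cover is a fixed point.
#'
#' @param state a [CarbonState-class].
#' @param clim climate summary from [climSummary()].
#' @param params model parameter list.
#' @param dt time step in years (default 1).
#' @return Updated [CarbonState-class].
#' @export
vegetationDynamics <- function(state, clim, params = defaultModelParams(), dt = 1) {
  hasAbn <- rowSums(state@abnGrass) + state@abnTree > 1e-12
  state@age[hasAbn] <- state@age[hasAbn] + dt
  convFrac <- 1 - exp(-dt / params$tauSucc)
  eligible <- clim$suitableForest & state@age > params$grassLag
  if (any(eligible)) {
    cover <- state@cover; veg <- state@veg
    for (g in c(PFT_COLDGRASS, PFT_WARMGRASS)) {
      conv <- ifelse(eligible, state@abnGrass[, g - 2L] * convFrac, 0)
      conv <- pmin(conv, cover[, g])
      if (!any(conv > 0)) next
      # displaced grass biomass to metabolic litter (grasses have no wood)
      state@litter[, 1] <- state@litter[, 1] + conv * (veg[, g, 1] + veg[, g, 2])
      state@litter[, 2] <- state@litter[, 2] +
        conv * (veg[, g, 3] + veg[, g, 4] + veg[, g, 5])
      cover[, g] <- cover[, g] - conv
      state@abnGrass[, g - 2L] <- state@abnGrass[, g - 2L] - conv
      for (tr in c(PFT_BROADLEAF, PFT_NEEDLELEAF)) {
        add <- ifelse(clim$treePft == tr, conv, 0)
        veg <- diluteDensity(veg, tr, cover[, tr], add)
        cover[, tr] <- cover[, tr] + add
      }
      state@abnTree <- state@abnTree + conv
    }
    state@cover <- cover; state@veg <- veg
  }
  if (any(abs(rowSums(state@cover) + state@bare - 1) > 1e-8))
    stop("cover fractions escaped the unit partition")
  state
}
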