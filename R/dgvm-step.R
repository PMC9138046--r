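# Annual model step: land use, twelve monthly flux steps, harvest, and
# vegetation dynamics, with exact carbon bookkeeping.

# Forcing for one year as per-cell matrices [nCell, 12].
yearForcing <- function(forcing, t) {
  n <- nCells(forcing@grid)
  list(temp = matrix(forcing@temp[, , , t], n, 12),
       precip = matrix(forcing@precip[, , , t], n, 12),
       par = matrix(forcing@par[, , , t], n, 12),
       co2 = forcing@co2[t])
}

#' Step the model through one year
#'
#' Order of operations: land-use transition to the year's cropland
#' fraction, then twelve monthly steps (soil-water balance, per-PFT
#' photosynthesis, allocation and turnover, decomposition), then the annual
#' crop harvest (remaining crop biomass split between export and metabolic
#' litter) and annual vegetation dynamics. The bookkeeping identity
#' `delta(vegetation + litter + decomposer + soil + product) = NPP - Rh`
#' holds to machine precision; the land-use operator on its own never
#' changes total carbon.
#'
#' @param state a [CarbonState-class].
#' @param yearF one year of forcing from `yearForcing()` or a
#'   [ClimateForcing-class] plus `t` index.
#' @param newCrop per-cell cropland fraction for the year.
#' @param clim climate summary from [climSummary()].
#' @param params model parameter list.
#' @param record if `TRUE`, also return monthly wetness and annual litter
#'   inputs (used by the semi-analytic spin-up).
#' @param t index of the year inside `yearF` when a [ClimateForcing-class]
#'   is supplied.
#' @return list with `state` and `diag`, the latter a list of per-cell
#'   annual fluxes (kgC m-2 yr-1): `gpp`, `npp`, `ra`, `rh`, `export`,
#'   `luccTransfer`, `nbp` (= npp - rh - export - burned).
#' @export
stepYear <- function(state, yearF, newCrop, clim, params = defaultModelParams(),
                     record = FALSE, t = 1L) {
  if (methods::is(yearF, "ClimateForcing")) yearF <- yearForcing(yearF, t)
  n <- nCells(state)
  dt <- 1 / 12
  lu <- applyLandUse(state, newCrop, clim, params)
  state <- lu$state
  gpp <- npp <- ra <- rh <- numeric(n)
  litterInMet <- litterInStr <- numeric(n)
  wetRec <- if (record) matrix(0, n, 12) else NULL
  pft <- params$pft
  for (m in 1:12) {
    sw <- soilWaterStep(state@soilWater, yearF$precip[, m], yearF$temp[, m], params)
    state@soilWater <- sw$water
    wet <- sw$wetness
    if (record) wetRec[, m] <- wet
    tm <- yearF$temp[, m]
    for (p in 1:5) {
      cov <- state@cover[, p]
      if (!any(cov > 0)) next
      pp <- pft[p, ]
      lai <- state@veg[, p, 1] * pp$sla
      g <- photosynthesis(tm, wet, yearF$par[, m], yearF$co2, lai, pp,
                          theta = params$theta, par0 = params$par0,
                          lai0 = params$lai0)
      al <- nppAllocate(g, state@veg[, p, ], pp, dt = dt)
      tv <- turnoverStep(al$pools, pp, dt)
      state@veg[, p, ] <- tv$pools
      gpp <- gpp + cov * g * dt
      npp <- npp + cov * al$npp * dt
      ra <- ra + cov * al$ra * dt
      state@litter[, 1] <- state@litter[, 1] + cov * tv$metabolic
      state@litter[, 2] <- state@litter[, 2] + cov * tv$structural
      litterInMet <- litterInMet + cov * tv$metabolic
      litterInStr <- litterInStr + cov * tv$structural
    }
    dc <- decomposeStep(state@litter, state@decomposer, state@soil,
                        tm, wet, params, dt)
    state@litter <- dc$litter; state@decomposer <- dc$decomposer
    state@soil <- dc$soil
    rh <- rh + dc$rh
  }
  # annual crop harvest: remaining crop biomass exported / returned
  cov <- state@cover[, PFT_CROP]
  harvDens <- state@veg[, PFT_CROP, 1] + state@veg[, PFT_CROP, 2] +
    state@veg[, PFT_CROP, 3] + state@veg[, PFT_CROP, 4] + state@veg[, PFT_CROP, 5]
  harvest <- cov * harvDens
  export <- params$harvestExport * harvest
  toLitter <- harvest - export
  state@litter[, 1] <- state@litter[, 1] + toLitter
  litterInMet <- litterInMet + toLitter
  state@product <- state@product + export
  state@veg[, PFT_CROP, ] <- 0
  state <- vegetationDynamics(state, clim, params, dt = 1)
  bad <- !is.finite(cellTrackedC(state))
  if (any(bad))
    stop(sprintf("non-finite carbon state in cell %d", which(bad)[1]))
  diag <- list(gpp = gpp, npp = npp, ra = ra, rh = rh, export = export,
               luccTransfer = lu$transfer, burned = lu$burned,
               nbp = npp - rh - export - lu$burned)
  if (record) {
    diag$wetness <- wetRec
    diag$litterInMet <- litterInMet
    diag$litterInStr <- litterInStr
  }
  list(state = state, diag = diag)
}

#' Regional aggregation of per-cell fields
#'
#' Converts a per-cell carbon density (kgC m-2) to GtC, or a per-cell
#' fraction to Mha, by summing `value * cellArea` over a mask.
#'
#' @param x per-cell vector, or `[nlat, nlon]` matrix.
#' @param grid a [LandGrid-class].
#' @param mask logical per-cell mask (default: land).
#' @param type `"carbon"` (GtC) or `"area"` (Mha).
#' @return scalar total.
#' @export
aggregateRegion <- function(x, grid, mask = NULL, type = c("carbon", "area")) {
  type <- match.arg(type)
  v <- as.vector(x)
  a <- as.vector(grid@cellArea)
  if (is.null(mask)) mask <- as.vector(grid@landMask)
  mask <- as.vector(mask)
  if (!any(mask)) return(0)
  s <- sum(v[mask] * a[mask])
  if (type == "carbon") s * 1e-12 else s * 1e-10
}

# Annual regional totals of a state (GtC / Mha), restricted to land.
regionTotals <- function(state, params) {
  g <- state@grid
  vegG <- aggregateRegion(cellVegC(state), g)
  soilG <- aggregateRegion(cellSoilC(state), g)
  c(biosphere_gtc = vegG + soilG,  # additivity holds exactly by construction
    veg_gtc = vegG,
    soil_gtc = soilG,
    product_gtc = aggregateRegion(state@product, g),
    forest_mha = aggregateRegion(rowSums(state@cover[, 1:2, drop = FALSE]), g, type = "area"),
    grass_mha = aggregateRegion(rowSums(state@cover[, 3:4, drop = FALSE]), g, type = "area"),
    crop_mha = aggregateRegion(state@cover[, 5], g, type = "area"),
    bare_mha = aggregateRegion(state@bare, g, type = "area"),
    abn_forest_mha = aggregateRegion(state@abnTree, g, type = "area"),
    abn_grass_mha = aggregateRegion(rowSums(state@abnGrass), g, type = "area"))
}
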