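# Three-scenario experiment, attribution by differencing, conversion ledger
# and difference maps.

#' Run one land-use scenario from a common starting state
#'
#' Steps the model through the forcing years, prescribing the cropland
#' fraction of `cropField` each year, and records annual regional totals.
#' The series includes a baseline row (year before the first simulated
#' year) holding the starting pools.
#'
#' @param state0 starting [CarbonState-class] (typically the spin-up state).
#' @param forcing transient [ClimateForcing-class].
#' @param cropField a [CroplandField-class] covering the forcing years.
#' @param params model parameter list.
#' @param scenario scenario id string.
#' @return A [ScenarioResult-class].
#' @export
runScenario <- function(state0, forcing, cropField, params = defaultModelParams(),
                        scenario = "default") {
  stopifnot(identical(forcing@years, cropField@years))
  clim <- climSummary(forcing, params)
  state <- state0
  rows <- vector("list", length(forcing@years) + 1L)
  tot0 <- regionTotals(state, params)
  rows[[1]] <- data.frame(year = forcing@years[1] - 1L, t(tot0),
                          npp_gtc = 0, rh_gtc = 0, export_gtc = 0, nbp_gtc = 0)
  for (t in seq_along(forcing@years)) {
    st <- stepYear(state, forcing, as.vector(cropField@fraction[, , t]),
                   clim, params, t = t)
    state <- st$state
    tot <- regionTotals(state, params)
    rows[[t + 1L]] <- data.frame(
      year = forcing@years[t], t(tot),
      npp_gtc = aggregateRegion(st$diag$npp, state@grid),
      rh_gtc = aggregateRegion(st$diag$rh, state@grid),
      export_gtc = aggregateRegion(st$diag$export, state@grid),
      nbp_gtc = aggregateRegion(st$diag$nbp, state@grid))
  }
  methods::new("ScenarioResult", scenario = scenario,
               years = as.integer(forcing@years),
               series = do.call(rbind, rows),
               startState = state0, endState = state)
}

#' Run the fixed / default / optimized cropland scenarios
#'
#' All three scenarios share the same starting state, forcing and
#' parameters. Before the divergence year every scenario is driven by the
#' default cropland field (shared history, so the runs are bit-identical up
#' to then); from the divergence year on, the `fixed` scenario freezes the
#' default field at the divergence year, `default` follows the default
#' field, and `optimized` follows the calibrated field.
#'
#' @param state0 common starting [CarbonState-class].
#' @param forcing transient [ClimateForcing-class].
#' @param defaultField,optimizedField [CroplandField-class] objects on the
#'   forcing years.
#' @param params model parameter list.
#' @param divergenceYear year at which the scenarios separate (default: the
#'   first forcing year).
#' @return Named list of three [ScenarioResult-class] objects
#'   (`fixed`, `default`, `optimized`).
#' @export
runThreeScenarios <- function(state0, forcing, defaultField, optimizedField,
                              params = defaultModelParams(),
                              divergenceYear = NULL) {
  yrs <- forcing@years
  if (is.null(divergenceYear)) divergenceYear <- yrs[1]
  if (!divergenceYear %in% yrs) stop("divergence year outside the forcing range")
  iDiv <- match(divergenceYear, yrs)
  mk <- function(frac) methods::new("CroplandField", grid = defaultField@grid,
                                    years = as.integer(yrs), fraction = frac,
                                    metadata = list())
  fracDef <- defaultField@fraction
  fracFix <- fracDef
  for (t in seq_along(yrs)) if (t > iDiv) fracFix[, , t] <- fracDef[, , iDiv]
  fracOpt <- optimizedField@fraction
  for (t in seq_along(yrs)) if (t < iDiv) fracOpt[, , t] <- fracDef[, , t]
  list(
    fixed = runScenario(state0, forcing, mk(fracFix), params, "fixed"),
    default = runScenario(state0, forcing, mk(fracDef), params, "default"),
    optimized = runScenario(state0, forcing, mk(fracOpt), params, "optimized")
  )
}

#' Attribute the carbon-sink impact by scenario differencing
#'
#' Per-year pool differences (first minus second scenario) for biosphere,
#' vegetation and soil-side carbon; the biosphere difference equals the
#' vegetation plus soil differences exactly. The cumulative attributed sink
#' is the difference at the final year (both runs start from the same
#' state).
#'
#' @param a,b [ScenarioResult-class] objects on the same years and grid
#'   (conventionally `a` = optimized, `b` = fixed).
#' @return list with `series` (data.frame: year, d_biosphere_gtc, d_veg_gtc,
#'   d_soil_gtc), `cumulative_gtc`, `veg_share`, `soil_share`.
#' @export
attributeSink <- function(a, b) {
  stopifnot(identical(a@years, b@years))
  sa <- a@series; sb <- b@series
  stopifnot(identical(sa$year, sb$year))
  dVeg <- sa$veg_gtc - sb$veg_gtc
  dSoil <- sa$soil_gtc - sb$soil_gtc
  # biosphere difference as the sum of its exact decomposition, so the
  # additivity contract holds to the last bit
  ser <- data.frame(year = sa$year, d_biosphere_gtc = dVeg + dSoil,
                    d_veg_gtc = dVeg, d_soil_gtc = dSoil)
  cum <- ser$d_biosphere_gtc[nrow(ser)]
  vs <- if (cum != 0) ser$d_veg_gtc[nrow(ser)] / cum else NA_real_
  list(series = ser, cumulative_gtc = cum,
       veg_share = vs, soil_share = if (is.na(vs)) NA_real_ else 1 - vs)
}

#' Conversion ledger: where the lost cropland went
#'
#' Per year relative to the base year: cropland (plus bare-ground)
#' reduction; forest and grass area standing on formerly cropped area
#' (tracked per cell by succession origin, i.e. gross flows, not net area
#' differencing); and the residual, reduction minus vegetation established
#' on abandoned land, which shrinks as succession completes.
#'
#' @param result a [ScenarioResult-class].
#' @param baseYear reference year (default: the baseline row).
#' @return data.frame: `year`, `reduction_mha`, `forest_on_abandoned_mha`,
#'   `grass_on_abandoned_mha`, `residual_mha`.
#' @export
conversionLedger <- function(result, baseYear = NULL) {
  s <- result@series
  if (is.null(baseYear)) baseYear <- s$year[1]
  i0 <- match(baseYear, s$year)
  if (is.na(i0)) stop("base year not in the result series")
  base <- s$crop_mha[i0] + s$bare_mha[i0]
  red <- base - (s$crop_mha + s$bare_mha)
  data.frame(year = s$year,
             reduction_mha = red,
             forest_on_abandoned_mha = s$abn_forest_mha,
             grass_on_abandoned_mha = s$abn_grass_mha,
             residual_mha = red - s$abn_forest_mha - s$abn_grass_mha)
}

#' Per-cell end-state difference maps
#'
#' Differences (first minus second scenario) of the biosphere, vegetation
#' and soil-side carbon densities at the end of the runs, as
#' `[nlat, nlon]` matrices; the regional sum of the biosphere map equals
#' the attribution series' final value exactly.
#'
#' @param a,b [ScenarioResult-class] objects on the same grid.
#' @return list of matrices `biosphere`, `veg`, `soil` (kgC m-2).
#' @export
differenceMaps <- function(a, b) {
  ga <- a@endState@grid
  stopifnot(identical(dim(ga@cellArea), dim(b@endState@grid@cellArea)))
  nlat <- length(ga@lat); nlon <- length(ga@lon)
  shape <- function(v) matrix(v, nlat, nlon)
  list(biosphere = shape(cellTotalC(a@endState) - cellTotalC(b@endState)),
       veg = shape(cellVegC(a@endState) - cellVegC(b@endState)),
       soil = shape(cellSoilC(a@endState) - cellSoilC(b@endState)))
}
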