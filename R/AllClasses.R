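#' @import methods
NULL

PFT_IDS <- c("broadleaf", "needleleaf", "coldgrass", "warmgrass", "crop")
VEG_POOLS <- c("leaf", "froot", "croot", "sapwood", "heartwood")
SOIL_POOLS <- c("fast", "intermediate", "slow")
LITTER_POOLS <- c("metabolic", "structural")

#' Regular latitude-longitude land grid
#'
#' Container for the model domain: cell-centre coordinates, spherical cell
#' areas, a land mask and an integer country mask (0 outside the study
#' region, 1..K for study countries).
#'
#' @slot lat numeric, ascending latitude cell centres (degrees north).
#' @slot lon numeric, ascending longitude cell centres (degrees east).
#' @slot cellArea matrix `[nlat, nlon]`, cell area in m^2.
#' @slot landMask logical matrix `[nlat, nlon]`.
#' @slot countryMask integer matrix `[nlat, nlon]`; non-zero only on land.
#' @exportClass LandGrid
setClass("LandGrid", representation(
  lat = "numeric", lon = "numeric", cellArea = "matrix",
  landMask = "matrix", countryMask = "matrix"
))

setValidity("LandGrid", function(object) {
  nlat <- length(object@lat); nlon <- length(object@lon)
  msg <- character()
  if (nlat < 2L || nlon < 2L) msg <- c(msg, "grid needs at least 2x2 cells")
  if (is.unsorted(object@lat, strictly = TRUE)) msg <- c(msg, "lat must be strictly ascending")
  if (is.unsorted(object@lon, strictly = TRUE)) msg <- c(msg, "lon must be strictly ascending")
  for (s in c("cellArea", "landMask", "countryMask")) {
    d <- dim(slot(object, s))
    if (!identical(d, c(nlat, nlon))) msg <- c(msg, sprintf("%s must be [nlat, nlon]", s))
  }
  if (nlat >= 3 && sd(diff(object@lat)) > 1e-8 * mean(diff(object@lat)))
    msg <- c(msg, "lat spacing must be regular")
  if (nlon >= 3 && sd(diff(object@lon)) > 1e-8 * mean(diff(object@lon)))
    msg <- c(msg, "lon spacing must be regular")
  if (any(object@cellArea[object@landMask] <= 0)) msg <- c(msg, "cellArea must be > 0 on land")
  if (any(object@countryMask != 0L & !object@landMask))
    msg <- c(msg, "countryMask must be zero off land")
  if (length(msg)) msg else TRUE
})

#' Annual national cropland area series
#'
#' @slot country character country code.
#' @slot years integer, strictly increasing years.
#' @slot area numeric, cropland area in Mha (>= 0).
#' @exportClass CountrySeries
setClass("CountrySeries", representation(
  country = "character", years = "integer", area = "numeric"
))

setValidity("CountrySeries", function(object) {
  msg <- character()
  if (length(object@country) != 1L) msg <- c(msg, "country must be a single code")
  if (length(object@years) != length(object@area))
    msg <- c(msg, "years and area must have equal length")
  if (length(object@years) && is.unsorted(object@years, strictly = TRUE))
    msg <- c(msg, "years must be strictly increasing")
  if (any(!is.finite(object@area)) || any(object@area < 0))
    msg <- c(msg, "area must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CountrySeries
#' @param country single country code.
#' @param years integer years.
#' @param area numeric areas (Mha).
#' @return A [CountrySeries-class] object.
#' @export
CountrySeries <- function(country, years, area) {
  new("CountrySeries", country = as.character(country),
      years = as.integer(years), area = as.numeric(area))
}

#' Annual cropland adjustment-rate series
#'
#' Dimensionless per-year multipliers, one column per country (or a single
#' `"REGION"` column for the region-wide mode). A rate of 1 leaves the
#' gridded cropland fraction unchanged.
#'
#' @slot years integer years.
#' @slot rate matrix `[nYears, nCountries]` with country codes as colnames;
#'   all entries > 0.
#' @exportClass AdjustRateSeries
setClass("AdjustRateSeries", representation(years = "integer", rate = "matrix"))

setValidity("AdjustRateSeries", function(object) {
  msg <- character()
  if (nrow(object@rate) != length(object@years))
    msg <- c(msg, "rate must have one row per year")
  if (is.null(colnames(object@rate))) msg <- c(msg, "rate columns must be named by country")
  if (any(!is.finite(object@rate)) || any(object@rate <= 0))
    msg <- c(msg, "rates must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' Gridded annual cropland fraction field
#'
#' @slot grid a [LandGrid-class].
#' @slot years integer years.
#' @slot fraction array `[nlat, nlon, nYears]`, values in `[0, 1]`, zero off
#'   land.
#' @slot metadata list of provenance / processing notes (e.g. the clamping
#'   report written by [rescaleGridded()]).
#' @exportClass CroplandField
setClass("CroplandField", representation(
  grid = "LandGrid", years = "integer", fraction = "array", metadata = "list"
), prototype(metadata = list()))

setValidity("CroplandField", function(object) {
  msg <- character()
  d <- dim(object@fraction)
  nlat <- length(object@grid@lat); nlon <- length(object@grid@lon)
  if (length(d) != 3L || d[1] != nlat || d[2] != nlon || d[3] != length(object@years))
    msg <- c(msg, "fraction must be [nlat, nlon, nYears]")
  if (any(!is.finite(object@fraction)) ||
      any(object@fraction < -1e-12) || any(object@fraction > 1 + 1e-12))
    msg <- c(msg, "fractions must lie in [0, 1]")
  off <- !object@grid@landMask
  if (length(d) == 3L && any(abs(object@fraction[rep(off, d[3])]) > 1e-12))
    msg <- c(msg, "fraction must be zero off land")
  if (length(msg)) msg else TRUE
})

#' Monthly climate forcing plus annual CO2
#'
#' @slot grid a [LandGrid-class].
#' @slot years integer years.
#' @slot temp array `[nlat, nlon, 12, nYears]` air temperature, degrees C.
#' @slot precip array, precipitation, mm month^-1 (>= 0).
#' @slot par array, photosynthetically active radiation, W m^-2 (>= 0).
#' @slot co2 numeric, annual CO2 in ppm, one value per year.
#' @exportClass ClimateForcing
setClass("ClimateForcing", representation(
  grid = "LandGrid", years = "integer",
  temp = "array", precip = "array", par = "array", co2 = "numeric"
))

setValidity("ClimateForcing", function(object) {
  msg <- character()
  nlat <- length(object@grid@lat); nlon <- length(object@grid@lon)
  want <- c(nlat, nlon, 12L, length(object@years))
  for (s in c("temp", "precip", "par")) {
    if (!identical(dim(slot(object, s)), want))
      msg <- c(msg, sprintf("%s must be [nlat, nlon, 12, nYears]", s))
    if (any(!is.finite(slot(object, s)))) msg <- c(msg, sprintf("%s must be finite", s))
  }
  if (any(object@precip < 0)) msg <- c(msg, "precip must be >= 0")
  if (any(object@par < 0)) msg <- c(msg, "par must be >= 0")
  if (length(object@co2) != length(object@years))
    msg <- c(msg, "co2 must have one value per year")
  if (length(msg)) msg else TRUE
})

#' Per-cell carbon and cover state of the vegetation model
#'
#' Vegetation pools are stored as densities over the PFT's own cover area
#' (kgC per m^2 of that PFT); litter, decomposer, soil and product pools are
#' per m^2 of the whole cell. Cells are in column-major grid order.
#'
#' @slot grid a [LandGrid-class].
#' @slot veg array `[nCell, 5 PFTs, 5 pools]` (leaf, fine root, coarse root,
#'   sapwood, heartwood), kgC m^-2 of PFT area.
#' @slot litter matrix `[nCell, 2]` metabolic and structural litter, kgC m^-2.
#' @slot decomposer numeric `[nCell]`, kgC m^-2.
#' @slot soil matrix `[nCell, 3]` fast, intermediate, slow, kgC m^-2.
#' @slot product numeric `[nCell]`, cumulative harvested/exported carbon
#'   (kgC m^-2); tracked for exact conservation, excluded from biosphere
#'   totals.
#' @slot cover matrix `[nCell, 5]` fractional cover per PFT.
#' @slot bare numeric `[nCell]` bare-ground fraction; cover sums + bare = 1.
#' @slot abnGrass matrix `[nCell, 2]` fraction of the cell that is
#'   abandoned-origin cold / warm grass.
#' @slot abnTree numeric `[nCell]` abandoned-origin tree fraction.
#' @slot age numeric `[nCell]` years since (first) abandonment, 0 if never.
#' @slot soilWater numeric `[nCell]` bucket water content, mm.
#' @exportClass CarbonState
setClass("CarbonState", representation(
  grid = "LandGrid", veg = "array", litter = "matrix", decomposer = "numeric",
  soil = "matrix", product = "numeric", cover = "matrix", bare = "numeric",
  abnGrass = "matrix", abnTree = "numeric", age = "numeric",
  soilWater = "numeric"
))

setValidity("CarbonState", function(object) {
  n <- length(object@grid@lat) * length(object@grid@lon)
  msg <- character()
  if (!identical(dim(object@veg), c(n, 5L, 5L))) msg <- c(msg, "veg must be [nCell, 5, 5]")
  if (!identical(dim(object@litter), c(n, 2L))) msg <- c(msg, "litter must be [nCell, 2]")
  if (!identical(dim(object@soil), c(n, 3L))) msg <- c(msg, "soil must be [nCell, 3]")
  if (!identical(dim(object@cover), c(n, 5L))) msg <- c(msg, "cover must be [nCell, 5]")
  pools <- c(object@veg, object@litter, object@decomposer, object@soil, object@product)
  if (any(!is.finite(pools))) msg <- c(msg, "carbon pools must be finite")
  if (any(pools < -1e-10)) msg <- c(msg, "carbon pools must be >= 0")
  part <- rowSums(object@cover) + object@bare
  if (any(abs(part - 1) > 1e-9)) msg <- c(msg, "cover + bare must sum to 1")
  if (any(object@cover < -1e-10) || any(object@bare < -1e-10))
    msg <- c(msg, "cover fractions must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of one land-use scenario run
#'
#' @slot scenario scenario id, one of `"fixed"`, `"default"`, `"optimized"`
#'   (free-form ids are allowed).
#' @slot years integer simulated years.
#' @slot series data.frame of annual regional totals: pool groups in GtC,
#'   PFT areas in Mha, fluxes in GtC yr^-1.
#' @slot startState,endState [CarbonState-class] snapshots.
#' @exportClass ScenarioResult
setClass("ScenarioResult", representation(
  scenario = "character", years = "integer", series = "data.frame",
  startState = "CarbonState", endState = "CarbonState"
))

setValidity("ScenarioResult", function(object) {
  msg <- character()
  need <- c("year", "biosphere_gtc", "veg_gtc", "soil_gtc")
  if (!all(need %in% names(object@series)))
    msg <- c(msg, paste("series must contain", paste(need, collapse = ", ")))
  else {
    gap <- abs(object@series$biosphere_gtc -
                 (object@series$veg_gtc + object@series$soil_gtc))
    if (any(gap > 1e-9 * pmax(1, abs(object@series$biosphere_gtc))))
      msg <- c(msg, "biosphere carbon must equal vegetation + soil-side carbon")
  }
  if (length(msg)) msg else TRUE
})
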