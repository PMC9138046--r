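# Accessors and show methods.

#' @name grid-accessors
#' @title Accessors for LandGrid and gridded objects
#' @param x a LandGrid, CroplandField, ClimateForcing or CarbonState.
#' @return The requested component.
NULL

#' @rdname grid-accessors
#' @export
setGeneric("latCenters", function(x) standardGeneric("latCenters"))
#' @rdname grid-accessors
#' @export
setGeneric("lonCenters", function(x) standardGeneric("lonCenters"))
#' @rdname grid-accessors
#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))
#' @rdname grid-accessors
#' @export
setGeneric("landMask", function(x) standardGeneric("landMask"))
#' @rdname grid-accessors
#' @export
setGeneric("countryMask", function(x) standardGeneric("countryMask"))
#' @rdname grid-accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname grid-accessors
#' @export
setGeneric("seriesYears", function(x) standardGeneric("seriesYears"))
#' @rdname grid-accessors
#' @export
setGeneric("areaMha", function(x) standardGeneric("areaMha"))
#' @rdname grid-accessors
#' @export
setGeneric("fraction", function(x) standardGeneric("fraction"))
#' @rdname grid-accessors
#' @export
setGeneric("adjustRate", function(x) standardGeneric("adjustRate"))
#' @rdname grid-accessors
#' @export
setGeneric("regionalSeries", function(x) standardGeneric("regionalSeries"))
#' @rdname grid-accessors
#' @export
setGeneric("endState", function(x) standardGeneric("endState"))
#' @rdname grid-accessors
#' @export
setGeneric("scenarioId", function(x) standardGeneric("scenarioId"))

setMethod("latCenters", "LandGrid", function(x) x@lat)
setMethod("lonCenters", "LandGrid", function(x) x@lon)
setMethod("cellArea", "LandGrid", function(x) x@cellArea)
setMethod("landMask", "LandGrid", function(x) x@landMask)
setMethod("countryMask", "LandGrid", function(x) x@countryMask)
setMethod("nCells", "LandGrid", function(x) length(x@lat) * length(x@lon))

setMethod("latCenters", "CroplandField", function(x) x@grid@lat)
setMethod("lonCenters", "CroplandField", function(x) x@grid@lon)
setMethod("seriesYears", "CroplandField", function(x) x@years)
setMethod("fraction", "CroplandField", function(x) x@fraction)

setMethod("seriesYears", "CountrySeries", function(x) x@years)
setMethod("areaMha", "CountrySeries", function(x) x@area)

setMethod("seriesYears", "AdjustRateSeries", function(x) x@years)
setMethod("adjustRate", "AdjustRateSeries", function(x) x@rate)

setMethod("seriesYears", "ClimateForcing", function(x) x@years)

setMethod("nCells", "CarbonState", function(x) nCells(x@grid))

setMethod("seriesYears", "ScenarioResult", function(x) x@years)
setMethod("regionalSeries", "ScenarioResult", function(x) x@series)
setMethod("endState", "ScenarioResult", function(x) x@endState)
setMethod("scenarioId", "ScenarioResult", function(x) x@scenario)

setMethod("show", "LandGrid", function(object) {
  cat(sprintf("LandGrid: %d x %d cells, lat %.2f..%.2f, lon %.2f..%.2f\n",
              length(object@lat), length(object@lon),
              min(object@lat), max(object@lat), min(object@lon), max(object@lon)))
  cat(sprintf("  land cells: %d, study countries: %d\n",
              sum(object@landMask), length(setdiff(unique(object@countryMask), 0L))))
})

setMethod("show", "CountrySeries", function(object) {
  cat(sprintf("CountrySeries '%s': %d years (%d..%d), %.2f..%.2f Mha\n",
              object@country, length(object@years),
              min(object@years), max(object@years),
              min(object@area), max(object@area)))
})

setMethod("show", "AdjustRateSeries", function(object) {
  cat(sprintf("AdjustRateSeries: years %d..%d, countries: %s, rate range %.3f..%.3f\n",
              min(object@years), max(object@years),
              paste(colnames(object@rate), collapse = ", "),
              min(object@rate), max(object@rate)))
})

setMethod("show", "CroplandField", function(object) {
  cat(sprintf("CroplandField: %d x %d x %d years, fraction range %.3f..%.3f\n",
              length(object@grid@lat), length(object@grid@lon),
              length(object@years), min(object@fraction), max(object@fraction)))
})

setMethod("show", "ClimateForcing", function(object) {
  cat(sprintf(
    "ClimateForcing: %d years, T %.1f..%.1f degC, P %.0f..%.0f mm/mo, CO2 %.1f..%.1f ppm\n",
    length(object@years), min(object@temp), max(object@temp),
    min(object@precip), max(object@precip), min(object@co2), max(object@co2)))
})

setMethod("show", "CarbonState", function(object) {
  land <- as.vector(object@grid@landMask)
  cat(sprintf("CarbonState: %d cells (%d land)\n", nCells(object), sum(land)))
  cat(sprintf("  mean veg C %.2f, soil-side C %.2f kgC m-2 (land)\n",
              mean(cellVegC(object)[land]), mean(cellSoilC(object)[land])))
})

setMethod("show", "ScenarioResult", function(object) {
  s <- object@series
  cat(sprintf("ScenarioResult '%s': %d..%d\n", object@scenario,
              min(s$year), max(s$year)))
  cat(sprintf("  biosphere C %.2f -> %.2f GtC\n",
              s$biosphere_gtc[1], s$biosphere_gtc[nrow(s)]))
})
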