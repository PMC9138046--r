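# Cropland-series calibration: anchor an arable-land series to sown-area
# dynamics, turn the correction into an annual adjustment rate, and rescale
# a gridded cropland-fraction field without changing its spatial pattern.

alignYears <- function(a, b) {
  common <- intersect(a@years, b@years)
  if (!length(common)) stop("series share no years")
  sort(common)
}

seriesAt <- function(s, yrs) s@area[match(yrs, s@years)]

#' Optimize a national cropland series against a reference record
#'
#' Replaces the interannual dynamics of an arable-land series with those of
#' a sown-area reference while anchoring the level at the base year:
#' `out(i) = fao(baseYear) + ref(i) - ref(baseYear)`. The output equals the
#' arable series exactly at the base year, so the record stays continuous
#' with the pre-calibration history.
#'
#' @param fao arable-land [CountrySeries-class].
#' @param reference sown-area [CountrySeries-class] (same country).
#' @param baseYear anchor year present in both series.
#' @return A [CountrySeries-class] over the reference years `>= baseYear`.
#' @examples
#' fao <- CountrySeries("C1", 1990:1995, rep(100, 6))
#' ref <- CountrySeries("C1", 1990:1995, c(90, 88, 85, 80, 75, 70))
#' areaMha(optimizeCountrySeries(fao, ref, 1990))
#' @export
optimizeCountrySeries <- function(fao, reference, baseYear = 1990L) {
  stopifnot(methods::is(fao, "CountrySeries"), methods::is(reference, "CountrySeries"))
  baseYear <- as.integer(baseYear)
  if (!baseYear %in% fao@years) stop("base year missing from the arable-land series")
  if (!baseYear %in% reference@years) stop("base year missing from the reference series")
  yrs <- reference@years[reference@years >= baseYear]
  out <- seriesAt(fao, baseYear) + seriesAt(reference, yrs) -
    seriesAt(reference, baseYear)
  if (any(out < 0)) {
    bad <- yrs[which(out < 0)[1]]
    stop(sprintf("optimized area negative in %d: inconsistent input series", bad))
  }
  CountrySeries(fao@country, yrs, out)
}

#' Sum country series into a regional total
#'
#' @param optimized the calibrated [CountrySeries-class].
#' @param directFao list of [CountrySeries-class] taken from the arable-land
#'   records unchanged (may be empty).
#' @return A [CountrySeries-class] with country code `"REGION"`.
#' @export
buildRegionSeries <- function(optimized, directFao = list()) {
  stopifnot(methods::is(optimized, "CountrySeries"))
  total <- optimized@area
  for (s in directFao) {
    if (!identical(s@years, optimized@years))
      stop("year-range mismatch between country series")
    total <- total + s@area
  }
  CountrySeries("REGION", optimized@years, total)
}

#' Cropland adjustment rate: optimized over original totals
#'
#' `rate(j) = optimized(j) / fao(j)`; where the two series agree at the base
#' year the rate is exactly 1 there. Multiplying the original records by the
#' rate re-establishes the optimized totals.
#'
#' @param optimized,fao [CountrySeries-class] objects on common years;
#'   `fao` must be strictly positive.
#' @return An [AdjustRateSeries-class] with one column named after the
#'   optimized series' country.
#' @export
computeAdjustRate <- function(optimized, fao) {
  yrs <- alignYears(optimized, fao)
  f <- seriesAt(fao, yrs)
  if (any(f == 0)) stop("FAO total is zero in some year; rate undefined")
  r <- matrix(seriesAt(optimized, yrs) / f, ncol = 1,
              dimnames = list(NULL, optimized@country))
  methods::new("AdjustRateSeries", years = as.integer(yrs), rate = r)
}

#' Combine per-country adjustment-rate series
#'
#' @param rates list of single-column [AdjustRateSeries-class] objects on
#'   identical years.
#' @return One multi-column [AdjustRateSeries-class].
#' @export
combineAdjustRates <- function(rates) {
  stopifnot(length(rates) >= 1)
  yrs <- rates[[1]]@years
  for (r in rates) if (!identical(r@years, yrs)) stop("rate year ranges differ")
  methods::new("AdjustRateSeries", years = yrs,
               rate = do.call(cbind, lapply(rates, slot, "rate")))
}

#' Rescale a gridded cropland field by annual adjustment rates
#'
#' Multiplies every cell's cropland fraction inside the study countries by
#' the year's (per-country or region-wide) rate, clamping to `[0, 1]` and
#' reporting the area lost to clamping. Cells outside the study countries
#' and years outside the rate record are passed through unchanged (rate 1).
#' Because the operation is a per-country scalar multiply, the within-country
#' rank order of cells is preserved whenever no clamping occurs.
#'
#' @param field a [CroplandField-class].
#' @param rates an [AdjustRateSeries-class]; column names are country codes
#'   (`"C1"`, ...) in per-country mode, or a single column (any name) in
#'   region-wide mode.
#' @param mode `"per-country"` or `"region-wide"`.
#' @param passthrough if `TRUE` (default) years outside the rate record get
#'   rate 1; if `FALSE` they raise an error.
#' @return A [CroplandField-class]; `clampReport()` retrieves a data.frame
#'   (`year`, `clamped_mha`) of area lost to clamping.
#' @export
rescaleGridded <- function(field, rates, mode = c("per-country", "region-wide"),
                           passthrough = TRUE) {
  stopifnot(methods::is(field, "CroplandField"), methods::is(rates, "AdjustRateSeries"))
  mode <- match.arg(mode)
  grid <- field@grid
  cmask <- as.vector(grid@countryMask)
  areaV <- as.vector(grid@cellArea)
  nlat <- length(grid@lat); nlon <- length(grid@lon)
  frac <- field@fraction
  clamped <- numeric(length(field@years))
  for (t in seq_along(field@years)) {
    yr <- field@years[t]
    i <- match(yr, rates@years)
    if (is.na(i)) {
      if (!passthrough)
        stop(sprintf("adjustment rate missing for simulated year %d", yr))
      next
    }
    v <- as.vector(frac[, , t])
    out <- v
    if (mode == "region-wide") {
      sel <- cmask > 0L
      out[sel] <- v[sel] * rates@rate[i, 1]
    } else {
      for (cc in colnames(rates@rate)) {
        code <- as.integer(sub("^C", "", cc))
        sel <- cmask == code
        out[sel] <- v[sel] * rates@rate[i, cc]
      }
    }
    over <- pmax(out - 1, 0)
    clamped[t] <- sum(over * areaV) * 1e-10
    out <- pmin(pmax(out, 0), 1)
    frac[, , t] <- matrix(out, nlat, nlon)
  }
  meta <- field@metadata
  meta$clampReport <- data.frame(year = field@years, clamped_mha = clamped)
  meta$rateMode <- mode
  methods::new("CroplandField", grid = grid, years = field@years,
               fraction = frac, metadata = meta)
}

#' Clamping report of a rescaled cropland field
#' @param field a [CroplandField-class] produced by [rescaleGridded()].
#' @return data.frame with columns `year` and `clamped_mha`, or `NULL`.
#' @export
clampReport <- function(field) field@metadata$clampReport

#' National or gridded cropland area and its decline
#'
#' For a [CountrySeries-class], `area(y0) - area(y1)` in Mha. For a
#' [CroplandField-class], national totals are fraction times cell area
#' summed over the study mask (countryMask > 0), converted to Mha.
#'
#' @param x a [CountrySeries-class] or [CroplandField-class].
#' @param y0,y1 years bounding the interval (`y0 < y1`).
#' @return Abandoned area in Mha (positive when cropland declined).
#' @export
setGeneric("abandonmentArea", function(x, y0, y1) standardGeneric("abandonmentArea"))

#' @rdname abandonmentArea
#' @export
setMethod("abandonmentArea", "CountrySeries", function(x, y0, y1) {
  if (y0 >= y1) stop("need y0 < y1")
  if (!all(c(y0, y1) %in% x@years)) stop("years out of range of the series")
  seriesAt(x, y0) - seriesAt(x, y1)
})

#' @rdname abandonmentArea
#' @export
setMethod("abandonmentArea", "CroplandField", function(x, y0, y1) {
  if (y0 >= y1) stop("need y0 < y1")
  if (!all(c(y0, y1) %in% x@years)) stop("years out of range of the field")
  croplandTotalMha(x, y0) - croplandTotalMha(x, y1)
})

#' Gridded national cropland total
#' @param field a [CroplandField-class].
#' @param year a year in the field's record.
#' @param countries integer country codes (default: all study countries).
#' @return Total cropland area in Mha.
#' @export
croplandTotalMha <- function(field, year, countries = NULL) {
  t <- match(year, field@years)
  if (is.na(t)) stop("year out of range of the field")
  cmask <- as.vector(field@grid@countryMask)
  sel <- if (is.null(countries)) cmask > 0L else cmask %in% countries
  sum(as.vector(field@fraction[, , t])[sel] *
        as.vector(field@grid@cellArea)[sel]) * 1e-10
}
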