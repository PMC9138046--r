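# Plain-text I/O: country tables and adjustment rates as CSV, gridded
# fields as a grid CSV plus a long-format values CSV. Numeric values are
# written with 17 significant digits so read(write(x)) round-trips
# bit-exactly.

fmtNum <- function(x) sprintf("%.17g", x)

writeCsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmtNum)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read national cropland series from CSV
#'
#' Expects columns `country`, `year`, `area_mha` (extra columns are
#' ignored). Accepts exports in the style of international agricultural
#' statistics portals after renaming to these columns.
#'
#' @param path CSV file path.
#' @return Named list of [CountrySeries-class], one per country.
#' @export
readCountryCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("country", "year", "area_mha"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  year <- suppressWarnings(as.numeric(df$year))
  area <- suppressWarnings(as.numeric(df$area_mha))
  badRow <- which(!is.finite(year) | !is.finite(area))
  if (length(badRow))
    stop(sprintf("non-numeric year/area_mha at row %d", badRow[1]))
  if (anyDuplicated(df[c("country", "year")]))
    stop("duplicate (country, year) rows")
  out <- lapply(split(seq_len(nrow(df)), df$country), function(i) {
    o <- i[order(year[i])]
    CountrySeries(df$country[o[1]], year[o], area[o])
  })
  out[order(names(out))]
}

#' Write national cropland series to CSV
#' @param series a [CountrySeries-class] or a list of them.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeCountryCsv <- function(series, path) {
  if (methods::is(series, "CountrySeries")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(country = s@country, year = s@years, area_mha = s@area)))
  writeCsv(df, path)
}

#' Read / write adjustment-rate series as CSV
#'
#' Columns `country`, `year`, `rate`.
#' @param path CSV path.
#' @param rates an [AdjustRateSeries-class].
#' @return `readAdjustRateCsv()` returns an [AdjustRateSeries-class].
#' @export
readAdjustRateCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  yrs <- sort(unique(df$year))
  countries <- unique(df$country)
  r <- matrix(NA_real_, length(yrs), length(countries),
              dimnames = list(NULL, countries))
  for (i in seq_len(nrow(df)))
    r[match(df$year[i], yrs), df$country[i]] <- df$rate[i]
  if (any(is.na(r))) stop("incomplete rate table")
  methods::new("AdjustRateSeries", years = as.integer(yrs), rate = r)
}

#' @rdname readAdjustRateCsv
#' @export
writeAdjustRateCsv <- function(rates, path) {
  df <- expand.grid(year = rates@years, country = colnames(rates@rate),
                    stringsAsFactors = FALSE)
  df$rate <- as.vector(rates@rate)
  writeCsv(df[c("country", "year", "rate")], path)
}

#' Read / write a land grid as CSV
#'
#' One row per cell: `lat`, `lon`, `cell_area_m2`, `land` (0/1),
#' `country` (integer code).
#' @param grid a [LandGrid-class].
#' @param path CSV path.
#' @return `readGridCsv()` returns a [LandGrid-class].
#' @export
writeGridCsv <- function(grid, path) {
  df <- data.frame(lat = cellLat(grid), lon = cellLon(grid),
                   cell_area_m2 = as.vector(grid@cellArea),
                   land = as.integer(as.vector(grid@landMask)),
                   country = as.vector(grid@countryMask))
  writeCsv(df, path)
}

#' @rdname writeGridCsv
#' @export
readGridCsv <- function(path) {
  df <- utils::read.csv(path)
  lat <- as.numeric(sort(unique(df$lat))); lon <- as.numeric(sort(unique(df$lon)))
  nlat <- length(lat); nlon <- length(lon)
  o <- order(match(df$lon, lon), match(df$lat, lat))
  df <- df[o, ]
  methods::new("LandGrid", lat = lat, lon = lon,
               cellArea = matrix(as.numeric(df$cell_area_m2), nlat, nlon),
               landMask = matrix(df$land == 1L, nlat, nlon),
               countryMask = matrix(as.integer(df$country), nlat, nlon))
}

#' Read / write a gridded annual field as long-format CSV
#'
#' Values CSV has columns `year`, `lat`, `lon`, `value`; the grid is stored
#' in a companion CSV ([writeGridCsv()]). The round trip is bit-exact.
#'
#' @param field a [CroplandField-class].
#' @param path values CSV path.
#' @param gridPath companion grid CSV path (default: `path` with a
#'   `_grid.csv` suffix).
#' @param validate check fraction bounds on read (default `TRUE`).
#' @return `readGriddedCsv()` returns a [CroplandField-class].
#' @export
writeGriddedCsv <- function(field, path, gridPath = NULL) {
  if (is.null(gridPath)) gridPath <- sub("\\.csv$", "_grid.csv", path)
  writeGridCsv(field@grid, gridPath)
  g <- field@grid
  n <- nCells(g)
  df <- data.frame(
    year = rep(field@years, each = n),
    lat = rep(cellLat(g), times = length(field@years)),
    lon = rep(cellLon(g), times = length(field@years)),
    value = as.vector(field@fraction))
  writeCsv(df, path)
}

#' @rdname writeGriddedCsv
#' @export
readGriddedCsv <- function(path, gridPath = NULL, validate = TRUE) {
  if (is.null(gridPath)) gridPath <- sub("\\.csv$", "_grid.csv", path)
  if (!file.exists(gridPath)) stop("missing grid file: ", gridPath)
  grid <- readGridCsv(gridPath)
  df <- utils::read.csv(path)
  yrs <- sort(unique(df$year))
  nlat <- length(grid@lat); nlon <- length(grid@lon)
  if (nrow(df) != nlat * nlon * length(yrs))
    stop("gridded CSV does not cover the full grid for every year")
  o <- order(match(df$year, yrs), match(df$lon, grid@lon), match(df$lat, grid@lat))
  frac <- array(as.numeric(df$value[o]), c(nlat, nlon, length(yrs)))
  if (validate && (any(frac < -1e-12) || any(frac > 1 + 1e-12)))
    stop("fraction values outside [0, 1]")
  methods::new("CroplandField", grid = grid, years = as.integer(yrs),
               fraction = frac, metadata = list(source = path))
}
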