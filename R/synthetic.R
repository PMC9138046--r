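# Synthetic inputs: land grid, national cropland tables, gridded cropland
# fraction, monthly climate. Everything is deterministic given its seed, so
# the full analysis pipeline is testable without external downloads.

EARTH_RADIUS <- 6371000  # m

# Smooth zero-mean random field on [nlat, nlon]: iterated 3x3 box filtering
# of white noise, rescaled to unit sd. Gives contiguous blobs.
smoothField <- function(nlat, nlon, passes = 6L) {
  f <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
  pad <- function(m, di, dj) {
    i <- pmin(pmax(seq_len(nlat) + di, 1L), nlat)
    j <- pmin(pmax(seq_len(nlon) + dj, 1L), nlon)
    m[i, j, drop = FALSE]
  }
  for (k in seq_len(passes)) {
    acc <- matrix(0, nlat, nlon)
    for (di in -1:1) for (dj in -1:1) acc <- acc + pad(f, di, dj)
    f <- acc / 9
  }
  (f - mean(f)) / stats::sd(f)
}

cellLat <- function(grid) rep(grid@lat, times = length(grid@lon))
cellLon <- function(grid) rep(grid@lon, each = length(grid@lat))

#' Generate a synthetic land grid with country regions
#'
#' Builds a regular lat-lon grid over a mid-latitude band, computes
#' spherical cell areas, carves a land mask from a smooth random field and
#' partitions the land into `nCountries` contiguous longitudinal blocks
#' (country 1 is the largest, carrying the sown-area reference series
#' downstream).
#'
#' @param nLat,nLon number of cells (>= 2 each).
#' @param latRange,lonRange numeric length-2 extents in degrees.
#' @param nCountries number of study countries (1..5).
#' @param seed integer RNG seed; output is reproducible bit-for-bit.
#' @param landFrac fraction of cells that are land (default 0.9).
#' @return A [LandGrid-class].
#' @examples
#' g <- genGrid(4, 4, latRange = c(50, 60), lonRange = c(20, 30), nCountries = 1, seed = 1)
#' sum(landMask(g))
#' @export
genGrid <- function(nLat = 20L, nLon = 40L, latRange = c(45, 65),
                    lonRange = c(20, 100), nCountries = 3L, seed = 1L,
                    landFrac = 0.9) {
  if (nLat < 2L || nLon < 2L) stop("grid must be at least 2 x 2")
  if (diff(latRange) <= 0 || diff(lonRange) <= 0)
    stop("degenerate extent: lat/lon ranges must have positive span")
  if (nCountries < 1L || nCountries > 5L) stop("nCountries must be in 1..5")
  withr::with_seed(as.integer(seed), {
    dlat <- diff(latRange) / nLat
    dlon <- diff(lonRange) / nLon
    lat <- latRange[1] + dlat * (seq_len(nLat) - 0.5)
    lon <- lonRange[1] + dlon * (seq_len(nLon) - 0.5)
    latS <- (lat - dlat / 2) * pi / 180
    latN <- (lat + dlat / 2) * pi / 180
    areaCol <- EARTH_RADIUS^2 * (dlon * pi / 180) * (sin(latN) - sin(latS))
    cellArea <- matrix(areaCol, nLat, nLon)
    topo <- smoothField(nLat, nLon)
    land <- topo > stats::quantile(topo, 1 - landFrac)
    # countries: contiguous longitude bands over land, country 1 widest
    shares <- c(0.55, 0.3, 0.15, 0.1, 0.1)[seq_len(nCountries)]
    shares <- shares / sum(shares)
    breaks <- c(0, cumsum(rev(shares)))  # country 1 occupies the eastern side
    colIdx <- ceiling(breaks * nLon)
    cmask <- matrix(0L, nLat, nLon)
    for (k in seq_len(nCountries)) {
      code <- nCountries + 1L - k
      cols <- (colIdx[k] + 1L):colIdx[k + 1L]
      cmask[, cols] <- code
    }
    cmask[!land] <- 0L
    # guarantee at least one land cell per country
    for (k in seq_len(nCountries)) {
      if (!any(cmask == k)) {
        free <- which(land & cmask == 0L)
        if (!length(free)) free <- which(land)
        cmask[free[1]] <- k
      }
    }
    methods::new("LandGrid", lat = lat, lon = lon, cellArea = cellArea,
                 landMask = land, countryMask = cmask)
  })
}

#' Generate national cropland statistics tables
#'
#' Emulates the two kinds of national records the calibration reconciles:
#' near-flat arable-land series (FAO-style) for every country, and a
#' sown-area series (ROSSTAT-style) for country 1 that drops sharply from
#' the baseline, bottoms out late in the record and partially recovers.
#' Defaults mirror the printed national statistics for the post-Soviet
#' case: country 1 arable land 133.71 Mha declining ~7.8% over the period,
#' sown area starting at ~85.7% of it, losing 34.5% to a minimum 17 years
#' in, then recovering 12.6% of the loss.
#'
#' @param years integer year range (baseline first; >= 21 years).
#' @param seed RNG seed.
#' @param nCountries number of countries (country 1 gets the sown series).
#' @param baseArea baseline arable area per country, Mha.
#' @param decline list with elements `fao` (total relative decline of the
#'   country-1 arable series), `others` (per-country declines for the rest),
#'   `sown` (relative drop of the sown series from its baseline to the
#'   minimum, in [0, 1)), `sownRatio` (sown/arable at baseline),
#'   `minOffset` (years from baseline to the sown minimum) and `recovery`
#'   (fraction of the drop regained by the final year).
#' @param noiseSd sd (Mha) of smooth interannual noise; 0 gives exactly
#'   piecewise-linear series.
#' @return list with `fao` (list of [CountrySeries-class], one per country)
#'   and `rosstat` (a [CountrySeries-class] for country 1).
#' @export
genCountryTables <- function(years = 1990:2017, seed = 1L, nCountries = 3L,
                             baseArea = c(133.71, 33.5, 6.2, 12, 9),
                             decline = list(fao = 0.078,
                                            others = c(0.08, 0.09, 0.05, 0.05),
                                            sown = 0.345, sownRatio = 0.857,
                                            minOffset = 17L, recovery = 0.126),
                             noiseSd = 0.3) {
  years <- as.integer(years)
  n <- length(years)
  if (n < 21L) stop("year range must cover a baseline plus at least 20 years")
  d <- utils::modifyList(list(fao = 0.078, others = c(0.08, 0.09, 0.05, 0.05),
                              sown = 0.345, sownRatio = 0.857, minOffset = 17L,
                              recovery = 0.126), decline)
  if (d$sown >= 1 || d$fao >= 1) stop("requested decline exceeds 100%")
  withr::with_seed(as.integer(seed), {
    smoothNoise <- function(sd) {
      if (sd == 0) return(rep(0, n))
      x <- stats::filter(stats::rnorm(n + 10), rep(1 / 4, 4), sides = 1)
      x <- x[!is.na(x)][seq_len(n)]
      x * sd / max(stats::sd(x), 1e-12)
    }
    fao <- vector("list", nCountries)
    for (k in seq_len(nCountries)) {
      dk <- if (k == 1L) d$fao else d$others[min(k - 1L, length(d$others))]
      base <- baseArea[min(k, length(baseArea))]
      area <- base * (1 - dk * (seq_len(n) - 1) / (n - 1)) + smoothNoise(noiseSd)
      area[1] <- base
      fao[[k]] <- CountrySeries(paste0("C", k), years, pmax(area, 0))
    }
    sown0 <- baseArea[1] * d$sownRatio
    sownMin <- sown0 * (1 - d$sown)
    iMin <- 1L + as.integer(d$minOffset)
    if (iMin > n) iMin <- n
    traj <- numeric(n)
    traj[1:iMin] <- sown0 + (sownMin - sown0) * (0:(iMin - 1)) / max(iMin - 1, 1)
    if (iMin < n)
      traj[(iMin + 1):n] <- sownMin + d$recovery * (sown0 - sownMin) *
        ((iMin + 1):n - iMin) / (n - iMin)
    traj <- traj + smoothNoise(noiseSd)
    traj[1] <- sown0
    ros <- CountrySeries("C1", years, pmax(traj, 0))
    # sown area is a subset of arable land
    ros@area <- pmin(ros@area, fao[[1]]@area)
    list(fao = fao, rosstat = ros)
  })
}

#' Generate a HYDE-like gridded cropland-fraction field
#'
#' Spatially clustered cropland (a latitudinal belt modulated by a smooth
#' random field) with almost no temporal trend: interannual variation is a
#' small zero-mean multiplicative factor, reproducing the near-static
#' behaviour of historical land-use reconstructions over recent decades.
#'
#' @param grid a [LandGrid-class].
#' @param years integer years.
#' @param seed RNG seed.
#' @param temporalCv per-cell interannual coefficient of variation
#'   (default 0.01, must be <= 0.05); 0 freezes the field.
#' @param beltCenterFrac latitude of the cropland belt, as a fraction of the
#'   grid's latitudinal span from the southern edge (default 0.35).
#' @param maxFrac peak cropland fraction (default 0.65).
#' @param matchTotal optional named numeric: target national cropland totals
#'   (Mha, names = country codes `"C1"`...) that the base-year field is
#'   scaled to, country by country.
#' @return A [CroplandField-class].
#' @export
genHydeLike <- function(grid, years = 1990:2017, seed = 1L, temporalCv = 0.01,
                        beltCenterFrac = 0.35, maxFrac = 0.65,
                        matchTotal = NULL) {
  stopifnot(methods::is(grid, "LandGrid"))
  if (temporalCv < 0 || temporalCv > 0.05)
    stop("temporalCv must lie in [0, 0.05]")
  years <- as.integer(years)
  nlat <- length(grid@lat); nlon <- length(grid@lon); n <- length(years)
  withr::with_seed(as.integer(seed), {
    beltLat <- min(grid@lat) + beltCenterFrac * diff(range(grid@lat))
    beltWidth <- 0.25 * diff(range(grid@lat))
    belt <- exp(-((matrix(grid@lat, nlat, nlon) - beltLat) / beltWidth)^2)
    tex <- pmax(smoothField(nlat, nlon) + 0.8, 0)^2
    base <- belt * tex
    base <- base / max(base) * maxFrac
    base[!grid@landMask] <- 0
    if (!is.null(matchTotal)) {
      for (cc in names(matchTotal)) {
        code <- as.integer(sub("^C", "", cc))
        sel <- grid@countryMask == code
        cur <- sum(base[sel] * grid@cellArea[sel]) * 1e-10
        if (cur > 0) base[sel] <- pmin(base[sel] * matchTotal[[cc]] / cur, 1)
      }
    }
    eps <- if (temporalCv > 0) {
      e <- stats::rnorm(n)
      (e - mean(e)) / max(stats::sd(e), 1e-12) * temporalCv
    } else rep(0, n)
    frac <- array(0, c(nlat, nlon, n))
    for (t in seq_len(n)) frac[, , t] <- pmin(pmax(base * (1 + eps[t]), 0), 1)
    methods::new("CroplandField", grid = grid, years = years, fraction = frac,
                 metadata = list(seed = as.integer(seed), temporalCv = temporalCv))
  })
}

#' Generate synthetic monthly climate forcing with an annual CO2 ramp
#'
#' Temperature has a latitudinal gradient and a seasonal cycle (July
#' maximum); precipitation increases with latitude so the southern part of
#' the domain falls below the forest-suitability threshold (a steppe belt);
#' PAR follows the seasonal cycle. Interannual anomalies are smooth,
#' zero-mean over the record, and CO2 rises linearly.
#'
#' @param grid a [LandGrid-class].
#' @param years integer years.
#' @param seed RNG seed.
#' @param tNoiseSd sd of the annual temperature anomaly (degC); 0 repeats
#'   the climatology every year.
#' @param pNoiseCv coefficient of variation of the annual precipitation
#'   factor.
#' @param co2Start,co2Rate CO2 at the first year (ppm) and annual increment
#'   (ppm yr-1).
#' @return A [ClimateForcing-class].
#' @export
genClimate <- function(grid, years = 1990:2017, seed = 1L, tNoiseSd = 0.5,
                       pNoiseCv = 0.08, co2Start = 354, co2Rate = 1.9) {
  stopifnot(methods::is(grid, "LandGrid"))
  years <- as.integer(years)
  nlat <- length(grid@lat); nlon <- length(grid@lon); n <- length(years)
  withr::with_seed(as.integer(seed), {
    latM <- matrix(grid@lat, nlat, nlon)
    tMean <- 18 - 0.7 * (latM - min(grid@lat))
    tAmp <- 12 + 0.25 * (latM - min(grid@lat))
    pBase <- 30 + 1.5 * (latM - min(grid@lat))
    parBase <- 110 - 1.2 * (latM - min(grid@lat))
    season <- cos(2 * pi * ((1:12) - 7) / 12)
    temp <- array(0, c(nlat, nlon, 12, n))
    precip <- array(0, c(nlat, nlon, 12, n))
    par <- array(0, c(nlat, nlon, 12, n))
    center <- function(x) x - mean(x)
    tAnom <- if (tNoiseSd > 0) center(stats::rnorm(n, 0, tNoiseSd)) else rep(0, n)
    pFac <- if (pNoiseCv > 0) pmax(1 + center(stats::rnorm(n, 0, pNoiseCv)), 0.2) else rep(1, n)
    for (m in 1:12) {
      tClim <- tMean + tAmp * season[m]
      pClim <- pBase * (1 + 0.3 * season[m])
      parClim <- pmax(parBase * (0.55 + 0.45 * season[m]), 5)
      for (t in seq_len(n)) {
        temp[, , m, t] <- tClim + tAnom[t]
        precip[, , m, t] <- pmax(pClim * pFac[t], 0)
        par[, , m, t] <- parClim
      }
    }
    co2 <- co2Start + co2Rate * (seq_len(n) - 1)
    methods::new("ClimateForcing", grid = grid, years = years,
                 temp = temp, precip = precip, par = par, co2 = co2)
  })
}

#' Climatological (single repeating year) forcing
#'
#' Averages a multi-year [ClimateForcing-class] month by month into a
#' one-year climatology (CO2 of the first year), for spin-up.
#'
#' @param forcing a [ClimateForcing-class].
#' @return A one-year [ClimateForcing-class].
#' @export
climatology <- function(forcing) {
  stopifnot(methods::is(forcing, "ClimateForcing"))
  av <- function(a) {
    out <- array(0, c(dim(a)[1:3], 1L))
    out[, , , 1] <- apply(a, 1:3, mean)
    out
  }
  methods::new("ClimateForcing", grid = forcing@grid,
               years = forcing@years[1],
               temp = av(forcing@temp), precip = av(forcing@precip),
               par = av(forcing@par), co2 = forcing@co2[1])
}

#' Per-cell climate summary used by vegetation dynamics
#'
#' @param forcing a [ClimateForcing-class] (its climatology is used).
#' @param params model parameter list, see [defaultModelParams()].
#' @return list with per-cell vectors: `meanT` (degC), `annP` (mm yr-1),
#'   `suitableForest`, `warmGrass` (logicals) and `treePft` (succession
#'   target PFT index: 1 broadleaf or 2 needleleaf).
#' @export
climSummary <- function(forcing, params = defaultModelParams()) {
  stopifnot(methods::is(forcing, "ClimateForcing"))
  meanT <- as.vector(apply(forcing@temp, 1:2, mean))
  annP <- as.vector(apply(forcing@precip, 1:2, mean)) * 12
  list(
    meanT = meanT, annP = annP,
    suitableForest = annP >= params$forestPrecipMin & meanT >= params$forestTempMin,
    warmGrass = meanT >= params$warmGrassTemp,
    treePft = ifelse(meanT >= params$broadleafTemp, 1L, 2L)
  )
}
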