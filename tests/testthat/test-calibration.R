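test_that("series optimization reproduces the anchored-dynamics arithmetic", {
  fao <- CountrySeries("C1", c(1990, 1995), c(100, 98))
  ref <- CountrySeries("C1", c(1990, 1995), c(90, 70))
  out <- optimizeCountrySeries(fao, ref, 1990)
  expect_equal(areaMha(out)[match(1995, seriesYears(out))], 80)
  # continuity: exact equality at the base year
  expect_identical(areaMha(out)[1], 100)

  flat <- CountrySeries("C1", 1990:1995, rep(55, 6))
  out2 <- optimizeCountrySeries(CountrySeries("C1", 1990:1995, 100 + 0:5), flat, 1990)
  expect_equal(areaMha(out2), rep(100, 6))
})

test_that("series optimization matches an independent term-by-term oracle", {
  fao <- CountrySeries("C1", c(1990, 2000, 2010), c(120, 119, 118))
  ref <- CountrySeries("C1", c(1990, 2000, 2010), c(100, 60, 75))
  out <- optimizeCountrySeries(fao, ref, 1990)
  # oracle: recompute the anchoring identity year by year
  oracle <- vapply(seq_along(seriesYears(ref)), function(i) {
    120 + areaMha(ref)[i] - 100
  }, 0)
  expect_equal(areaMha(out), oracle)
  expect_equal(oracle, c(120, 80, 95))
})

test_that("series optimization rejects inconsistent inputs", {
  fao <- CountrySeries("C1", 1991:1995, rep(100, 5))
  ref <- CountrySeries("C1", 1990:1995, c(90, 80, 70, 60, 50, 40))
  expect_error(optimizeCountrySeries(fao, ref, 1990), "base year")
  fao2 <- CountrySeries("C1", 1990:1995, rep(10, 6))
  expect_error(optimizeCountrySeries(fao2, ref, 1990), "1992")
})

test_that("regional totals sum the member series", {
  opt <- CountrySeries("C1", 1990:1994, c(5, 4, 3, 2, 1))
  ten <- CountrySeries("C2", 1990:1994, rep(10, 5))
  reg <- buildRegionSeries(opt, list(ten, ten))
  expect_equal(areaMha(reg), areaMha(opt) + 20)
  expect_identical(reg@country, "REGION")
  expect_equal(areaMha(buildRegionSeries(opt, list())), areaMha(opt))
  short <- CountrySeries("C3", 1990:1993, rep(1, 4))
  expect_error(buildRegionSeries(opt, list(short)), "mismatch")

  set.seed(42)
  series <- lapply(1:3, function(k)
    CountrySeries(paste0("C", k), 1990:1999, runif(10, 1, 50)))
  reg3 <- buildRegionSeries(series[[1]], series[-1])
  # brute-force accumulation oracle
  acc <- rep(0, 10)
  for (s in series) for (i in 1:10) acc[i] <- acc[i] + areaMha(s)[i]
  expect_equal(areaMha(reg3), acc)
})

test_that("adjustment rates are quotients with the documented identities", {
  opt <- CountrySeries("C1", 1990:1995, c(10, 9, 8, 7, 8, 9))
  expect_equal(unname(adjustRate(computeAdjustRate(opt, opt))[, 1]), rep(1, 6))
  half <- CountrySeries("C1", 1990:1995, areaMha(opt) / 2)
  expect_equal(unname(adjustRate(computeAdjustRate(half, opt))[, 1]), rep(0.5, 6))
  zero <- CountrySeries("C1", 1990:1995, c(10, 0, 8, 7, 8, 9))
  expect_error(computeAdjustRate(opt, zero), "zero")

  # synthetic decline: the rate minimum coincides with the reference minimum
  tabs <- genCountryTables(seed = 13, noiseSd = 0)
  o <- optimizeCountrySeries(tabs$fao[[1]], tabs$rosstat, 1990)
  rate <- computeAdjustRate(o, tabs$fao[[1]])
  # oracle: exhaustive scan of the quotient series
  q <- areaMha(o) / areaMha(tabs$fao[[1]])
  expect_equal(which.min(adjustRate(rate)[, 1]), which.min(q))
  expect_equal(seriesYears(rate)[which.min(adjustRate(rate)[, 1])],
               seriesYears(tabs$rosstat)[which.min(areaMha(tabs$rosstat))])
})

test_that("monotone coupling: falling reference with flat records lowers the rate", {
  fao <- CountrySeries("C1", 1990:1999, rep(100, 10))
  ref <- CountrySeries("C1", 1990:1999, seq(90, 45, length.out = 10))
  o <- optimizeCountrySeries(fao, ref, 1990)
  r <- adjustRate(computeAdjustRate(o, fao))[, 1]
  expect_true(all(diff(r) < 0))
})

mkField <- function(grid, years, frac) {
  methods::new("CroplandField", grid = grid, years = as.integer(years),
               fraction = frac, metadata = list())
}

test_that("gridded rescaling multiplies, clamps and preserves rank order", {
  g <- genGrid(6, 8, latRange = c(48, 60), lonRange = c(30, 46),
               nCountries = 1L, seed = 31)
  yrs <- 2000:2002
  base <- genHydeLike(g, yrs, seed = 32, temporalCv = 0)
  ones <- methods::new("AdjustRateSeries", years = as.integer(yrs),
                       rate = matrix(1, 3, 1, dimnames = list(NULL, "C1")))
  out <- rescaleGridded(base, ones)
  expect_identical(fraction(out), fraction(base))
  expect_equal(sum(clampReport(out)$clamped_mha), 0)

  r74 <- methods::new("AdjustRateSeries", years = as.integer(yrs),
                      rate = matrix(0.74, 3, 1, dimnames = list(NULL, "C1")))
  frac <- fraction(base)
  cell <- which(landMask(g) & countryMask(g) == 1L)[1]
  frac[, , ][cell] <- 0.5  # year 1 slice
  fld <- mkField(g, yrs, frac)
  out74 <- rescaleGridded(fld, r74)
  expect_equal(fraction(out74)[, , 1][cell], 0.37)
  # rank order within the country is unchanged (no clamping)
  sel <- as.vector(countryMask(g) == 1L)
  expect_identical(order(as.vector(fraction(fld)[, , 2])[sel]),
                   order(as.vector(fraction(out74)[, , 2])[sel]))

  # clamping is reported in Mha
  fracHi <- fraction(base)
  fracHi[, , 1][cell] <- 0.9
  up <- methods::new("AdjustRateSeries", years = as.integer(yrs),
                     rate = matrix(1.2, 3, 1, dimnames = list(NULL, "C1")))
  outHi <- rescaleGridded(mkField(g, yrs, fracHi), up)
  expect_true(all(fraction(outHi) <= 1))
  expect_gt(clampReport(outHi)$clamped_mha[1], 0)
})

test_that("rescaling conserves national totals and round-trips", {
  g <- genGrid(6, 8, latRange = c(48, 60), lonRange = c(30, 46),
               nCountries = 1L, seed = 33)
  yrs <- 2000:2004
  base <- genHydeLike(g, yrs, seed = 34, maxFrac = 0.5)
  r <- methods::new("AdjustRateSeries", years = as.integer(yrs),
                    rate = matrix(seq(0.9, 0.5, length.out = 5), 5, 1,
                                  dimnames = list(NULL, "C1")))
  out <- rescaleGridded(base, r)
  for (t in seq_along(yrs)) {
    expect_equal(croplandTotalMha(out, yrs[t]),
                 croplandTotalMha(base, yrs[t]) * unname(adjustRate(r)[t, 1]),
                 tolerance = 1e-12)
  }
  inv <- methods::new("AdjustRateSeries", years = as.integer(yrs),
                      rate = matrix(1 / adjustRate(r)[, 1], 5, 1,
                                    dimnames = list(NULL, "C1")))
  back <- rescaleGridded(out, inv)
  expect_equal(fraction(back), fraction(base), tolerance = 1e-12)

  # a year without a rate: passthrough by default, error when disallowed
  wide <- genHydeLike(g, 1998:2004, seed = 34, maxFrac = 0.5)
  thru <- rescaleGridded(wide, r)
  expect_identical(fraction(thru)[, , 1], fraction(wide)[, , 1])
  expect_error(rescaleGridded(wide, r, passthrough = FALSE), "1998")
})

test_that("abandonment areas difference the national or gridded record", {
  s <- CountrySeries("C1", 1990:1995, rep(50, 6))
  expect_equal(abandonmentArea(s, 1990, 1995), 0)
  s2 <- CountrySeries("C1", c(1990, 2017), c(100, 80))
  expect_equal(abandonmentArea(s2, 1990, 2017), 20)
  expect_error(abandonmentArea(s2, 2017, 1990), "y0 < y1")
  expect_error(abandonmentArea(s2, 1990, 2020), "out of range")

  g <- genGrid(6, 8, latRange = c(48, 60), lonRange = c(30, 46),
               nCountries = 1L, seed = 35)
  f <- genHydeLike(g, 2000:2003, seed = 36, temporalCv = 0)
  shrunk <- fraction(f)
  shrunk[, , 4] <- shrunk[, , 4] * 0.8
  fld <- mkField(g, 2000:2003, shrunk)
  got <- abandonmentArea(fld, 2000, 2003)
  # cell-by-cell summation oracle
  sel <- countryMask(g) > 0L
  oracle <- sum((shrunk[, , 1][sel] - shrunk[, , 4][sel]) * cellArea(g)[sel]) * 1e-10
  expect_equal(got, oracle, tolerance = 1e-12)
})
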